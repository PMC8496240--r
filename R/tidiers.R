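#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a REML fit
#'
#' One row per variance component, with standard errors when the fit was
#' run with `se = TRUE`.
#'
#' @param x A `poe_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `estimate` (and `se`).
#' @method tidy poe_fit
#' @export
tidy.poe_fit <- function(x, ...) {
  est <- vc_as_vector(x$vc, x$model)
  out <- tibble::tibble(component = names(est), estimate = unname(est))
  if (!is.null(x$se)) out <- dplyr::left_join(out, x$se, by = "component")
  out
}

#' Glance at a REML fit
#'
#' @param x A `poe_fit`.
#' @param ... Unused.
#' @return A one-row tibble: logL, convergence, sizes, and the derived
#'   genetic parameters ([derived_parameters()]).
#' @method glance poe_fit
#' @export
glance.poe_fit <- function(x, ...) {
  base <- tibble::tibble(model = x$model, logL = x$logL,
                         converged = x$converged, n_outer = x$n_outer,
                         nobs = x$n, n_effects = x$m)
  if (x$model == "imprinting") {
    dplyr::bind_cols(base, derived_parameters(x$vc))
  } else {
    base
  }
}

#' Tidy BLUP solutions
#'
#' @param x A `poe_blup`.
#' @param effects Return per-slot solutions instead of the per-individual
#'   summary.
#' @param ... Unused.
#' @return A tibble of solutions: per individual (`a_s`, `a_d`,
#'   `poe_dev`) or per effect slot.
#' @method tidy poe_blup
#' @export
tidy.poe_blup <- function(x, effects = FALSE, ...) {
  if (effects) x$effects else x$individuals
}

#' @method glance poe_blup
#' @export
glance.poe_blup <- function(x, ...) {
  tibble::tibble(model = x$model, logL = x$logL,
                 n_effects = nrow(x$effects),
                 n_individuals = nrow(x$individuals))
}

#' Plot estimated variance components
#'
#' Bar chart of the estimated components with +/- 2 SE error bars when
#' standard errors are available.
#'
#' @param object A `poe_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poe_fit
#' @export
autoplot.poe_fit <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = sprintf("REML variance components (%s model)", object$model)) +
    ggplot2::theme_minimal()
  if ("se" %in% names(d) && !all(is.na(d$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - 2 * .data$se,
                   ymax = .data$estimate + 2 * .data$se), width = 0.2)
  }
  p
}

#' Plot predicted effects as sire against effects as dam
#'
#' Points off the diagonal indicate predicted parent-of-origin deviations.
#'
#' @param object A `poe_blup`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poe_blup
#' @export
autoplot.poe_blup <- function(object, ...) {
  ggplot2::ggplot(object$individuals,
                  ggplot2::aes(x = .data$a_s, y = .data$a_d)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "predicted effect as sire",
                  y = "predicted effect as dam") +
    ggplot2::theme_minimal()
}

#' Heatmap of a relationship matrix
#'
#' @param M A labelled relationship matrix (dense or sparse).
#' @return A ggplot object.
#' @export
plot_relmat <- function(M) {
  M <- as.matrix(M)
  d <- tibble::tibble(
    row = factor(rep(rownames(M), times = ncol(M)), levels = rev(rownames(M))),
    col = factor(rep(colnames(M), each = nrow(M)), levels = colnames(M)),
    value = as.vector(M))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "cov") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
print.poe_fit <- function(x, ...) {
  cat(sprintf("REML %s model fit: logL = %.4f (%s, %d outer pass(es))\n",
              x$model, x$logL,
              if (x$converged) "converged" else "NOT converged", x$n_outer))
  print(tidy(x))
  invisible(x)
}

#' @export
print.poe_blup <- function(x, ...) {
  cat(sprintf("BLUP solutions (%s model), %d individuals, %d effect slots\n",
              x$model, nrow(x$individuals), nrow(x$effects)))
  print(x$individuals)
  invisible(x)
}

#' @importFrom rlang .data
NULL
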