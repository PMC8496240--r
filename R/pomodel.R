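#' Variance components of the parent-of-origin model
#'
#' Container for the gametic variance as sire (`sigma_s2`), as dam
#' (`sigma_d2`), their covariance (`sigma_sd`), the residual variance
#' (`sigma_e2`) and an optional i.i.d. group (litter) variance
#' (`sigma_c2`). Validity requires positive variances and a positive
#' semidefinite 2x2 gametic covariance matrix; the derived imprinting
#' variance `sigma_i2 = sigma_s2 + sigma_d2 - 2 sigma_sd` is then
#' automatically non-negative.
#'
#' @param sigma_s2,sigma_d2 Gametic variances under paternal / maternal
#'   expression (trait units squared), > 0.
#' @param sigma_sd Covariance between the two expression patterns.
#' @param sigma_e2 Residual variance, > 0.
#' @param sigma_c2 Optional group (litter) variance, >= 0 or `NULL`.
#' @return A validated `ggrm_vc` list.
#' @export
variance_components <- function(sigma_s2, sigma_d2, sigma_sd, sigma_e2,
                                sigma_c2 = NULL) {
  if (!all(is.finite(c(sigma_s2, sigma_d2, sigma_sd, sigma_e2)))) {
    abort_input("variance components must be finite")
  }
  if (sigma_s2 <= 0 || sigma_d2 <= 0 || sigma_e2 <= 0) {
    abort_input("sigma_s2, sigma_d2 and sigma_e2 must be > 0")
  }
  if (sigma_sd^2 > sigma_s2 * sigma_d2 * (1 + 1e-12)) {
    abort_input("gametic covariance matrix [[sigma_s2, sigma_sd], [sigma_sd, sigma_d2]] is not PSD")
  }
  if (!is.null(sigma_c2) && (!is.finite(sigma_c2) || sigma_c2 < 0)) {
    abort_input("sigma_c2 must be >= 0")
  }
  structure(list(sigma_s2 = sigma_s2, sigma_d2 = sigma_d2,
                 sigma_sd = sigma_sd, sigma_e2 = sigma_e2,
                 sigma_c2 = sigma_c2),
            class = "ggrm_vc")
}

#' Residual precision weights of the general parent-of-origin model
#'
#' Records of individuals represented by their own gametic effects carry
#' weight 1. Records linked to parental effects (reduced and mixed
#' observation equations) have a composite residual containing both
#' parental Mendelian sampling terms, with variance
#' `(1 - F_sire)/2 * sigma_s2 + (1 - F_dam)/2 * sigma_d2 + sigma_e2`;
#' the weight is `sigma_e2` divided by that variance, so the residual
#' variance of record i is `sigma_e2 / w_i` and `diag(w)` is the precision
#' multiplier in the mixed-model equations.
#'
#' @param kind Character vector of equation kinds (`"gametic"`,
#'   `"reduced"`, `"mixed_sire_ta"`, `"mixed_dam_ta"`).
#' @param F_sire,F_dam Parental inbreeding coefficients (ignored for
#'   `"gametic"` records).
#' @param vc A [variance_components()] object (for the Mendelian null pass
#'   `sigma_s2 = sigma_d2 = sigma_sd = sigma_a2`).
#' @return Numeric vector of weights in `(0, 1]`.
#' @export
residual_weights <- function(kind, F_sire, F_dam, vc) {
  vr <- 0.5 * (1 - F_sire) * vc$sigma_s2 + 0.5 * (1 - F_dam) * vc$sigma_d2 +
    vc$sigma_e2
  w <- ifelse(kind == "gametic", 1, vc$sigma_e2 / vr)
  if (any(!is.finite(w) | w <= 0)) abort_input("weights must be finite and > 0")
  w
}

#' Assemble the design of a parent-of-origin analysis
#'
#' Builds the observation equations linking phenotypes to genetic-effect
#' slots. Individuals represented by gametic pairs get a `"gametic"`
#' equation (coefficient 1 on their own paternal slot in the as-design and
#' maternal slot in the ad-design). Transmitting-ability individuals get a
#' reduced-type equation on their parents' effects: coefficient 1 on a
#' parental transmitting-ability slot, or 1/2 on each of a gametic parent's
#' two slots; kinds are `"reduced"` (parents share a representation),
#' `"mixed_sire_ta"` (sire transmitting ability, dam gametic) and
#' `"mixed_dam_ta"` (the reverse).
#'
#' @param ped A pedigree.
#' @param phenotypes Data frame with an `id` column, the response column
#'   and any fixed-effect / group columns.
#' @param fixed One-sided formula for the fixed effects (default `~ 1`);
#'   factors get a first-level reference constraint, aliased columns are
#'   dropped with a message.
#' @param response Name of the response column (default `"y"`).
#' @param group Optional name of an i.i.d. group (litter) column.
#' @param equations `"auto"` (per-individual, from the representation),
#'   `"gametic"` (require all phenotyped individuals gametic-represented)
#'   or `"reduced"` (reduced equations for all final progeny — phenotyped
#'   individuals with offspring keep their own gametic equations — and
#'   phenotyped final progeny pruned from the effect set).
#' @return A `ggrm_design` list with the (possibly pruned) pedigree, slot
#'   table, response `y`, designs `X`, `Zs`, `Zd`, optional `Zc`, and the
#'   observation table `obs` (id, kind, parental F).
#' @export
poe_design <- function(ped, phenotypes, fixed = ~1, response = "y",
                       group = NULL, equations = c("auto", "gametic", "reduced")) {
  equations <- match.arg(equations)
  ped <- as_pedigree(ped)
  phenotypes <- as.data.frame(phenotypes)
  if (!"id" %in% names(phenotypes)) {
    names(phenotypes)[1L] <- "id"
  }
  phenotypes$id <- as.character(phenotypes$id)
  if (!response %in% names(phenotypes)) {
    abort_input(sprintf("response column '%s' not found", response))
  }
  if (nrow(phenotypes) == 0L) abort_input("no records: empty phenotype table")
  missing_ids <- setdiff(phenotypes$id, ped$id)
  if (length(missing_ids)) {
    abort_input(sprintf("phenotyped individual(s) not in the pedigree: %s",
                        paste(utils::head(missing_ids, 5L), collapse = ", ")))
  }

  pi <- match(phenotypes$id, ped$id)
  rep_i <- ped$rep[pi]
  use_gametic <- switch(equations,
    auto = rep_i == "gametic",
    gametic = {
      if (any(rep_i != "gametic")) {
        abort_input("equations = 'gametic' requires all phenotyped individuals to carry representation code 2")
      }
      rep(TRUE, length(pi))
    },
    reduced = {
      ## reduced equations are exact only for final progeny: an individual
      ## with offspring contributes Mendelian sampling to other effects and
      ## must keep its own (gametic) equation
      has_off <- phenotypes$id %in% c(ped$sire, ped$dam)
      has_off & rep_i == "gametic"
    }
  )
  sire <- ped$sire[pi]
  dam <- ped$dam[pi]
  if (any(!use_gametic & (is.na(sire) | is.na(dam)))) {
    bad <- phenotypes$id[!use_gametic & (is.na(sire) | is.na(dam))][1L]
    abort_input(sprintf(
      "individual '%s' needs a reduced observation equation but has an unknown parent", bad))
  }

  if (equations == "reduced") {
    keep <- unique(c(stats::na.omit(sire[!use_gametic]),
                     stats::na.omit(dam[!use_gametic]),
                     phenotypes$id[use_gametic]))
    pruned <- setdiff(ped$id, prune_pedigree(ped, keep)$id)
    if (length(pruned)) {
      rlang::inform(sprintf(
        "reduced analysis: %d individual(s) without links to the effect set dropped from the pedigree",
        length(pruned)))
    }
    ped <- prune_pedigree(ped, keep)
  }

  ## sire/dam were resolved on the full pedigree above; after pruning the
  ## record individuals themselves may be gone but their parents remain.
  slots <- effect_slots(ped)
  Ftab <- inbreeding(ped)
  Fv <- stats::setNames(Ftab$F, Ftab$id)
  slot_of <- split(slots$slot, factor(slots$id, levels = ped$id))
  rep_of <- function(id) ifelse(is.na(id), NA_character_,
                                ped$rep[match(id, ped$id)])

  n <- nrow(phenotypes)
  m <- nrow(slots)
  kind <- character(n)
  zi_s <- vector("list", n); zx_s <- vector("list", n)
  zi_d <- vector("list", n); zx_d <- vector("list", n)
  for (r in seq_len(n)) {
    if (use_gametic[r]) {
      kind[r] <- "gametic"
      own <- slot_of[[phenotypes$id[r]]]
      zi_s[[r]] <- own[1L]; zx_s[[r]] <- 1
      zi_d[[r]] <- own[2L]; zx_d[[r]] <- 1
    } else {
      srep <- rep_of(sire[r]); drep <- rep_of(dam[r])
      kind[r] <- if (srep == drep) "reduced"
                 else if (srep == "ta") "mixed_sire_ta" else "mixed_dam_ta"
      ss <- slot_of[[sire[r]]]
      dd <- slot_of[[dam[r]]]
      zi_s[[r]] <- ss; zx_s[[r]] <- if (length(ss) == 1L) 1 else c(0.5, 0.5)
      zi_d[[r]] <- dd; zx_d[[r]] <- if (length(dd) == 1L) 1 else c(0.5, 0.5)
    }
  }
  Zs <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lengths(zi_s)),
                             j = unlist(zi_s), x = unlist(zx_s),
                             dims = c(n, m))
  Zd <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lengths(zi_d)),
                             j = unlist(zi_d), x = unlist(zx_d),
                             dims = c(n, m))

  X <- stats::model.matrix(fixed, data = phenotypes)
  if (ncol(X) == 0L) abort_input("empty fixed-effect design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    rlang::inform(sprintf("dropping %d aliased fixed-effect column(s): %s",
                          length(aliased), paste(aliased, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  Zc <- NULL
  if (!is.null(group)) {
    if (!group %in% names(phenotypes)) {
      abort_input(sprintf("group column '%s' not found", group))
    }
    g <- factor(phenotypes[[group]])
    Zc <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(g), x = 1,
                               dims = c(n, nlevels(g)),
                               dimnames = list(NULL, levels(g)))
  }

  obs <- tibble::tibble(
    id = phenotypes$id, kind = kind,
    F_sire = ifelse(kind == "gametic", NA_real_, unname(Fv[sire])),
    F_dam = ifelse(kind == "gametic", NA_real_, unname(Fv[dam]))
  )
  y <- as.numeric(phenotypes[[response]])
  if (anyNA(y)) abort_input("missing values in the response")

  structure(list(ped = ped, slots = slots, y = y, X = X, Zs = Zs, Zd = Zd,
                 Zc = Zc, obs = obs, n = n, m = m, p = ncol(X),
                 q = if (is.null(Zc)) 0L else ncol(Zc),
                 response = response, equations = equations),
            class = "ggrm_design")
}

## Fixed-weight cross-products shared by all likelihood evaluations.
## H = [X Zs Zd (Zc)] for the imprinting model, [X Zs+Zd (Zc)] for the
## Mendelian single-vector model.
design_blocks <- function(design, w, model) {
  parts <- if (model == "imprinting") {
    list(Matrix::Matrix(design$X, sparse = TRUE), design$Zs, design$Zd)
  } else {
    list(Matrix::Matrix(design$X, sparse = TRUE), design$Zs + design$Zd)
  }
  if (!is.null(design$Zc)) parts <- c(parts, list(design$Zc))
  H <- do.call(cbind, parts)
  Hw <- H * w
  list(M = Matrix::forceSymmetric(Matrix::crossprod(H, Hw)),
       rhs = as.numeric(Matrix::crossprod(H, w * design$y)),
       ytWy = sum(w * design$y^2), sumlogw = sum(log(w)), w = w)
}

## One REML evaluation at fixed weights. Returns the restricted
## log-likelihood (constant terms omitted) and, optionally, solutions.
reml_eval <- function(design, vc, ginv, model, blocks, ld_gbar,
                      solutions = FALSE) {
  m <- design$m; p <- design$p; q <- design$q; n <- design$n
  se2 <- vc$sigma_e2
  if (model == "imprinting") {
    Sigma <- matrix(c(vc$sigma_s2, vc$sigma_sd, vc$sigma_sd, vc$sigma_d2), 2L)
    detS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
    if (detS <= 0) return(list(logl = -Inf))
    Sinv <- solve(Sigma)
    Gpart <- Matrix::kronecker(Sinv, ginv)
    ld_gstar <- m * log(detS) + 2 * ld_gbar
    k <- 2L * m
  } else {
    sa2 <- vc$sigma_s2
    Gpart <- ginv / sa2
    ld_gstar <- m * log(sa2) + ld_gbar
    k <- m
  }
  if (q > 0L) {
    if (is.null(vc$sigma_c2) || vc$sigma_c2 <= 0) return(list(logl = -Inf))
    ld_gstar <- ld_gstar + q * log(vc$sigma_c2)
    pad <- Matrix::bdiag(Matrix::Matrix(0, p, p), Gpart,
                         Matrix::Diagonal(q, 1 / vc$sigma_c2))
  } else {
    pad <- Matrix::bdiag(Matrix::Matrix(0, p, p), Gpart)
  }
  C <- Matrix::forceSymmetric(blocks$M / se2 + pad)
  ch <- tryCatch(suppressWarnings(Matrix::Cholesky(C, LDL = FALSE,
                                                   perm = TRUE)),
                 error = function(e) NULL)
  if (is.null(ch)) return(list(logl = -Inf))
  ld_C <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  rhs <- blocks$rhs / se2
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  ypy <- blocks$ytWy / se2 - sum(sol * rhs)
  ld_R <- n * log(se2) - blocks$sumlogw
  logl <- -0.5 * (ld_R + ld_gstar + ld_C + ypy)
  out <- list(logl = logl)
  if (solutions) {
    out$beta <- stats::setNames(sol[seq_len(p)], colnames(design$X))
    if (model == "imprinting") {
      out$a_s <- sol[p + seq_len(m)]
      out$a_d <- sol[p + m + seq_len(m)]
    } else {
      out$a_s <- out$a_d <- sol[p + seq_len(m)]
    }
    if (q > 0L) out$group <- stats::setNames(sol[p + k + seq_len(q)],
                                             colnames(design$Zc))
  }
  out
}

logdet_gbar <- function(ginv) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(ginv), LDL = FALSE, perm = TRUE)
  -2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

#' Restricted log-likelihood of the general parent-of-origin model
#'
#' Evaluates the REML log-likelihood (additive constants omitted) of the
#' weighted mixed model at the given variance components, with residual
#' weights computed from those same components. Deterministic given inputs.
#'
#' @param design A [poe_design()] object.
#' @param vc A [variance_components()] object (Mendelian null: pass equal
#'   `sigma_s2 = sigma_d2 = sigma_sd` and set `model = "mendelian"`).
#' @param ginv Sparse inverse relationship matrix (defaults to
#'   [generalized_inverse()] of the design's pedigree).
#' @param model `"imprinting"` (two correlated gametic effect vectors) or
#'   `"mendelian"` (a single vector, the additive/animal-model null).
#' @param weights Optional fixed weight vector overriding the
#'   self-consistent weights (used by the outer reweighting loop).
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(design, vc, ginv = NULL,
                        model = c("imprinting", "mendelian"), weights = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "ggrm_design"))
  if (is.null(ginv)) ginv <- generalized_inverse(design$ped)
  if (is.null(weights)) {
    weights <- residual_weights(design$obs$kind, design$obs$F_sire,
                                design$obs$F_dam, vc)
  }
  blocks <- design_blocks(design, weights, model)
  reml_eval(design, vc, ginv, model, blocks, logdet_gbar(ginv))$logl
}

#' BLUP solutions of the parent-of-origin mixed model
#'
#' Solves the mixed-model equations at fixed variance components and maps
#' the slot solutions back to individuals: transmitting abilities as sire
#' and dam (gametic slots averaged) and the imprinting deviation
#' `a_s - a_d`.
#'
#' @inheritParams reml_loglik
#' @return A `poe_blup` object: `beta` (tibble of fixed effects), `effects`
#'   (per-slot solutions), `individuals` (per-individual transmitting
#'   abilities and imprinting deviations), `logL`, `model`.
#' @export
poe_blup <- function(design, vc, ginv = NULL,
                     model = c("imprinting", "mendelian"), weights = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "ggrm_design"))
  if (is.null(ginv)) ginv <- generalized_inverse(design$ped)
  if (is.null(weights)) {
    weights <- residual_weights(design$obs$kind, design$obs$F_sire,
                                design$obs$F_dam, vc)
  }
  blocks <- design_blocks(design, weights, model)
  ev <- reml_eval(design, vc, ginv, model, blocks, logdet_gbar(ginv),
                  solutions = TRUE)
  if (!is.finite(ev$logl)) abort_input("mixed-model equations are singular at these components")
  slots <- design$slots
  effects <- tibble::tibble(slot = slots$slot, id = slots$id,
                            kind = slots$kind, label = slots$label,
                            a_s = ev$a_s, a_d = ev$a_d)
  individuals <- effects |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(representation = if (dplyr::n() == 1L) "ta" else "gametic",
                     a_s = mean(.data$a_s), a_d = mean(.data$a_d),
                     .groups = "drop") |>
    dplyr::mutate(poe_dev = .data$a_s - .data$a_d) |>
    dplyr::arrange(match(.data$id, slots$id))
  structure(list(beta = tibble::tibble(term = names(ev$beta),
                                       estimate = unname(ev$beta)),
                 effects = effects, individuals = individuals,
                 group = ev$group, logL = ev$logl, model = model,
                 vc = vc),
            class = "poe_blup")
}

#' REML estimation of imprinting variance components
#'
#' Maximises the restricted log-likelihood over
#' `(log sigma_s2, log sigma_d2, atanh r, log sigma_e2[, log sigma_c2])`
#' (Nelder-Mead), which keeps the gametic covariance matrix positive
#' definite by construction. When reduced or mixed observation equations
#' are present, an outer loop recomputes the residual weights from the
#' current estimates and refits until the log-likelihood stabilises,
#' starting from equal weights. The Mendelian null constrains
#' `sigma_s2 = sigma_d2 = sigma_sd` and is fitted as the equivalent
#' single-vector (animal-type) model.
#'
#' @inheritParams reml_loglik
#' @param start Optional [variance_components()] start values.
#' @param se Compute standard errors from the numerical Hessian of the
#'   restricted likelihood on the variance-component scale.
#' @param control List: `maxit` (inner Nelder-Mead iterations, 1500),
#'   `reltol` (inner relative tolerance, 1e-10), `tol_outer` (absolute
#'   logL change between reweighting passes, 1e-6), `max_outer` (50).
#' @return A `poe_fit` object; see [tidy.poe_fit()] and
#'   [glance.poe_fit()].
#' @export
fit_poe_reml <- function(design, model = c("imprinting", "mendelian"),
                         ginv = NULL, start = NULL, se = FALSE,
                         control = list()) {
  model <- match.arg(model)
  stopifnot(inherits(design, "ggrm_design"))
  ctrl <- utils::modifyList(list(maxit = 1500L, reltol = 1e-10,
                                 tol_outer = 1e-6, max_outer = 50L), control)
  if (is.null(ginv)) ginv <- generalized_inverse(design$ped)
  ld_gbar <- logdet_gbar(ginv)
  has_group <- design$q > 0L

  vy <- stats::var(design$y)
  if (is.null(start)) {
    start <- variance_components(0.25 * vy, 0.25 * vy, 0.05 * vy, 0.5 * vy,
                                 if (has_group) 0.1 * vy else NULL)
  }
  par0 <- if (model == "imprinting") {
    c(log(start$sigma_s2), log(start$sigma_d2),
      atanh(max(min(start$sigma_sd / sqrt(start$sigma_s2 * start$sigma_d2),
                    0.99), -0.99)),
      log(start$sigma_e2), if (has_group) log(max(start$sigma_c2, 1e-8 * vy)))
  } else {
    c(log(start$sigma_s2), log(start$sigma_e2),
      if (has_group) log(max(start$sigma_c2, 1e-8 * vy)))
  }
  par_to_vc <- function(par) {
    if (model == "imprinting") {
      ss <- exp(par[1L]); dd <- exp(par[2L]); r <- tanh(par[3L])
      variance_components(ss, dd, r * sqrt(ss * dd), exp(par[4L]),
                          if (has_group) exp(par[5L]))
    } else {
      sa <- exp(par[1L])
      variance_components(sa, sa, sa, exp(par[2L]),
                          if (has_group) exp(par[3L]))
    }
  }

  needs_weights <- any(design$obs$kind != "gametic")
  w <- rep(1, design$n)
  trace <- list()
  par <- par0
  logl_prev <- -Inf
  converged <- FALSE
  n_outer <- 0L
  repeat {
    n_outer <- n_outer + 1L
    blocks <- design_blocks(design, w, model)
    negll <- function(p) {
      vc <- tryCatch(par_to_vc(p), error = function(e) NULL)
      if (is.null(vc)) return(1e10)
      ll <- reml_eval(design, vc, ginv, model, blocks, ld_gbar)$logl
      if (!is.finite(ll)) 1e10 else -ll
    }
    for (attempt in 1:3) {  # restart a degenerate simplex from its best point
      opt <- stats::optim(par, negll, method = "Nelder-Mead",
                          control = list(maxit = ctrl$maxit,
                                         reltol = ctrl$reltol))
      par <- opt$par
      if (opt$convergence == 0L) break
    }
    logl <- -opt$value
    trace[[n_outer]] <- tibble::tibble(outer = n_outer, logL = logl,
                                       inner_evals = opt$counts[["function"]])
    if (!needs_weights || abs(logl - logl_prev) < ctrl$tol_outer) {
      converged <- TRUE
      break
    }
    if (n_outer >= ctrl$max_outer) {
      rlang::warn("outer reweighting loop did not converge; best point returned")
      converged <- FALSE
      break
    }
    logl_prev <- logl
    w <- residual_weights(design$obs$kind, design$obs$F_sire,
                          design$obs$F_dam, par_to_vc(par))
  }
  vc <- par_to_vc(par)

  se_tab <- NULL
  if (se) {
    vc_vec <- vc_as_vector(vc, model)
    negll_vc <- function(x) {
      v <- tryCatch(vc_from_vector(x, model, has_group),
                    error = function(e) NULL)
      if (is.null(v)) return(1e10)
      ll <- reml_eval(design, v, ginv, model,
                      design_blocks(design, w, model), ld_gbar)$logl
      if (!is.finite(ll)) 1e10 else -ll
    }
    H <- tryCatch(stats::optimHess(vc_vec, negll_vc), error = function(e) NULL)
    Vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vcov)) {
      se_tab <- tibble::tibble(component = names(vc_vec),
                               se = sqrt(pmax(diag(Vcov), 0)))
    }
  }

  structure(list(vc = vc, logL = logl, model = model,
                 converged = isTRUE(converged) && opt$convergence == 0L,
                 n_outer = n_outer, weights = w,
                 trace = dplyr::bind_rows(trace), se = se_tab,
                 n = design$n, m = design$m, p = design$p, q = design$q,
                 equations = design$equations),
            class = "poe_fit")
}

vc_as_vector <- function(vc, model) {
  if (model == "imprinting") {
    out <- c(sigma_s2 = vc$sigma_s2, sigma_d2 = vc$sigma_d2,
             sigma_sd = vc$sigma_sd, sigma_e2 = vc$sigma_e2)
  } else {
    out <- c(sigma_a2 = vc$sigma_s2, sigma_e2 = vc$sigma_e2)
  }
  if (!is.null(vc$sigma_c2)) out <- c(out, sigma_c2 = vc$sigma_c2)
  out
}

vc_from_vector <- function(x, model, has_group) {
  if (model == "imprinting") {
    variance_components(x[1L], x[2L], x[3L], x[4L],
                        if (has_group) x[5L])
  } else {
    variance_components(x[1L], x[1L], x[1L], x[2L],
                        if (has_group) x[3L])
  }
}

#' Restricted likelihood-ratio test for imprinting variance
#'
#' `statistic = 2 (logL_imprinting - logL_mendelian)` compared with the
#' upper tail of a chi-square distribution (default 2 degrees of freedom,
#' the two extra free parameters of the imprinting model). A slightly
#' negative statistic (numerical slack) is clipped to zero with a warning.
#'
#' @param imprinting,mendelian `poe_fit` objects or restricted
#'   log-likelihood values.
#' @param df Degrees of freedom (default 2).
#' @param slack Numerical slack below zero tolerated without warning.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, the two logL.
#' @export
rlrt <- function(imprinting, mendelian, df = 2, slack = 1e-6) {
  l1 <- if (inherits(imprinting, "poe_fit")) imprinting$logL else as.numeric(imprinting)
  l0 <- if (inherits(mendelian, "poe_fit")) mendelian$logL else as.numeric(mendelian)
  stat <- 2 * (l1 - l0)
  if (stat < 0) {
    if (stat < -slack) {
      rlang::warn(sprintf("negative RLRT statistic (%.3g) clipped to 0", stat))
    }
    stat <- 0
  }
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 logL_imprinting = l1, logL_mendelian = l0)
}

#' Derived genetic parameters
#'
#' From the estimated components: imprinting variance
#' `sigma_i2 = sigma_s2 + sigma_d2 - 2 sigma_sd`, correlation between
#' expression patterns `r = sigma_sd / sqrt(sigma_s2 sigma_d2)`, relative
#' imprinting variance `i2 = sigma_i2 / (sigma_s2 + sigma_d2)`,
#' heritability `h2 = (sigma_s2 + sigma_d2) / sigma_p2` and relative group
#' variance `c2 = sigma_c2 / sigma_p2`, with the phenotypic variance
#' `sigma_p2 = sigma_s2 + sigma_d2 + sigma_c2 + sigma_e2`. The denominators
#' are chosen for internal consistency between `r`, `i2` and `h2`.
#'
#' @param vc A [variance_components()] object or `poe_fit`.
#' @return A one-row tibble.
#' @export
derived_parameters <- function(vc) {
  if (inherits(vc, "poe_fit")) vc <- vc$vc
  sc2 <- if (is.null(vc$sigma_c2)) 0 else vc$sigma_c2
  sg2 <- vc$sigma_s2 + vc$sigma_d2
  si2 <- sg2 - 2 * vc$sigma_sd
  sp2 <- sg2 + sc2 + vc$sigma_e2
  r <- if (vc$sigma_s2 > 0 && vc$sigma_d2 > 0) {
    vc$sigma_sd / sqrt(vc$sigma_s2 * vc$sigma_d2)
  } else NA_real_
  tibble::tibble(sigma_i2 = si2, r = r, i2 = si2 / sg2, h2 = sg2 / sp2,
                 c2 = sc2 / sp2, sigma_p2 = sp2)
}
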