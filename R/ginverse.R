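#' Contribution vector for one genetic effect
#'
#' Each genetic effect adds a rank-1 contribution `u_i u_i' delta_i` to the
#' inverse generalized gametic relationship matrix. The vector `u_i` holds 1
#' at the effect's own slot and negative coefficients at the slots of the
#' known parents' effects: -1/2 per parental transmitting ability (for a
#' transmitting-ability effect), -1/4 per parental gametic slot (ditto),
#' -1 for the parent's transmitting ability of a gametic effect, and -1/2
#' per parental gametic slot of a gametic effect. Between 1 and 5 entries.
#'
#' @param case One of the 12 case labels (see [classify_effects()]).
#' @param i Slot index of the effect itself.
#' @param sire,dam For `a-*` cases: slot index of a parent's transmitting
#'   ability (length 1) or of its gametic pair (length 2, paternal first);
#'   omit for unknown parents.
#' @param parent For `g-*` cases: slot index/indices of the parent the
#'   gamete derives from (length 1 if a transmitting ability, 2 if gametic).
#' @return A tibble with columns `slot`, `coef`; the own slot carries
#'   coefficient 1.
#' @export
contribution_vector <- function(case, i, sire = NULL, dam = NULL, parent = NULL) {
  spec <- case_spec(case)
  got <- list(sire = length(sire), dam = length(dam), parent = length(parent))
  for (part in names(spec$need)) {
    if (got[[part]] != spec$need[[part]]) {
      abort_input(sprintf(
        "case %s expects %d %s slot(s), got %d", case, spec$need[[part]],
        part, got[[part]]))
    }
  }
  for (part in setdiff(names(got), names(spec$need))) {
    if (got[[part]] != 0L) {
      abort_input(sprintf("case %s takes no '%s' slots", case, part))
    }
  }
  slots <- c(sire, dam, parent, i)
  tibble::tibble(slot = as.integer(slots), coef = c(spec$coefs, 1))
}

## Table of parental coefficient patterns per case: which parent slots are
## needed and the coefficient attached to each (own slot always last, +1).
case_spec <- function(case) {
  specs <- list(
    "a-00"   = list(need = c(),                    coefs = numeric(0)),
    "a-0a"   = list(need = c(dam = 1L),            coefs = -0.5),
    "a-a0"   = list(need = c(sire = 1L),           coefs = -0.5),
    "a-0gg"  = list(need = c(dam = 2L),            coefs = c(-0.25, -0.25)),
    "a-gg0"  = list(need = c(sire = 2L),           coefs = c(-0.25, -0.25)),
    "a-aa"   = list(need = c(sire = 1L, dam = 1L), coefs = c(-0.5, -0.5)),
    "a-agg"  = list(need = c(sire = 1L, dam = 2L), coefs = c(-0.5, -0.25, -0.25)),
    "a-gga"  = list(need = c(sire = 2L, dam = 1L), coefs = c(-0.25, -0.25, -0.5)),
    "a-gggg" = list(need = c(sire = 2L, dam = 2L), coefs = rep(-0.25, 4)),
    "g-a"    = list(need = c(parent = 1L),         coefs = -1),
    "g-gg"   = list(need = c(parent = 2L),         coefs = c(-0.5, -0.5)),
    "g-0"    = list(need = c(),                    coefs = numeric(0))
  )
  if (is.null(specs[[case]])) abort_input(sprintf("unknown case label '%s'", case))
  specs[[case]]
}

#' All 12 direct-inversion case labels
#' @return Character vector of length 12.
#' @export
inversion_cases <- function() {
  c("a-00", "a-0a", "a-a0", "a-0gg", "a-gg0", "a-aa", "a-agg", "a-gga",
    "a-gggg", "g-a", "g-gg", "g-0")
}

#' Inverse Mendelian sampling variance for one genetic effect
#'
#' The 12 cases group into five classes with closed-form inverse Mendelian
#' sampling variances, in terms of the inbreeding coefficients of the known
#' parents:
#' \describe{
#'   \item{`a-00`}{`delta = 2`}
#'   \item{`a-0a`, `a-a0`, `a-0gg`, `a-gg0`}{`delta = 8 / (3 - F_known)`}
#'   \item{`a-aa`, `a-agg`, `a-gga`, `a-gggg`}{`delta = 8 / (2 - F_sire - F_dam)`}
#'   \item{`g-a`, `g-gg`}{`delta = 2 / (1 - F_parent)`}
#'   \item{`g-0`}{`delta = 1`}
#' }
#' These satisfy the generic definition
#' `delta_i = 1 / (Gbar_ii - q_i' Gbar_prev q_i)` (with `q_i` the negated
#' parental coefficients of [contribution_vector()]) for every case, which
#' fixes the one-known-parent class at `8/(3 - F)` — e.g. the two-individual
#' pedigree with one known parent has `(A/2)^-1` diagonal `8/3` — and the
#' known-parent gametic class at `2/(1 - F)`. Alternative literal readings
#' of the rendered one-known-parent formula (`2/(1 - F)`) and of the gametic
#' class (`4/(1 - F)`) are inconsistent with that decomposition and are not
#' used.
#'
#' @inheritParams contribution_vector
#' @param F_sire,F_dam,F_parent Inbreeding coefficients in `[0, 1)` of the
#'   known parents the case requires (`F_parent`: the parent a gametic
#'   effect derives from; for one-known-parent `a` cases pass the known
#'   parent's F as `F_sire` or `F_dam` to match the case).
#' @return The scalar `delta`.
#' @export
mendelian_delta <- function(case, F_sire = NULL, F_dam = NULL, F_parent = NULL) {
  chk <- function(F, who) {
    if (is.null(F)) abort_input(sprintf("case %s needs %s", case, who))
    if (!is.finite(F) || F < 0 || F >= 1) {
      abort_input(sprintf("%s = %s outside [0, 1)", who, format(F)))
    }
    F
  }
  switch(case,
    "a-00" = 2,
    "a-0a" = , "a-0gg" = 8 / (3 - chk(F_dam, "F_dam (known parent)")),
    "a-a0" = , "a-gg0" = 8 / (3 - chk(F_sire, "F_sire (known parent)")),
    "a-aa" = , "a-agg" = , "a-gga" = , "a-gggg" =
      8 / (2 - chk(F_sire, "F_sire") - chk(F_dam, "F_dam")),
    "g-a" = , "g-gg" = 2 / (1 - chk(F_parent, "F_parent")),
    "g-0" = 1,
    abort_input(sprintf("unknown case label '%s'", case))
  )
}

#' Direct sparse inverse of the generalized gametic relationship matrix
#'
#' Builds `Gbar^-1` from the pedigree alone, without ever forming `Gbar`,
#' by accumulating one rank-1 contribution `u_i u_i' delta_i` per genetic
#' effect (the factorization `Gbar^-1 = (T')^-1 D^-1 T^-1`). The result is
#' order-independent and equals the dense inverse of [generalized_matrix()]
#' for any valid pedigree. Special cases: an all-`ta` pedigree gives
#' `(A/2)^-1 = 2 A^-1`, an all-`gametic` pedigree the classical gametic
#' inverse.
#'
#' @param ped A pedigree.
#' @param order Optional permutation of the slot processing order (testing
#'   hook; the accumulated sum does not depend on it).
#' @return A symmetric sparse [Matrix::Matrix] (class `dsCMatrix`) of
#'   dimension m, with slot labels as dimnames and the slot table in
#'   `attr(, "slots")`.
#' @export
generalized_inverse <- function(ped, order = NULL) {
  ped <- as_pedigree(ped)
  slots <- effect_slots(ped)
  m <- nrow(slots)
  if (m == 0L) {
    out <- Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(), dims = c(0L, 0L)))
    attr(out, "slots") <- slots
    return(out)
  }
  Fi <- inbreeding(ped)$F
  names(Fi) <- ped$id
  ## slot indices of each individual's effect(s), in slot order
  slot_of <- split(slots$slot, factor(slots$id, levels = ped$id))
  si <- match(slots$id, ped$id)
  sire <- ped$sire[si]
  dam <- ped$dam[si]

  proc <- if (is.null(order)) seq_len(m) else order
  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  for (k in proc) {
    case <- slots$case[k]
    is_ta <- slots$kind[k] == "ta"
    par_id <- if (is_ta) NULL else if (slots$kind[k] == "pat") sire[k] else dam[k]
    cv <- if (is_ta) {
      contribution_vector(case, slots$slot[k],
                          sire = if (!is.na(sire[k])) slot_of[[sire[k]]],
                          dam = if (!is.na(dam[k])) slot_of[[dam[k]]])
    } else {
      contribution_vector(case, slots$slot[k],
                          parent = if (!is.na(par_id)) slot_of[[par_id]])
    }
    delta <- mendelian_delta(
      case,
      F_sire = if (!is_ta || is.na(sire[k])) NULL else unname(Fi[sire[k]]),
      F_dam = if (!is_ta || is.na(dam[k])) NULL else unname(Fi[dam[k]]),
      F_parent = if (is_ta || is.na(par_id)) NULL else unname(Fi[par_id])
    )
    n <- nrow(cv)
    ii[[k]] <- rep(cv$slot, each = n)
    jj[[k]] <- rep(cv$slot, times = n)
    xx[[k]] <- as.vector(outer(cv$coef, cv$coef)) * delta
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(m, m),
                            dimnames = list(slots$label, slots$label))
  out <- Matrix::forceSymmetric(M, uplo = "L")
  attr(out, "slots") <- slots
  out
}

#' Write / read a sparse inverse in GIV triplet format
#'
#' Lower-triangle text triplets, 1-based indices, one `row col value` line
#' per nonzero with `row >= col`, sorted by row then column, 12 significant
#' digits. A comment header maps slot index to individual id and slot kind,
#' compatible with the "GIV" files consumed by common REML packages.
#'
#' @param M Symmetric (sparse) matrix, e.g. from [generalized_inverse()].
#' @param path Output path.
#' @param slots Slot table for the header (defaults to `attr(M, "slots")`).
#' @return The path ([write_giv()]); a list with `matrix` (dsCMatrix) and
#'   `slots` tibble ([read_giv()]).
#' @export
write_giv <- function(M, path, slots = attr(M, "slots")) {
  Tm <- Matrix::tril(methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix"))
  ord <- order(Tm@i, Tm@j)
  lines <- character(0)
  if (!is.null(slots)) {
    lines <- sprintf("# %d %s %s", slots$slot, slots$id, slots$kind)
  }
  lines <- c(lines, sprintf("%d %d %.12g", Tm@i[ord] + 1L, Tm@j[ord] + 1L,
                            Tm@x[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_giv
#' @export
read_giv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, "#")
  slots <- NULL
  if (any(hdr)) {
    parts <- do.call(rbind, strsplit(sub("^#\\s*", "", lines[hdr]), "\\s+"))
    slots <- tibble::tibble(slot = as.integer(parts[, 1]), id = parts[, 2],
                            kind = parts[, 3])
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
  x <- as.numeric(parts[, 3])
  m <- max(i, j, 0L)
  M <- Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, m)), uplo = "L")
  if (!is.null(slots)) {
    lab <- ifelse(slots$kind == "ta", slots$id, paste0(slots$id, ".", slots$kind))
    dimnames(M) <- list(lab, lab)
  }
  list(matrix = M, slots = slots)
}
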