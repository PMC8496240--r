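#' Additive (numerator) relationship matrix
#'
#' Dense tabular recursion over the sorted pedigree: for individual i with
#' parents s, d the row is `A[i, ] = (A[s, ] + A[d, ]) / 2` over earlier
#' individuals and `A[i, i] = 1 + A[s, d] / 2`; unknown parents contribute
#' zero. The diagonal is `1 + F`.
#'
#' Dense constructions here are reference code, O(t^2) in memory, guarded by
#' `max_t`; for large pedigrees the production path is the direct sparse
#' inverse ([generalized_inverse()]), which never forms a dense matrix.
#'
#' @param ped A pedigree.
#' @param max_t Size guard (default 10000 for A, 2000 for the 2t x 2t
#'   matrices downstream).
#' @return A t x t matrix with dimnames = ids, in pedigree order.
#' @export
numerator_matrix <- function(ped, max_t = 10000L) {
  ped <- as_pedigree(ped)
  t <- nrow(ped)
  check_size(t, max_t, "numerator_matrix")
  A <- matrix(0, t, t, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(t)) {
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (!is.na(si[i])) row <- row + 0.5 * A[si[i], prev]
    if (!is.na(di[i])) row <- row + 0.5 * A[di[i], prev]
    A[i, prev] <- row
    A[prev, i] <- row
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * A[si[i], di[i]] else 0
  }
  A
}

#' Classical gametic relationship matrix
#'
#' The 2t x 2t covariance matrix of per-gamete additive effects, two slots
#' per individual (paternal gamete first). Recursion in pedigree order: a
#' gamete inherited from a known parent p has covariance with any earlier
#' slot x equal to the average of p's two slots' covariances with x; its own
#' variance is 1, and the covariance between an individual's own two gametes
#' equals its inbreeding coefficient (the parents' coancestry). Founder
#' gametes are mutually uncorrelated.
#'
#' @inheritParams numerator_matrix
#' @return A 2t x 2t matrix, dimnames `id.pat` / `id.mat`.
#' @export
gametic_matrix <- function(ped, max_t = 2000L) {
  ped <- as_pedigree(ped)
  t <- nrow(ped)
  check_size(t, max_t, "gametic_matrix")
  lab <- as.vector(rbind(paste0(ped$id, ".pat"), paste0(ped$id, ".mat")))
  G <- matrix(0, 2L * t, 2L * t, dimnames = list(lab, lab))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(t)) {
    for (k in 1:2) {
      r <- 2L * (i - 1L) + k
      p <- if (k == 1L) si[i] else di[i]
      if (!is.na(p)) {
        prev <- seq_len(r - 1L)
        row <- 0.5 * (G[2L * p - 1L, prev] + G[2L * p, prev])
        G[r, prev] <- row
        G[prev, r] <- row
      }
      G[r, r] <- 1
    }
  }
  G
}

#' Transformation matrix from gametic slots to the generalized effect layout
#'
#' The m x 2t matrix K' that averages the two gametic slots of every
#' transmitting-ability individual (a row with two entries of 1/2) and keeps
#' the gametic slots of the rest (unit rows), so that `K' g = a` maps the
#' full gametic effect vector onto the mixed vector of transmitting
#' abilities and gametic effects. Rows follow [effect_slots()] order,
#' columns the paired gametic-slot order of [gametic_matrix()]. With all
#' individuals gametic K' is the 2t x 2t identity; with all transmitting
#' abilities it is `I_t %x% c(1/2, 1/2)`.
#'
#' @param ped A pedigree.
#' @return A sparse m x 2t [Matrix::Matrix] (rows sum to 1).
#' @export
transformation_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  slots <- effect_slots(ped, classify = FALSE)
  i_ind <- match(slots$id, ped$id)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  ta <- slots$kind == "ta"
  if (any(ta)) {
    rows <- c(rows, rep(slots$slot[ta], each = 2L))
    cols <- c(cols, as.vector(rbind(2L * i_ind[ta] - 1L, 2L * i_ind[ta])))
    vals <- c(vals, rep(0.5, 2L * sum(ta)))
  }
  if (any(!ta)) {
    rows <- c(rows, slots$slot[!ta])
    cols <- c(cols, 2L * i_ind[!ta] - ifelse(slots$kind[!ta] == "pat", 1L, 0L))
    vals <- c(vals, rep(1, sum(!ta)))
  }
  lab <- as.vector(rbind(paste0(ped$id, ".pat"), paste0(ped$id, ".mat")))
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nrow(slots), 2L * nrow(ped)),
                       dimnames = list(slots$label, lab))
}

#' Generalized gametic relationship matrix
#'
#' The m x m covariance matrix `Gbar = K' G K` of the mixed vector of
#' transmitting abilities (for `"ta"` individuals) and gametic effects (for
#' `"gametic"` individuals). Its blocks are half the numerator relationship
#' matrix among transmitting abilities, the classical gametic relationships
#' among gametic slots, and the transmitting-ability-by-gamete coancestries
#' in between. This is the dense reference construction; use
#' [generalized_inverse()] for the sparse inverse at scale.
#'
#' @inheritParams gametic_matrix
#' @return An m x m matrix with slot labels as dimnames.
#' @export
generalized_matrix <- function(ped, max_t = 2000L) {
  ped <- as_pedigree(ped)
  G <- gametic_matrix(ped, max_t = max_t)
  K <- transformation_matrix(ped)
  Gbar <- as.matrix(K %*% G %*% Matrix::t(K))
  dimnames(Gbar) <- list(rownames(K), rownames(K))
  Gbar
}

#' Write a labelled relationship matrix as TSV
#'
#' Triplet dump `row_label`, `col_label`, `value`; full matrix or lower
#' triangle only.
#'
#' @param M A matrix with dimnames.
#' @param path Output path.
#' @param lower Write the lower triangle only (default `TRUE`).
#' @export
write_relmat <- function(M, path, lower = TRUE) {
  M <- as.matrix(M)
  idx <- which(if (lower) lower.tri(M, diag = TRUE) else matrix(TRUE, nrow(M), ncol(M)),
               arr.ind = TRUE)
  out <- data.frame(row = rownames(M)[idx[, 1]], col = colnames(M)[idx[, 2]],
                    value = M[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_size <- function(t, max_t, what) {
  if (t > max_t) {
    abort_input(sprintf(
      "%s is dense reference code; pedigree size %d exceeds the guard (%d). Use the sparse direct inverse instead or raise max_t.",
      what, t, max_t))
  }
}
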