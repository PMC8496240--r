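#' Phased haplotype sets
#'
#' A `ggrm_haplotypes` object holds a 0/1 allele matrix with two haplotype
#' rows per individual (first row paternal where the parental origin is
#' known), a per-individual `ordered` flag, and marker allele frequencies.
#' Frequencies default to the column means over all haplotypes; supply
#' `freq` to use base-population frequencies instead.
#'
#' @param alleles Integer/numeric matrix (2t x p) of 0/1 allele indicators;
#'   row order is individual-major (haplotype 1 then 2).
#' @param ids Character vector of t individual ids.
#' @param ordered Logical vector of length t (`TRUE` = first haplotype is
#'   paternal), recycled if length 1.
#' @param freq Optional marker allele frequencies (length p, in `[0, 1]`).
#' @return A `ggrm_haplotypes` list with elements `alleles`, `ids`,
#'   `ordered`, `freq`.
#' @export
haplotype_set <- function(alleles, ids, ordered = TRUE, freq = NULL) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) %% 2L != 0L) {
    abort_input("odd number of haplotype rows; need exactly two per individual")
  }
  t <- nrow(alleles) / 2L
  if (length(ids) != t) abort_input("length(ids) must equal nrow(alleles) / 2")
  if (anyDuplicated(ids)) abort_input("duplicate individual ids in haplotype set")
  if (length(ordered) == 1L) ordered <- rep(ordered, t)
  if (anyNA(alleles) || !all(alleles %in% c(0, 1))) {
    abort_input("haplotype alleles must be 0/1 with no missing values (drop or impute markers upstream)")
  }
  if (is.null(freq)) freq <- colMeans(alleles)
  if (length(freq) != ncol(alleles) || any(freq < 0 | freq > 1)) {
    abort_input("freq must have one value in [0, 1] per marker")
  }
  if (is.null(colnames(alleles))) {
    colnames(alleles) <- paste0("m", seq_len(ncol(alleles)))
  }
  rownames(alleles) <- as.vector(rbind(paste0(ids, ".1"), paste0(ids, ".2")))
  structure(list(alleles = alleles, ids = as.character(ids),
                 ordered = stats::setNames(ordered, ids),
                 freq = stats::setNames(as.numeric(freq), colnames(alleles))),
            class = "ggrm_haplotypes")
}

#' Read / write haplotypes as TSV
#'
#' Format: a header line `id hap ordered <marker ids...>`, then one row per
#' haplotype: individual id, haplotype index (1/2), ordered flag (`O`/`U`),
#' and 0/1 allele calls.
#'
#' @param path File path.
#' @param freq Optional external allele frequencies (see [haplotype_set()]).
#' @return A `ggrm_haplotypes` ([read_haplotypes()]); the path, invisibly
#'   ([write_haplotypes()]).
#' @export
read_haplotypes <- function(path, freq = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) abort_input("haplotype TSV needs id, hap, ordered and >= 1 marker column")
  ids <- unique(df[[1L]])
  df <- df[order(match(df[[1L]], ids), df[[2L]]), , drop = FALSE]
  per <- table(df[[1L]])
  if (any(per != 2L)) {
    abort_input(sprintf("individual(s) without exactly two haplotype rows: %s",
                        paste(names(per)[per != 2L], collapse = ", ")))
  }
  alleles <- as.matrix(df[, -(1:3), drop = FALSE])
  ordered <- toupper(df[[3L]][seq(1L, nrow(df), by = 2L)]) == "O"
  haplotype_set(alleles, ids, ordered, freq = freq)
}

#' @rdname read_haplotypes
#' @param h A `ggrm_haplotypes`.
#' @export
write_haplotypes <- function(h, path) {
  out <- data.frame(id = rep(h$ids, each = 2L),
                    hap = rep(1:2, length(h$ids)),
                    ordered = rep(ifelse(h$ordered, "O", "U"), each = 2L),
                    h$alleles, check.names = FALSE)
  colnames(out)[-(1:3)] <- colnames(h$alleles)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Biallelic markers only; genotypes of individuals flagged as ordered must
#' be phased (`|` separator, first allele paternal); unphased (`/`) calls
#' are accepted, with arbitrary within-individual order, for unordered
#' individuals. Markers with missing or non-biallelic calls are an error
#' unless `drop_bad_markers = TRUE`, which drops them with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @param ordered Character vector of ids whose first haplotype is paternal,
#'   or a logical vector over samples; default: all samples ordered.
#' @param drop_bad_markers Drop unsupported markers instead of erroring.
#' @param freq Optional external allele frequencies (after any dropping).
#' @return A `ggrm_haplotypes`.
#' @export
read_phased_vcf <- function(path, ordered = NULL, drop_bad_markers = FALSE,
                            freq = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- colnames(gt)
  if (is.null(ordered)) ordered <- rep(TRUE, length(ids))
  if (is.character(ordered)) ordered <- ids %in% ordered
  bad <- matrix(!grepl("^[01][|/][01]$", gt) | is.na(gt), nrow = nrow(gt))
  bad_marker <- rowSums(bad) > 0
  alt <- vcfR::getALT(vcf)
  bad_marker <- bad_marker | is.na(alt) | grepl(",", alt)
  if (any(bad_marker)) {
    if (!drop_bad_markers) {
      abort_input(sprintf(
        "%d marker(s) with missing or non-biallelic calls (set drop_bad_markers = TRUE to drop them)",
        sum(bad_marker)))
    }
    rlang::warn(sprintf("dropped %d unsupported marker(s)", sum(bad_marker)))
    gt <- gt[!bad_marker, , drop = FALSE]
  }
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased[, ordered, drop = FALSE])) {
    j <- which(colSums(unphased[, ordered, drop = FALSE]) > 0)[1L]
    abort_input(sprintf("unphased genotype(s) for ordered individual '%s'",
                        ids[ordered][j]))
  }
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  alleles <- matrix(0L, nrow = 2L * length(ids), ncol = nrow(gt),
                    dimnames = list(NULL, rownames(gt)))
  alleles[seq(1L, by = 2L, length.out = length(ids)), ] <- t(h1)
  alleles[seq(2L, by = 2L, length.out = length(ids)), ] <- t(h2)
  haplotype_set(alleles, ids, ordered, freq = freq)
}

#' Centre haplotypes and compute the marker-variance scale
#'
#' Column j of the centred matrix C holds `allele - p_j`; the scale is
#' `s = sum_j p_j (1 - p_j)` (monomorphic markers contribute 0).
#'
#' @param h A `ggrm_haplotypes`.
#' @return A list with the centred 2t x p matrix `C`, the scale `s`, and
#'   the frequencies `freq` used.
#' @export
center_haplotypes <- function(h) {
  stopifnot(inherits(h, "ggrm_haplotypes"))
  C <- sweep(h$alleles, 2L, h$freq, "-")
  list(C = C, s = sum(h$freq * (1 - h$freq)), freq = h$freq)
}

#' Genomic gametic relationship matrix from phased haplotypes
#'
#' `Gg = C C' / s` over the 2t haplotype rows: the genomic analogue of the
#' classical gametic relationship matrix. Invariant to allele labelling and
#' marker order.
#'
#' @param h A `ggrm_haplotypes`.
#' @return A 2t x 2t matrix (haplotype labels as dimnames) with the scale
#'   in `attr(, "s")`.
#' @export
genomic_gametic_matrix <- function(h) {
  cs <- center_haplotypes(h)
  if (cs$s <= 0) abort_input("all markers monomorphic: scale s = 0")
  Gg <- tcrossprod(cs$C) / cs$s
  attr(Gg, "s") <- cs$s
  Gg
}

#' Generalized genomic gametic relationship matrix
#'
#' Collapses the two haplotype rows of individuals whose parental origin
#' cannot be ordered into their average, then forms the cross-product over
#' the mixed row set: `Gbar_g = K' Gg K`, the genomic counterpart of
#' [generalized_matrix()]. The average row does not depend on haplotype
#' order, so unordered information integrates cleanly with ordered
#' haplotypes.
#'
#' @param h A `ggrm_haplotypes`.
#' @param collapse Ids to collapse to averaged rows. Default: all unordered
#'   individuals. Every unordered individual must be collapsed (its row
#'   order is arbitrary); collapsing an ordered individual is allowed but
#'   discards information (warning).
#' @param method `"average"` (replace rows by means, then cross-product) or
#'   `"transform"` (explicit `K' Gg K`); both give the same matrix.
#' @return An m x m matrix (m = #collapsed + 2 #kept) with slot labels, the
#'   scale in `attr(, "s")` and the slot table in `attr(, "slots")`.
#' @export
generalized_genomic_matrix <- function(h, collapse = NULL,
                                       method = c("average", "transform")) {
  method <- match.arg(method)
  if (is.null(collapse)) collapse <- h$ids[!h$ordered]
  stray <- setdiff(collapse, h$ids)
  if (length(stray)) {
    abort_input(sprintf("unknown id(s) in collapse: %s", paste(stray, collapse = ", ")))
  }
  uncollapsed_unordered <- setdiff(h$ids[!h$ordered], collapse)
  if (length(uncollapsed_unordered)) {
    abort_input(sprintf(
      "unordered individual(s) must be collapsed: %s",
      paste(uncollapsed_unordered, collapse = ", ")))
  }
  collapsed_ordered <- intersect(collapse, h$ids[h$ordered])
  if (length(collapsed_ordered)) {
    rlang::warn(sprintf("collapsing %d ordered individual(s); phase information discarded",
                        length(collapsed_ordered)))
  }
  cs <- center_haplotypes(h)
  if (cs$s <= 0) abort_input("all markers monomorphic: scale s = 0")
  is_col <- h$ids %in% collapse
  kind <- unlist(lapply(is_col, function(cc) if (cc) "ta" else c("pat", "mat")),
                 use.names = FALSE)
  id_rep <- rep(h$ids, times = ifelse(is_col, 1L, 2L))
  slots <- tibble::tibble(slot = seq_along(id_rep), id = id_rep, kind = kind,
                          label = ifelse(kind == "ta", id_rep,
                                         paste0(id_rep, ".", kind)))
  if (method == "average") {
    rows <- matrix(0, nrow(slots), ncol(cs$C))
    for (k in seq_len(nrow(slots))) {
      i <- match(slots$id[k], h$ids)
      r1 <- 2L * i - 1L; r2 <- 2L * i
      rows[k, ] <- switch(slots$kind[k],
                          ta = 0.5 * (cs$C[r1, ] + cs$C[r2, ]),
                          pat = cs$C[r1, ],
                          mat = cs$C[r2, ])
    }
    Gbar <- tcrossprod(rows) / cs$s
  } else {
    t <- length(h$ids)
    i_ind <- match(slots$id, h$ids)
    ta <- slots$kind == "ta"
    rows_i <- c(rep(slots$slot[ta], each = 2L), slots$slot[!ta])
    cols_j <- c(as.vector(rbind(2L * i_ind[ta] - 1L, 2L * i_ind[ta])),
                2L * i_ind[!ta] - ifelse(slots$kind[!ta] == "pat", 1L, 0L))
    vals <- c(rep(0.5, 2L * sum(ta)), rep(1, sum(!ta)))
    K <- Matrix::sparseMatrix(i = rows_i, j = cols_j, x = vals,
                              dims = c(nrow(slots), 2L * t))
    Gg <- tcrossprod(cs$C) / cs$s
    Gbar <- as.matrix(K %*% Gg %*% Matrix::t(K))
  }
  dimnames(Gbar) <- list(slots$label, slots$label)
  attr(Gbar, "s") <- cs$s
  attr(Gbar, "slots") <- slots
  Gbar
}
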