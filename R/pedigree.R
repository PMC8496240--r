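#' Pedigrees with mixed effect representations
#'
#' A `ggrm_pedigree` is a tibble with one row per individual and columns
#' `id`, `sire`, `dam` (parent labels, `NA` = unknown) and `rep`, the
#' representation of the individual's genetic effects in the model:
#' `"ta"` for a single transmitting ability (half the breeding value) or
#' `"gametic"` for a pair of gametic effects (paternal and maternal gamete).
#' Rows are stored in topological order (parents before offspring); the
#' original input order is kept in the `"orig_order"` attribute for output
#' labelling.
#'
#' In pedigree files the representation column carries the codes `1`
#' (transmitting ability) and `2` (gametic pair) and unknown parents are
#' coded `0`; the label `0` is therefore reserved and not usable as an id.
#'
#' @param x A data frame with at least four columns: id, sire, dam and a
#'   representation code (`1`/`2` or `"ta"`/`"gametic"`). Extra columns
#'   (e.g. generation, litter, phenotype flags) are carried through.
#' @param auto_insert_parents If `TRUE` (default), parents that never appear
#'   as a row are inserted as unknown-parent founders with representation
#'   `"ta"`, with a warning. If `FALSE` a dangling parent is an error.
#' @return A `ggrm_pedigree` tibble, topologically sorted.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3), code = c(1, 1, 1, 2)
#' ))
#' ped_counts(ped)
#' @export
as_pedigree <- function(x, auto_insert_parents = TRUE) {
  if (inherits(x, "ggrm_pedigree")) return(x)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < 4L) {
    abort_input("a pedigree needs >= 4 columns (id, sire, dam, representation code)")
  }
  extra <- if (ncol(x) > 4L) x[, -(1:4), drop = FALSE] else NULL
  id <- trimws(as.character(x[[1L]]))
  sire <- trimws(as.character(x[[2L]]))
  dam <- trimws(as.character(x[[3L]]))
  rep_raw <- trimws(as.character(x[[4L]]))

  if (nrow(x) == 0L) {
    ped <- tibble::tibble(id = character(), sire = character(),
                          dam = character(), rep = character())
    return(new_pedigree(ped, character()))
  }

  rep <- dplyr::case_match(tolower(rep_raw),
    c("1", "ta", "a") ~ "ta",
    c("2", "gametic", "g") ~ "gametic",
    .default = NA_character_
  )
  if (anyNA(rep)) {
    bad <- which(is.na(rep))[1L]
    abort_input(sprintf(
      "unknown representation code '%s' in row %d (expected 1/ta or 2/gametic)",
      rep_raw[bad], bad))
  }
  sire[sire %in% c("0", "", "NA", ".")] <- NA_character_
  dam[dam %in% c("0", "", "NA", ".")] <- NA_character_
  if (any(id %in% c("0", "", NA))) {
    abort_input("'0', empty and NA are reserved for unknown parents, not usable as ids")
  }
  if (anyDuplicated(id)) {
    abort_input(sprintf("duplicate id(s): %s",
                        paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(id == sire, na.rm = TRUE) || any(id == dam, na.rm = TRUE)) {
    abort_input("an individual cannot be its own parent")
  }

  ped <- tibble::tibble(id = id, sire = sire, dam = dam, rep = rep)
  if (!is.null(extra)) ped <- dplyr::bind_cols(ped, tibble::as_tibble(extra))

  dangling <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(dangling)) {
    if (!auto_insert_parents) {
      abort_input(sprintf("parent(s) never defined as a record: %s",
                          paste(dangling, collapse = ", ")))
    }
    rlang::warn(sprintf(
      "%d parent(s) not in the pedigree inserted as unknown-parent founders (ta): %s",
      length(dangling), paste(dangling, collapse = ", ")))
    founders <- tibble::tibble(id = dangling, sire = NA_character_,
                               dam = NA_character_, rep = "ta")
    ped <- dplyr::bind_rows(founders, ped)
  }

  new_pedigree(ped_toposort(ped), id)
}

new_pedigree <- function(ped, orig_order) {
  attr(ped, "orig_order") <- orig_order
  class(ped) <- c("ggrm_pedigree", class(tibble::tibble()))
  ped
}

## Stable Kahn ordering: founders keep their relative input order, every
## parent ends up before its offspring. Cycles surface as a stalled queue.
ped_toposort <- function(ped) {
  t <- nrow(ped)
  if (t <= 1L) return(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(t)
  order_out <- integer(t)
  n_placed <- 0L
  while (n_placed < t) {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) {
      abort_input(sprintf("pedigree contains a cycle involving: %s",
                          paste(ped$id[!placed], collapse = ", ")))
    }
    order_out[n_placed + seq_along(ready)] <- ready
    placed[ready] <- TRUE
    n_placed <- n_placed + length(ready)
  }
  ped[order_out, , drop = FALSE]
}

#' Read or write a pedigree file
#'
#' Four columns (id, sire, dam, code) with `0` for unknown parents and the
#' representation code `1` (transmitting ability) or `2` (gametic pair);
#' comma- or whitespace-separated, optional header (auto-detected: a first
#' row whose fourth field is not `1`/`2` is taken as a header).
#'
#' @param path File path.
#' @param ... Passed to [as_pedigree()].
#' @return [read_pedigree()] a `ggrm_pedigree`; [write_pedigree()] the path,
#'   invisibly (rows in original input order, same 4-column format).
#' @export
read_pedigree <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(as_pedigree(data.frame(id = character(), sire = character(),
                                  dam = character(), code = character())))
  }
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "[[:space:]]+"
  fields <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    abort_input(sprintf("pedigree row %d has %d field(s), expected >= 4",
                        which(nf < 4L)[1L], min(nf)))
  }
  header <- !(fields[[1L]][4L] %in% c("1", "2"))
  if (header) fields <- fields[-1L]
  if (!length(fields)) {
    return(as_pedigree(data.frame(id = character(), sire = character(),
                                  dam = character(), code = character())))
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:4]))
  as_pedigree(data.frame(id = m[, 1], sire = m[, 2], dam = m[, 3],
                         code = m[, 4], stringsAsFactors = FALSE), ...)
}

#' @rdname read_pedigree
#' @param ped A `ggrm_pedigree`.
#' @param sep Field separator (default tab).
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  ped <- as_pedigree(ped)
  orig <- attr(ped, "orig_order")
  out <- ped[order(match(ped$id, orig)), c("id", "sire", "dam", "rep")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  out$rep <- ifelse(out$rep == "ta", "1", "2")
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pedigree size and effect counts
#'
#' @param ped A pedigree (anything [as_pedigree()] accepts).
#' @return A one-row tibble with `t` (individuals), `u` (transmitting-ability
#'   individuals), `v` (gametic-pair individuals) and `m = u + 2v`, the number
#'   of genetic-effect equations per expression pattern.
#' @export
ped_counts <- function(ped) {
  ped <- as_pedigree(ped)
  u <- sum(ped$rep == "ta")
  v <- sum(ped$rep == "gametic")
  tibble::tibble(t = nrow(ped), u = u, v = v, m = u + 2L * v)
}

#' Effect slot layout of a pedigree
#'
#' Expands the pedigree into its genetic-effect slots: one `"ta"` slot per
#' transmitting-ability individual and an adjacent `"pat"`/`"mat"` pair per
#' gametic individual, in pedigree order (paternal before maternal). The
#' total slot count is `m = u + 2v`.
#'
#' @param ped A pedigree.
#' @param classify If `TRUE` (default), add the inversion `case` label of
#'   every slot (see [classify_effects()]).
#' @return A tibble with columns `slot`, `id`, `kind` (`ta`/`pat`/`mat`),
#'   `label`, and optionally `case`.
#' @export
effect_slots <- function(ped, classify = TRUE) {
  ped <- as_pedigree(ped)
  n_slots <- ifelse(ped$rep == "ta", 1L, 2L)
  idx <- rep.int(seq_len(nrow(ped)), n_slots)
  kind <- unlist(lapply(seq_len(nrow(ped)), function(i) {
    if (ped$rep[i] == "ta") "ta" else c("pat", "mat")
  }), use.names = FALSE)
  if (!length(idx)) kind <- character()
  slots <- tibble::tibble(
    slot = seq_along(idx),
    id = ped$id[idx],
    kind = kind,
    label = ifelse(kind == "ta", ped$id[idx],
                   paste0(ped$id[idx], ".", kind))
  )
  if (classify && nrow(slots)) slots$case <- classify_effects(ped, slots)
  slots
}

#' Classify genetic effects into the 12 direct-inversion cases
#'
#' Every effect slot falls into one of 12 cases determined by its own kind
#' (transmitting ability `a` or gametic effect `g`) and the status of the
#' relevant parent(s): unknown (`0`), represented by a transmitting ability
#' (`a`), or by a gametic pair (`gg`). Transmitting abilities look at both
#' parents (sire status first): `a-00`, `a-0a`, `a-a0`, `a-0gg`, `a-gg0`,
#' `a-aa`, `a-agg`, `a-gga`, `a-gggg`. A gametic effect looks only at the
#' parent its gamete derives from: `g-0`, `g-a`, `g-gg`.
#'
#' @param ped A pedigree.
#' @param slots Slot table from [effect_slots()] (computed if omitted).
#' @return Character vector of case labels, one per slot.
#' @export
classify_effects <- function(ped, slots = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(slots)) slots <- effect_slots(ped, classify = FALSE)
  status <- function(parent_id) {
    s <- rep("0", length(parent_id))
    j <- match(parent_id, ped$id)
    known <- !is.na(j)
    s[known] <- ifelse(ped$rep[j[known]] == "ta", "a", "gg")
    s
  }
  i <- match(slots$id, ped$id)
  ss <- status(ped$sire[i])
  ds <- status(ped$dam[i])
  ifelse(slots$kind == "ta",
         paste0("a-", ifelse(ss == "0", "0", ss), ifelse(ds == "0", "0", ds)),
         paste0("g-", ifelse(slots$kind == "pat", ss, ds)))
}

#' Inbreeding coefficients from a pedigree
#'
#' F of an individual equals the coancestry of its parents (half their
#' additive relationship); individuals with at least one unknown parent get
#' F = 0 under the assumption of unrelated, non-inbred founders. Computed by
#' the vectorised tabular recursion on the numerator relationship matrix
#' (see [numerator_matrix()]), guarded by `max_t` since it is O(t^2) in
#' memory.
#'
#' @param ped A pedigree.
#' @param max_t Size guard for the dense recursion (default 10000).
#' @return A tibble with columns `id` and `F`, in pedigree order.
#' @export
inbreeding <- function(ped, max_t = 10000L) {
  ped <- as_pedigree(ped)
  if (nrow(ped) == 0L) return(tibble::tibble(id = character(), F = numeric()))
  A <- numerator_matrix(ped, max_t = max_t)
  tibble::tibble(id = ped$id, F = unname(diag(A)) - 1)
}

#' Restrict a pedigree to the ancestors of a set of individuals
#'
#' Keeps `ids` and all their ancestors; everything else (e.g. phenotyped
#' final progeny represented through their parents by reduced observation
#' equations) is dropped from the effect set.
#'
#' @param ped A pedigree.
#' @param ids Individuals to keep (with their ancestors).
#' @return A pruned `ggrm_pedigree`.
#' @export
prune_pedigree <- function(ped, ids) {
  ped <- as_pedigree(ped)
  keep <- rep(FALSE, nrow(ped))
  keep[match(intersect(ids, ped$id), ped$id)] <- TRUE
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in rev(seq_len(nrow(ped)))) {   # rows sorted: one reverse sweep closes ancestry
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  new_pedigree(out, intersect(attr(ped, "orig_order"), out$id))
}

#' Recode the representation column of a pedigree
#'
#' @param ped A pedigree.
#' @param gametic Ids to represent by gametic pairs; all others become
#'   transmitting abilities. Use `gametic = ped$id` for a classical gametic
#'   model and `gametic = character()` for a pure transmitting-ability
#'   (numerator-relationship) model.
#' @return The recoded `ggrm_pedigree`.
#' @export
set_representation <- function(ped, gametic) {
  ped <- as_pedigree(ped)
  ped$rep <- ifelse(ped$id %in% gametic, "gametic", "ta")
  ped
}

abort_input <- function(msg) {
  rlang::abort(msg, class = "ggrm_input_error")
}
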