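#' Simulation configuration
#'
#' Settings for generating a multi-generation pedigree with litters, true
#' variance components, and phenotyping structure that mimics routine
#' parent-of-origin data: discrete generations, full-sib litters, records
#' mostly on final progeny, phenotyped individuals represented by gametic
#' pairs and everybody else by transmitting abilities.
#'
#' @param n_founders Number of unrelated founders (generation 0).
#' @param n_generations Number of offspring generations.
#' @param n_matings Matings (litters) per generation.
#' @param litter_mean Mean litter size (sizes are `1 + Poisson(litter_mean - 1)`).
#' @param mating `"random"` or `"sib_avoid"` (no full-sib matings).
#' @param prop_phenotyped Probability that an eligible individual has a
#'   record.
#' @param phen_generations Number of final generations eligible for
#'   phenotyping (default 1: final progeny only).
#' @param representation `"auto"` (phenotyped => gametic pair, others
#'   transmitting ability), `"all_gametic"` or `"all_ta"`.
#' @param vc True [variance_components()].
#' @param mu Overall mean of the trait.
#' @param seed Random seed for [sim_pedigree()] (the other stages take
#'   their own seeds so each can be regenerated independently).
#' @return A `ggrm_sim_config` list.
#' @export
sim_config <- function(n_founders = 40L, n_generations = 4L, n_matings = 40L,
                       litter_mean = 5, mating = c("random", "sib_avoid"),
                       prop_phenotyped = 1, phen_generations = 1L,
                       representation = c("auto", "all_gametic", "all_ta"),
                       vc = variance_components(1, 1, 0.5, 1),
                       mu = 10, seed = 1L) {
  mating <- match.arg(mating)
  representation <- match.arg(representation)
  if (n_founders < 2L || n_matings < 1L || litter_mean < 1 ||
      prop_phenotyped < 0 || prop_phenotyped > 1) {
    abort_input("invalid simulation configuration")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_matings = as.integer(n_matings),
                 litter_mean = litter_mean, mating = mating,
                 prop_phenotyped = prop_phenotyped,
                 phen_generations = as.integer(phen_generations),
                 representation = representation, vc = vc, mu = mu,
                 seed = as.integer(seed)),
            class = "ggrm_sim_config")
}

#' Simulate a pedigree with litters
#'
#' Discrete generations: each generation draws `n_matings` sire/dam pairs
#' from the previous generation (optionally avoiding full-sib matings) and
#' each mating produces one full-sib litter. Phenotype flags and
#' representation codes follow the configuration.
#'
#' @param cfg A [sim_config()].
#' @return A `ggrm_pedigree` with extra columns `generation`, `litter`,
#'   `sex` and `phenotyped`.
#' @export
sim_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "ggrm_sim_config"))
  set.seed(cfg$seed)
  id <- seq_len(cfg$n_founders)
  gen <- rep(0L, cfg$n_founders)
  sire <- rep(NA_integer_, cfg$n_founders)
  dam <- rep(NA_integer_, cfg$n_founders)
  sex <- rep(c("M", "F"), length.out = cfg$n_founders)
  litter <- rep(NA_integer_, cfg$n_founders)
  next_id <- cfg$n_founders + 1L
  next_litter <- 1L
  for (g in seq_len(cfg$n_generations)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) {
      abort_input(sprintf("generation %d has no available %s", g - 1L,
                          if (!length(males)) "sires" else "dams"))
    }
    for (k in seq_len(cfg$n_matings)) {
      for (try in 1:100) {
        s <- males[sample.int(length(males), 1L)]
        d <- females[sample.int(length(females), 1L)]
        full_sibs <- !is.na(sire[s]) && !is.na(sire[d]) &&
          sire[s] == sire[d] && dam[s] == dam[d]
        if (cfg$mating == "random" || !full_sibs) break
        if (try == 100L) abort_input("mating constraints infeasible")
      }
      size <- 1L + stats::rpois(1L, max(cfg$litter_mean - 1, 0))
      kids <- next_id:(next_id + size - 1L)
      id <- c(id, kids)
      gen <- c(gen, rep(g, size))
      sire <- c(sire, rep(s, size))
      dam <- c(dam, rep(d, size))
      sex <- c(sex, sample(c("M", "F"), size, replace = TRUE))
      litter <- c(litter, rep(next_litter, size))
      next_id <- next_id + size
      next_litter <- next_litter + 1L
    }
  }
  phen_eligible <- gen > cfg$n_generations - cfg$phen_generations & gen > 0L
  phenotyped <- phen_eligible &
    stats::runif(length(id)) < cfg$prop_phenotyped
  code <- switch(cfg$representation,
                 auto = ifelse(phenotyped, 2L, 1L),
                 all_gametic = 2L, all_ta = 1L)
  as_pedigree(data.frame(id = id, sire = ifelse(is.na(sire), 0L, sire),
                         dam = ifelse(is.na(dam), 0L, dam), code = code,
                         generation = gen, litter = litter, sex = sex,
                         phenotyped = phenotyped))
}

## Symmetric square root for (possibly semidefinite) 2x2 covariances.
sigma_sqrt <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Gene-drop bivariate gametic effects through a pedigree
#'
#' Founder gametes draw i.i.d. bivariate normal (effect as sire, effect as
#' dam) pairs with covariance `Sigma`; a non-founder gamete is the average
#' of its parent's two gametes plus a Mendelian sampling deviate with
#' covariance `(1 - F_parent)/2 * Sigma`. The population covariance of the
#' resulting 2t effects is `Sigma %x% G` with G the classical gametic
#' relationship matrix.
#'
#' @param ped A pedigree.
#' @param Sigma 2x2 gametic covariance (`[[sigma_s2, sigma_sd], [sigma_sd,
#'   sigma_d2]]`), PSD.
#' @param seed Random seed.
#' @return A tibble with one row per gamete: `id`, `origin` (`pat`/`mat`),
#'   `effect_s`, `effect_d`, `mendelian_s`, `mendelian_d`.
#' @export
sim_gene_drop <- function(ped, Sigma, seed = 1L) {
  ped <- as_pedigree(ped)
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) abort_input("Sigma must be PSD")
  set.seed(seed)
  t <- nrow(ped)
  Fi <- inbreeding(ped)$F
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  L1 <- sigma_sqrt(Sigma)
  E <- matrix(0, 2L * t, 2L)
  MS <- matrix(0, 2L * t, 2L)
  for (i in seq_len(t)) {
    for (k in 1:2) {
      r <- 2L * (i - 1L) + k
      p <- if (k == 1L) si[i] else di[i]
      if (is.na(p)) {
        E[r, ] <- MS[r, ] <- as.vector(L1 %*% stats::rnorm(2L))
      } else {
        Lms <- sigma_sqrt(0.5 * (1 - Fi[p]) * Sigma)
        MS[r, ] <- as.vector(Lms %*% stats::rnorm(2L))
        E[r, ] <- 0.5 * (E[2L * p - 1L, ] + E[2L * p, ]) + MS[r, ]
      }
    }
  }
  tibble::tibble(id = rep(ped$id, each = 2L),
                 origin = rep(c("pat", "mat"), t),
                 effect_s = E[, 1L], effect_d = E[, 2L],
                 mendelian_s = MS[, 1L], mendelian_d = MS[, 2L])
}

#' Simulate phenotypes under the imprinting observation model
#'
#' `y = mu (+ generation effect) + paternal-gamete effect as sire +
#' maternal-gamete effect as dam (+ litter effect) + residual` for every
#' phenotyped individual.
#'
#' @param ped A pedigree (with `phenotyped` and optionally `generation`,
#'   `litter` columns; without a `phenotyped` column all individuals get a
#'   record).
#' @param effects Gametic effect table from [sim_gene_drop()].
#' @param vc True [variance_components()] (`sigma_e2`, optional
#'   `sigma_c2`).
#' @param mu Overall mean.
#' @param generation_effects Optional named numeric vector of fixed
#'   generation effects.
#' @param seed Random seed.
#' @return A tibble `id`, `y` plus `generation` / `litter` columns when
#'   present in the pedigree.
#' @export
sim_phenotypes <- function(ped, effects, vc, mu = 0,
                           generation_effects = NULL, seed = 1L) {
  ped <- as_pedigree(ped)
  set.seed(seed)
  who <- if ("phenotyped" %in% names(ped)) ped$id[ped$phenotyped] else ped$id
  if (!length(who)) abort_input("no phenotyped individuals")
  pat <- effects[effects$origin == "pat", ]
  mat <- effects[effects$origin == "mat", ]
  g_s <- pat$effect_s[match(who, pat$id)]
  g_d <- mat$effect_d[match(who, mat$id)]
  if (anyNA(g_s) || anyNA(g_d)) {
    abort_input("effects table does not cover all phenotyped individuals")
  }
  y <- mu + g_s + g_d
  out <- tibble::tibble(id = who, y = y)
  i <- match(who, ped$id)
  if ("generation" %in% names(ped)) {
    out$generation <- ped$generation[i]
    if (!is.null(generation_effects)) {
      out$y <- out$y + generation_effects[as.character(out$generation)]
    }
  }
  if ("litter" %in% names(ped)) {
    out$litter <- ped$litter[i]
    if (!is.null(vc$sigma_c2) && vc$sigma_c2 > 0) {
      lev <- unique(out$litter)
      ce <- stats::rnorm(length(lev), 0, sqrt(vc$sigma_c2))
      out$y <- out$y + ce[match(out$litter, lev)]
    }
  }
  out$y <- out$y + stats::rnorm(nrow(out), 0, sqrt(vc$sigma_e2))
  out
}

#' Gene-drop biallelic markers through a pedigree
#'
#' Founder haplotypes draw alleles `Bernoulli(p_j)` per marker; a
#' non-founder gamete copies, independently per marker, one of the parent's
#' two alleles (free recombination). Parental origin is tracked, so all
#' individuals are flagged ordered.
#'
#' @param ped A pedigree.
#' @param n_markers Number of markers.
#' @param freq Founder allele frequencies: scalar, length-`n_markers`
#'   vector, or range `c(lo, hi)` to draw uniformly.
#' @param seed Random seed.
#' @return A [haplotype_set()] with the founder frequencies kept in
#'   `$founder_freq` (the set's own `freq` element holds realised sample
#'   frequencies, the default reference for centering).
#' @export
sim_haplotypes <- function(ped, n_markers, freq = c(0.05, 0.95), seed = 1L) {
  ped <- as_pedigree(ped)
  set.seed(seed)
  p <- if (length(freq) == 1L) rep(freq, n_markers)
       else if (length(freq) == n_markers) freq
       else stats::runif(n_markers, freq[1L], freq[2L])
  t <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  H <- matrix(0L, 2L * t, n_markers)
  for (i in seq_len(t)) {
    for (k in 1:2) {
      r <- 2L * (i - 1L) + k
      par <- if (k == 1L) si[i] else di[i]
      if (is.na(par)) {
        H[r, ] <- as.integer(stats::runif(n_markers) < p)
      } else {
        pick <- stats::runif(n_markers) < 0.5
        H[r, ] <- ifelse(pick, H[2L * par - 1L, ], H[2L * par, ])
      }
    }
  }
  h <- haplotype_set(H, ped$id, ordered = TRUE)
  h$founder_freq <- stats::setNames(p, colnames(h$alleles))
  h
}
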