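# Shared fixtures: the 4-individual worked pedigree, random pedigree
# generation, and an independent recursive-kinship oracle.

p1_pedigree <- function() {
  as_pedigree(data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3),
                         code = c(1, 1, 1, 2)))
}

# The 5 x 5 generalized matrix of the worked pedigree (slots 1, 2, 3,
# 4.pat, 4.mat); all entries quarters.
p1_gbar <- function() {
  matrix(c(2, 0, 1, 2, 1,
           0, 2, 1, 0, 1,
           1, 1, 2, 1, 2,
           2, 0, 1, 4, 1,
           1, 1, 2, 1, 4), 5, 5, byrow = TRUE) / 4
}

# Random pedigree with missing parents, both representation codes and
# multi-generation inbreeding (parents drawn from all earlier individuals).
random_pedigree <- function(t, seed, p_parent = 0.8, p_gametic = 0.5) {
  set.seed(seed)
  sire <- dam <- rep(0L, t)
  for (i in seq_len(t)) {
    if (i > 1L) {
      if (stats::runif(1) < p_parent) sire[i] <- sample.int(i - 1L, 1L)
      if (stats::runif(1) < p_parent) dam[i] <- sample.int(i - 1L, 1L)
    }
  }
  code <- 1L + (stats::runif(t) < p_gametic)
  as_pedigree(data.frame(id = seq_len(t), sire = sire, dam = dam, code = code))
}

# A hand-built pedigree whose effect slots realise all 12 inversion cases.
witness_pedigree <- function() {
  as_pedigree(data.frame(
    id   = c(1, 2, 11, 3, 4, 5, 6, 7, 8, 9, 10, 12, 13),
    sire = c(0, 0, 0,  0, 1, 0, 2, 1, 1, 2, 2,  1,  2),
    dam  = c(0, 0, 0,  1, 0, 2, 0, 3, 2, 1, 11, 3,  11),
    code = c(1, 2, 2,  1, 1, 1, 1, 1, 1, 1, 1,  2,  2)))
}

# Independent coancestry oracle: direct recursion on kinship coefficients,
# no matrix recursion shared with the package implementation.
kinship_oracle <- function(ped) {
  t <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  phi <- matrix(NA_real_, t, t)
  get <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + get(si[i], di[i]))
    } else if (i > j) {
      0.5 * (get(si[i], j) + get(di[i], j))
    } else {
      0.5 * (get(si[j], i) + get(di[j], i))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(t)) for (j in seq_len(i)) get(i, j)
  phi
}

# Small simulated data set for mixed-model tests.
sim_small <- function(seed, n_founders = 20L, n_generations = 2L,
                      n_matings = 15L, vc = variance_components(1, 1, 0.5, 1),
                      mu = 5, phen_generations = 1L) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_matings = n_matings, litter_mean = 4,
                    phen_generations = phen_generations, vc = vc, mu = mu,
                    seed = seed)
  ped <- sim_pedigree(cfg)
  eff <- sim_gene_drop(ped, matrix(c(vc$sigma_s2, vc$sigma_sd, vc$sigma_sd,
                                     vc$sigma_d2), 2), seed = seed + 1L)
  phen <- sim_phenotypes(ped, eff, vc, mu = mu, seed = seed + 2L)
  list(ped = ped, phen = phen, vc = vc, cfg = cfg)
}
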