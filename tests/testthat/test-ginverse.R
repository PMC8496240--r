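test_that("contribution vectors follow the per-case coefficient table", {
  cases <- list(
    list(case = "a-00", args = list(), coef = 1, at = 9),
    list(case = "a-0a", args = list(dam = 3), coef = c(-0.5, 1), at = c(3, 9)),
    list(case = "a-a0", args = list(sire = 2), coef = c(-0.5, 1), at = c(2, 9)),
    list(case = "a-0gg", args = list(dam = c(4, 5)), coef = c(-0.25, -0.25, 1),
         at = c(4, 5, 9)),
    list(case = "a-gg0", args = list(sire = c(1, 2)), coef = c(-0.25, -0.25, 1),
         at = c(1, 2, 9)),
    list(case = "a-aa", args = list(sire = 1, dam = 2), coef = c(-0.5, -0.5, 1),
         at = c(1, 2, 9)),
    list(case = "a-agg", args = list(sire = 1, dam = c(4, 5)),
         coef = c(-0.5, -0.25, -0.25, 1), at = c(1, 4, 5, 9)),
    list(case = "a-gga", args = list(sire = c(1, 2), dam = 3),
         coef = c(-0.25, -0.25, -0.5, 1), at = c(1, 2, 3, 9)),
    list(case = "a-gggg", args = list(sire = c(1, 2), dam = c(4, 5)),
         coef = c(-0.25, -0.25, -0.25, -0.25, 1), at = c(1, 2, 4, 5, 9)),
    list(case = "g-a", args = list(parent = 2), coef = c(-1, 1), at = c(2, 9)),
    list(case = "g-gg", args = list(parent = c(1, 2)), coef = c(-0.5, -0.5, 1),
         at = c(1, 2, 9)),
    list(case = "g-0", args = list(), coef = 1, at = 9)
  )
  for (cc in cases) {
    cv <- do.call(contribution_vector, c(list(case = cc$case, i = 9), cc$args))
    expect_equal(cv$coef, cc$coef, info = cc$case)
    expect_equal(cv$slot, cc$at, info = cc$case)
    expect_gte(nrow(cv), 1)
    expect_lte(nrow(cv), 5)
  }
  expect_error(contribution_vector("a-aa", 9, sire = 1),
               class = "ggrm_input_error")
  expect_error(contribution_vector("g-a", 9, parent = c(1, 2)),
               class = "ggrm_input_error")
  expect_error(contribution_vector("g-0", 9, sire = 1),
               class = "ggrm_input_error")
})

test_that("inverse Mendelian sampling variances match their five classes", {
  expect_equal(mendelian_delta("a-00"), 2)
  expect_equal(mendelian_delta("g-0"), 1)
  expect_equal(mendelian_delta("a-aa", F_sire = 0, F_dam = 0), 4)
  expect_equal(mendelian_delta("a-0a", F_dam = 0), 8 / 3)
  expect_equal(mendelian_delta("a-gg0", F_sire = 0.2), 8 / 2.8)
  expect_equal(mendelian_delta("g-a", F_parent = 0), 2)
  expect_equal(mendelian_delta("g-gg", F_parent = 0.5), 4)
  expect_equal(mendelian_delta("a-gggg", F_sire = 0.25, F_dam = 0.5), 8 / 1.25)
  expect_error(mendelian_delta("g-a", F_parent = 1), class = "ggrm_input_error")
  expect_error(mendelian_delta("a-aa", F_sire = 0), class = "ggrm_input_error")
})

test_that("one-known-parent and gametic deltas agree with the dense oracle", {
  # TA individual with a single known TA parent: (A/2)^-1 has diagonal 8/3
  two <- as_pedigree(data.frame(id = 1:2, sire = c(0, 1), dam = 0, code = 1))
  dense <- solve(generalized_matrix(two))
  expect_equal(unname(dense),
               matrix(c(8, -4, -4, 8), 2) / 3, tolerance = 1e-12)
  expect_equal(dense[2, 2], mendelian_delta("a-a0", F_sire = 0))
  # gamete from a known non-inbred gametic parent: diagonal contribution 2
  gg <- as_pedigree(data.frame(id = 1:2, sire = c(0, 1), dam = 0, code = 2))
  dense_g <- solve(generalized_matrix(gg))
  expect_equal(dense_g[3, 3], mendelian_delta("g-gg", F_parent = 0))
  # and from a TA parent
  ga <- as_pedigree(data.frame(id = 1:2, sire = c(0, 1), dam = 0,
                               code = c(1, 2)))
  expect_equal(solve(generalized_matrix(ga))[2, 2],
               mendelian_delta("g-a", F_parent = 0))
})

test_that("direct inverse reproduces the worked example and its documented dimensions", {
  Ginv <- generalized_inverse(p1_pedigree())
  expect_equal(unname(as.matrix(Ginv) %*% p1_gbar()), diag(5),
               tolerance = 1e-12)
  # 12 individuals, nine transmitting abilities + three gametic pairs -> 15
  ped12 <- random_pedigree(12, seed = 5)
  ped12 <- set_representation(ped12, gametic = ped12$id[c(3, 7, 11)])
  expect_equal(dim(generalized_inverse(ped12)), c(15L, 15L))
  single <- as_pedigree(data.frame(id = 1, sire = 0, dam = 0, code = 1))
  expect_equal(as.matrix(generalized_inverse(single)),
               matrix(2, dimnames = list("1", "1")))
})

test_that("direct inverse equals the dense inverse on random pedigrees", {
  for (seed in 1:40) {
    ped <- random_pedigree(sample(5:50, 1), seed = 500 + seed,
                           p_gametic = stats::runif(1))
    err <- max(abs(as.matrix(generalized_inverse(ped)) -
                     solve(generalized_matrix(ped))))
    expect_lt(err, 1e-9)
  }
})

test_that("accumulation order does not change the inverse", {
  ped <- random_pedigree(30, seed = 77)
  m <- ped_counts(ped)$m
  set.seed(1)
  ref <- as.matrix(generalized_inverse(ped))
  for (k in 1:3) {
    perm <- sample.int(m)
    expect_equal(as.matrix(generalized_inverse(ped, order = perm)), ref,
                 tolerance = 1e-12)
  }
})

test_that("special cases collapse to 2 A^-1 and the classical gametic inverse", {
  ped <- random_pedigree(30, seed = 13)
  all_ta <- set_representation(ped, gametic = character())
  expect_equal(unname(as.matrix(generalized_inverse(all_ta))),
               unname(2 * solve(numerator_matrix(all_ta))), tolerance = 1e-9)
  all_g <- set_representation(ped, gametic = ped$id)
  expect_equal(unname(as.matrix(generalized_inverse(all_g))),
               unname(solve(gametic_matrix(all_g))), tolerance = 1e-9)
})

test_that("every contribution is rank-1 PSD with one to five nonzeros", {
  args_for <- function(case) {
    switch(case,
      "a-00" = , "g-0" = list(),
      "a-0a" = list(dam = 3), "a-a0" = list(sire = 1),
      "a-0gg" = list(dam = c(3, 4)), "a-gg0" = list(sire = c(1, 2)),
      "a-aa" = list(sire = 1, dam = 3),
      "a-agg" = list(sire = 1, dam = c(3, 4)),
      "a-gga" = list(sire = c(1, 2), dam = 3),
      "a-gggg" = list(sire = c(1, 2), dam = c(3, 4)),
      "g-a" = list(parent = 1), "g-gg" = list(parent = c(1, 2)))
  }
  for (case in inversion_cases()) {
    cv <- do.call(contribution_vector, c(list(case = case, i = 9),
                                         args_for(case)))
    expect_gte(nrow(cv), 1)
    expect_lte(nrow(cv), 5)
    delta <- mendelian_delta(case, F_sire = 0.1, F_dam = 0.2, F_parent = 0.3)
    U <- outer(cv$coef, cv$coef) * delta
    ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-12)            # PSD
    expect_equal(sum(ev > 1e-12), 1L)     # rank 1
  }
  # the full accumulated inverse over a pedigree realising all 12 cases is PD
  Ginv <- generalized_inverse(witness_pedigree())
  expect_gt(min(eigen(as.matrix(Ginv), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("GIV files round-trip with sorted 1-based lower-triangle triplets", {
  ped <- random_pedigree(15, seed = 3)
  Ginv <- generalized_inverse(ped)
  f <- withr::local_tempfile()
  write_giv(Ginv, f)
  lines <- readLines(f)
  hdr <- sum(startsWith(lines, "#"))
  expect_equal(hdr, ped_counts(ped)$m)
  body <- do.call(rbind, strsplit(lines[!startsWith(lines, "#")], " "))
  i <- as.integer(body[, 1]); j <- as.integer(body[, 2])
  expect_true(all(i >= j))
  expect_true(all(diff(i) >= 0))
  back <- read_giv(f)
  expect_equal(as.matrix(back$matrix), as.matrix(Ginv), tolerance = 1e-10)
  expect_equal(back$slots$id, effect_slots(ped)$id)
})
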