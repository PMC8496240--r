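test_that("residual weights follow the composite-residual variance", {
  vc <- variance_components(1, 1, 0.5, 1)
  expect_equal(residual_weights("gametic", NA, NA, vc), 1)
  expect_equal(residual_weights("reduced", 0, 0, vc), 0.5)
  # fully inbred parents: Mendelian sampling terms vanish, weight 1
  expect_equal(residual_weights("reduced", 1 - 1e-12, 1 - 1e-12, vc), 1,
               tolerance = 1e-9)
  vc2 <- variance_components(2, 1, 0.5, 3)
  expect_equal(residual_weights("mixed_sire_ta", 0.2, 0.6, vc2),
               3 / (0.5 * 0.8 * 2 + 0.5 * 0.4 * 1 + 3))
})

test_that("variance components are validated", {
  expect_error(variance_components(-1, 1, 0, 1), class = "ggrm_input_error")
  expect_error(variance_components(1, 1, 1.5, 1), class = "ggrm_input_error")
  vc <- variance_components(2, 1, 0.5, 1)
  expect_equal(derived_parameters(vc)$sigma_i2, 2)
})

test_that("observation equations link the expected slots", {
  ped <- p1_pedigree()
  phen <- data.frame(id = "4", y = 1.0)
  d <- poe_design(ped, phen)
  expect_equal(d$obs$kind, "gametic")
  expect_equal(as.vector(d$Zs), c(0, 0, 0, 1, 0))  # own paternal slot
  expect_equal(as.vector(d$Zd), c(0, 0, 0, 0, 1))  # own maternal slot

  # recode 4 as transmitting ability: reduced equation on sire 1 and dam 3
  ped_ta <- set_representation(ped, gametic = character())
  d2 <- poe_design(ped_ta, phen)
  expect_equal(d2$obs$kind, "reduced")
  expect_equal(as.vector(d2$Zs), c(1, 0, 0, 0))
  expect_equal(as.vector(d2$Zd), c(0, 0, 1, 0))

  # mixed: sire gametic, dam transmitting ability
  ped_mix <- set_representation(ped, gametic = "1")
  d3 <- poe_design(ped_mix, phen)
  expect_equal(d3$obs$kind, "mixed_dam_ta")
  slots <- effect_slots(ped_mix)
  zs <- as.vector(d3$Zs)
  expect_equal(zs[slots$id == "1"], c(0.5, 0.5))
  expect_equal(as.vector(d3$Zd)[slots$label == "3"], 1)
})

test_that("designs reject unusable inputs", {
  ped <- p1_pedigree()
  expect_error(poe_design(ped, data.frame(id = "4", y = 1)[0, ]),
               "no records", class = "ggrm_input_error")
  expect_error(poe_design(ped, data.frame(id = "9", y = 1)),
               "not in the pedigree", class = "ggrm_input_error")
  # TA-represented founder cannot form a reduced equation
  ped_ta <- set_representation(ped, gametic = character())
  expect_error(poe_design(ped_ta, data.frame(id = "1", y = 1)),
               "unknown parent", class = "ggrm_input_error")
  expect_error(poe_design(ped, data.frame(id = "4", y = 1), fixed = ~0),
               "empty fixed-effect", class = "ggrm_input_error")
  expect_error(poe_design(ped, data.frame(id = "4", y = 1),
                          equations = "gametic") -> d_ok, NA)
  ped_mix <- set_representation(ped, gametic = c("1", "2", "3"))
  expect_error(poe_design(ped_mix, data.frame(id = "4", y = 1),
                          equations = "gametic"),
               "representation code 2", class = "ggrm_input_error")
})

test_that("generalized and classical gametic models are equivalent", {
  sim <- sim_small(seed = 61)
  vc <- variance_components(1, 1, 0.5, 1)
  d_gen <- poe_design(sim$ped, sim$phen)
  ped_cl <- set_representation(sim$ped, gametic = sim$ped$id)
  d_cl <- poe_design(ped_cl, sim$phen)
  for (v in list(vc, variance_components(2, 0.7, -0.3, 1.4))) {
    expect_equal(reml_loglik(d_gen, v), reml_loglik(d_cl, v),
                 tolerance = 1e-9)
  }
  b_gen <- poe_blup(d_gen, vc)
  b_cl <- poe_blup(d_cl, vc)
  expect_equal(b_gen$beta$estimate, b_cl$beta$estimate, tolerance = 1e-8)
  # transmitting abilities equal the averaged gametic pairs
  cmp <- dplyr::inner_join(b_gen$individuals, b_cl$individuals, by = "id")
  expect_equal(cmp$a_s.x, cmp$a_s.y, tolerance = 1e-8)
  expect_equal(cmp$a_d.x, cmp$a_d.y, tolerance = 1e-8)
})

test_that("reduced equations with matched weights give the same likelihood", {
  sim <- sim_small(seed = 67)
  vc <- variance_components(1.2, 0.9, 0.4, 1.1)
  d_gen <- poe_design(sim$ped, sim$phen)
  d_red <- suppressMessages(poe_design(sim$ped, sim$phen,
                                       equations = "reduced"))
  expect_lt(nrow(d_red$ped), nrow(d_gen$ped))  # final progeny pruned
  expect_equal(reml_loglik(d_red, vc), reml_loglik(d_gen, vc),
               tolerance = 1e-9)
})

test_that("the restricted likelihood obeys the scaling relation", {
  sim <- sim_small(seed = 71)
  d <- poe_design(sim$ped, sim$phen)
  vc <- variance_components(1, 1, 0.5, 1)
  l0 <- reml_loglik(d, vc)
  fac <- 3.3
  phen2 <- sim$phen
  phen2$y <- phen2$y * sqrt(fac)
  d2 <- poe_design(sim$ped, phen2)
  l1 <- reml_loglik(d2, variance_components(fac, fac, 0.5 * fac, fac))
  nstar <- d$n - d$p
  expect_equal(l1 - l0, -nstar / 2 * log(fac), tolerance = 1e-8)
})

test_that("perfect correlation removes all imprinting deviations", {
  sim <- sim_small(seed = 73)
  d <- poe_design(sim$ped, sim$phen)
  b <- poe_blup(d, variance_components(1, 1, 1 - 1e-10, 1))
  expect_lt(max(abs(b$individuals$poe_dev)), 1e-6)
  # the Mendelian fit enforces it exactly
  bm <- poe_blup(d, variance_components(1, 1, 1, 1), model = "mendelian")
  expect_true(all(bm$individuals$poe_dev == 0))
})

test_that("REML recovers sensible components and the null is calibrated", {
  sim <- sim_small(seed = 79, n_founders = 30, n_matings = 25,
                   phen_generations = 2L)
  d <- poe_design(sim$ped, sim$phen)
  fit <- fit_poe_reml(d)
  expect_true(fit$converged)
  expect_gt(fit$vc$sigma_e2, 0)
  expect_gte(derived_parameters(fit$vc)$sigma_i2, 0)
  fitm <- fit_poe_reml(d, model = "mendelian")
  expect_lte(fitm$logL, fit$logL + 1e-4)
  out <- rlrt(fit, fitm)
  expect_gte(out$statistic, 0)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  # tidiers
  td <- tidy(fit)
  expect_setequal(td$component,
                  c("sigma_s2", "sigma_d2", "sigma_sd", "sigma_e2"))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the likelihood-ratio statistic reproduces the reference log-likelihood arithmetic", {
  out1 <- rlrt(-17868.840, -17891.870)
  expect_equal(out1$statistic, 46.06, tolerance = 1e-10)
  expect_lt(out1$p_value, 1e-9)
  out2 <- rlrt(-17875.270, -17894.640)
  expect_equal(out2$statistic, 38.74, tolerance = 1e-10)
  expect_equal(rlrt(-10, -10)$statistic, 0)
  expect_equal(rlrt(-10, -10)$p_value, 1)
  expect_warning(out3 <- rlrt(-11, -10), "clipped")
  expect_equal(out3$statistic, 0)
})

test_that("derived parameters are internally consistent", {
  vc0 <- variance_components(1, 1, 1, 1)
  expect_equal(derived_parameters(vc0)$sigma_i2, 0)
  # a gametic-variance ratio of ~3.41 reproduces r = 0.819 with i2 = 0.314
  k2 <- 3.408
  vc1 <- variance_components(k2, 1, 0.819 * sqrt(k2), 1)
  dp <- derived_parameters(vc1)
  expect_equal(dp$r, 0.819, tolerance = 1e-6)
  expect_equal(dp$i2, 0.314, tolerance = 2e-3)
  vc2 <- variance_components(1, 0.8, 0.2, 1.5, 0.7)
  dp2 <- derived_parameters(vc2)
  expect_equal(dp2$sigma_p2, 1 + 0.8 + 1.5 + 0.7)
  expect_equal(dp2$h2, 1.8 / 4)
  expect_equal(dp2$c2, 0.7 / 4)
})

test_that("group (litter) variance enters the model", {
  vc <- variance_components(1, 1, 0.5, 1, sigma_c2 = 0.8)
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_matings = 15,
                    litter_mean = 4, vc = vc, mu = 5, seed = 83)
  ped <- sim_pedigree(cfg)
  eff <- sim_gene_drop(ped, matrix(c(1, .5, .5, 1), 2), seed = 84)
  phen <- sim_phenotypes(ped, eff, vc, mu = 5, seed = 85)
  d <- poe_design(ped, phen, group = "litter")
  expect_gt(d$q, 0)
  l_with <- reml_loglik(d, vc)
  expect_true(is.finite(l_with))
  b <- poe_blup(d, vc)
  expect_equal(length(b$group), d$q)
})
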