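test_that("abundance standardisation divides by effort then study maximum", {
  ab <- c(10, 5); eff <- c(1, 1); st <- c("s1", "s1")
  out <- standardise_and_rescale_abundance(ab, eff, st)
  expect_equal(out$rescaled, c(1, 0.5))
  # doubling abundance and effort together changes nothing
  out2 <- standardise_and_rescale_abundance(c(20, 5), c(2, 1), st)
  expect_equal(out2$rescaled, out$rescaled)
  # single nonzero site rescales to 1
  expect_equal(standardise_and_rescale_abundance(7, 2, "s")$rescaled, 1)
  # all-zero study flagged and left alone
  z <- standardise_and_rescale_abundance(c(0, 0), c(1, 1), c("z", "z"))
  expect_equal(z$flagged_studies, "z")
  expect_equal(z$rescaled, c(0, 0))
  expect_error(standardise_and_rescale_abundance(1, 0, "s"), "effort")
})

test_that("balanced Bray-Curtis components match hand evaluation", {
  h <- bc_balanced_dissimilarity(c(2, 0, 1), c(1, 1, 1))
  expect_equal(h$A, 2); expect_equal(h$B, 1); expect_equal(h$C, 1)
  expect_equal(h$d_bal, 1 / 3)
  # identical nonzero vectors: no dissimilarity
  same <- bc_balanced_dissimilarity(c(1, 2), c(1, 2))
  expect_equal(same$d_bal, 0); expect_equal(same$similarity, 1)
  # empty-site convention
  expect_equal(bc_balanced_dissimilarity(c(1, 2), c(0, 0))$similarity, 0)
  expect_error(bc_balanced_dissimilarity(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(bc_balanced_dissimilarity(c(1, 2), c(1, 1, 1)), "equal length")
  # symmetric, and never above the full Bray-Curtis dissimilarity
  set.seed(19)
  for (rep in 1:20) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    f <- bc_balanced_dissimilarity(x, y)
    g <- bc_balanced_dissimilarity(y, x)
    expect_equal(f$d_bal, g$d_bal)
    A <- sum(pmin(x, y)); B <- sum(x) - A; C <- sum(y) - A
    bc_full <- (B + C) / (2 * A + B + C)
    expect_lte(f$d_bal, bc_full + 1e-12)
  }
})

test_that("adjusted logit compresses, centres and inverts exactly", {
  expect_equal(logit_adjusted(0.5), 0)
  expect_equal(logit_adjusted(0), log(0.05 / 0.95))
  for (s in c(0, 0.1, 0.37, 0.5, 0.92, 1)) {
    expect_equal(inv_logit_adjusted(logit_adjusted(s)), s, tolerance = 1e-12)
  }
  expect_error(logit_adjusted(0.5, adj = 0.6), "adj")
})

test_that("Gower distance averages range-normalised differences", {
  rng <- c(a = 10, b = 5)
  s1 <- c(a = 0, b = 0); s2 <- c(a = 2, b = 3)
  expect_equal(gower_env_distance(s1, s2, rng), mean(c(0.2, 0.6)))
  expect_equal(gower_env_distance(s1, s1, rng), 0)
  expect_equal(gower_env_distance(s1, c(a = 10, b = 5), rng), 1)
  expect_equal(gower_env_distance(s1, s2, rng, cube_root = TRUE), 0.4^(1/3))
  expect_warning(gower_env_distance(s1, s2, c(a = 10, b = 0)), "zero-range")
})

test_that("BII arithmetic helpers match their defining formulas", {
  expect_equal(adjust_urban(1), 0.70)
  expect_equal(adjust_urban(0), 0)
  expect_equal(adjust_urban(0.9), 0.63)
  expect_equal(agroforestry_bii(0.9, 0.8, 0.7), 0.8)
  expect_equal(agroforestry_bii(0.6, 0.6, 0.6), 0.6)
  # hyper-intensive trajectory: start, plateau, midpoint
  expect_equal(hyper_intensive_bii(2037), 0.63)
  expect_equal(hyper_intensive_bii(2070), 0.50)
  expect_equal(hyper_intensive_bii(2080), 0.50)
  expect_equal(hyper_intensive_bii(2030), 0.63)
  expect_equal(hyper_intensive_bii(2053.5), 0.565)
  expect_error(hyper_intensive_bii(2040, c(2037, 0.5, 2070, 0.6)),
               "bii_end")
})

test_that("BII estimation recovers generator ground truth", {
  cls <- c("reference", "cropland", "pasture", "urban")
  ab_truth <- c(reference = 1, cropland = 0.6, pasture = 0.8, urban = 0.4)
  cs_truth <- c(reference = 1, cropland = 0.7, pasture = 0.85, urban = 0.55)
  pr <- generate_predicts_like(cls, n_studies = 30L, sites_per_study = 12L,
                               n_species = 40L, seed = 101L,
                               class_ab_truth = ab_truth,
                               class_cs_truth = cs_truth)
  est <- estimate_bii_coefficients(pr)
  expect_equal(est$bii[est$class == "reference"], 1)
  truth <- ab_truth * cs_truth
  for (cl in setdiff(cls, "reference")) {
    expect_lt(abs(est$bii[est$class == cl] - truth[[cl]]), 0.1)
  }
  # no degradation anywhere: every class estimates near 1
  pr0 <- generate_predicts_like(cls, n_studies = 30L, seed = 103L,
                                class_ab_truth = setNames(rep(1, 4), cls),
                                class_cs_truth = setNames(rep(1, 4), cls))
  est0 <- estimate_bii_coefficients(pr0)
  expect_true(all(abs(est0$bii - 1) < 0.1))
})

test_that("habitat condition maps apply BII per class and average slices", {
  tab <- default_bii_table()
  lu <- matrix("seminatural", 5, 3,
               dimnames = list(NULL, c(2020, 2030, 2040)))
  hm <- habitat_condition_map(lu, tab, slice = c(2020, 2040))
  expect_true(all(hm$yearly == 1))
  expect_equal(hm$slice_mean, rep(1, 5))

  # constant non-reference land use: slice mean equals the yearly value
  lu2 <- matrix("intensive_agriculture", 4, 3,
                dimnames = list(NULL, c(2020, 2030, 2040)))
  hm2 <- habitat_condition_map(lu2, tab, slice = c(2020, 2040))
  b_ia <- tab$bii[tab$class == "intensive_agriculture"]
  expect_equal(unique(as.numeric(hm2$yearly)), b_ia)
  expect_equal(hm2$slice_mean, rep(b_ia, 4))

  # dynamic class: slice mean is the mean of the per-year interpolations
  yrs <- seq(2060, 2080, by = 10)
  lu3 <- matrix("hyper_intensive_pastoral", 2, length(yrs),
                dimnames = list(NULL, yrs))
  hm3 <- habitat_condition_map(lu3, tab, slice = c(2060, 2080))
  expect_equal(hm3$slice_mean,
               rep(mean(hyper_intensive_bii(yrs)), 2))
  # slice mean always bounded by yearly extremes
  expect_true(all(hm3$slice_mean >= min(hm3$yearly) &
                    hm3$slice_mean <= max(hm3$yearly)))

  expect_error(habitat_condition_map(
    matrix("moonbase", 2, 1, dimnames = list(NULL, 2020)), tab),
    "moonbase")
})
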