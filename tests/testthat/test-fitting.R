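test_that("frequency tables validate their invariants", {
  ft <- frequency_table(list(t1 = c(a = 3, b = 7)))
  expect_equal(unname(ft$totals), 10)
  expect_error(frequency_table(list(t1 = c(a = -1, b = 2))), "nonnegative")
  expect_error(frequency_table(list(t1 = c(a = 1.5, b = 2))), "integers")
  expect_silent(frequency_table(list(t1 = c(a = 1.5, b = 2)), integer = FALSE))
  expect_error(frequency_table(list(t1 = c(1, 2))), "named")
})

test_that("frequency-table CSV round-trips", {
  b1 <- experiment_base_model("exp1")
  ft <- simulate_table(b1, recovery_truth(),
                       design_totals(experiment_design("exp1")), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_freq_csv(ft, f)
  ft2 <- read_freq_csv(f)
  for (tn in names(ft$counts))
    expect_equal(ft2$counts[[tn]][names(ft$counts[[tn]])], ft$counts[[tn]])
})

test_that("a saturated model reproduces the observed proportions exactly", {
  toy <- saturated_toy()
  expect_identical(degrees_of_freedom(toy), 0L)
  ft <- frequency_table(list(t = c(A = 30, B = 20, C = 50)))
  f <- fit_mpt(toy, ft, n_starts = 5, seed = 1)
  expect_lt(f$G2, 1e-8)
  p <- category_probabilities(toy, f$estimates)$t
  expect_equal(unname(p), c(0.3, 0.2, 0.5), tolerance = 1e-5)
  expect_true(is.na(f$p_value))
})

test_that("fitting an expected-value table recovers the parameters", {
  b1 <- experiment_base_model("exp1")
  truth <- recovery_truth()
  et <- expected_table(b1, truth, design_totals(experiment_design("exp1")))
  f <- fit_mpt(b1, et, n_starts = 5, seed = 2)
  expect_true(f$converged)
  expect_lt(f$G2, 1e-6)
  expect_equal(f$estimates, truth, tolerance = 1e-4)
  expect_equal(f$p_value, 1, tolerance = 1e-6)
})

test_that("fitted G2 beats an exhaustive 21-point grid search", {
  toy <- grid_toy_model()
  set.seed(9)
  th <- random_theta(toy, 0.2, 0.8)
  tot <- c(ad.high = 170, test.high = 170, new.high = 160)  # ~500 observations
  ft <- simulate_table(toy, th, tot, seed = 10)
  f <- fit_mpt(toy, ft, n_starts = 10, seed = 11)
  expect_true(f$converged)
  expect_lte(f$G2, grid_min_g2(toy, ft) + 1e-8)
})

test_that("fit results are internally consistent", {
  b1 <- experiment_base_model("exp1")
  ft <- simulate_table(b1, recovery_truth(),
                       design_totals(experiment_design("exp1")), seed = 12)
  f <- fit_mpt(b1, ft, n_starts = 10, seed = 13)
  expect_gte(f$G2, 0)
  expect_equal(f$p_value, pchisq(f$G2, f$df, lower.tail = FALSE))
  expect_true(all(f$estimates >= 0 & f$estimates <= 1))
  # G2 agrees with the oracle statistic at the estimates
  expect_equal(f$G2, oracle_g2(b1, f$estimates, ft), tolerance = 1e-8)
  # unidentifiable model refuses to fit
  expect_error(fit_mpt(two_source_model(), ft), "over-parameterised")
})

test_that("nested comparison behaves like a likelihood-ratio test", {
  b1 <- experiment_base_model("exp1")
  truth <- recovery_truth()
  tot <- design_totals(experiment_design("exp1"))
  ft <- simulate_table(b1, truth, tot, seed = 20)
  f <- fit_mpt(b1, ft, n_starts = 10, seed = 21)

  # fixing a parameter at its estimate costs (almost) nothing
  sub0 <- apply_restrictions(b1, restr_fix("b.high",
                                           unname(f$estimates["b.high"])))
  cmp0 <- compare_mpt(f, sub0, n_starts = 5, seed = 22)
  expect_lt(cmp0$delta_G2, 1e-4)
  expect_identical(cmp0$delta_df, 1L)

  # a real restriction never improves the fit
  sub <- hypothesis_submodel(b1, "g_ad_credibility", "exp1")
  cmp <- compare_mpt(f, sub, n_starts = 5, seed = 23)
  expect_gte(cmp$delta_G2, 0)
  expect_equal(cmp$p_value,
               pchisq(cmp$delta_G2, cmp$delta_df, lower.tail = FALSE))

  # non-nested pair is rejected: different restriction, not a refinement
  other <- apply_restrictions(two_source_model(),
                              list(restr_equal("b.high", "b.low")))
  expect_error(compare_mpt(f, other), "not nested")
})

test_that("delta G2 for a violated equality grows with sample size", {
  # deterministic check on expected-value tables: the generator has
  # g_ad.high != g_ad.low, so the misfit of the equality model scales ~ n
  b1 <- experiment_base_model("exp1")
  truth <- recovery_truth()           # g_ad .39 vs .61 across credibility
  sub <- hypothesis_submodel(b1, "g_ad_credibility", "exp1")
  deltas <- vapply(c(1e3, 1e4), function(n) {
    tot <- stats::setNames(rep(n, length(b1$trees)), names(b1$trees))
    et <- expected_table(b1, truth, tot)
    f <- fit_mpt(b1, et, n_starts = 5, seed = 30)
    compare_mpt(f, sub, n_starts = 5, seed = 31)$delta_G2
  }, numeric(1))
  expect_gt(deltas[2], 5 * deltas[1])
  expect_equal(deltas[2] / deltas[1], 10, tolerance = 0.05)
})

test_that("null-true delta G2(1) follows a chi-square(1) distribution", {
  b1 <- experiment_base_model("exp1")
  truth <- recovery_truth()
  truth[c("a_ad.high", "a_ad.low")] <- 0.5   # equality holds in the generator
  sub <- hypothesis_submodel(b1, "g_ad_credibility", "exp1")
  tot <- design_totals(experiment_design("exp1"))
  set.seed(40)
  deltas <- replicate(400, {
    ft <- simulate_table(b1, truth, tot)
    f <- fit_mpt(b1, ft, n_starts = 1, start = truth)
    compare_mpt(f, sub, n_starts = 1)$delta_G2
  })
  ks <- suppressWarnings(stats::ks.test(deltas, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("parametric bootstrap SEs are reproducible and scale with n", {
  b1 <- experiment_base_model("exp1")
  tot <- design_totals(experiment_design("exp1"))
  ft <- simulate_table(b1, recovery_truth(), tot, seed = 50)
  f <- fit_mpt(b1, ft, n_starts = 10, seed = 51)

  bs1 <- bootstrap_se(b1, ft, B = 25, seed = 52, fit = f)
  bs2 <- bootstrap_se(b1, ft, B = 25, seed = 52, fit = f)
  expect_identical(bs1$draws, bs2$draws)     # bit-reproducible under a seed
  expect_identical(bs1$se, bs2$se)
  expect_true(all(bs1$se >= 0))
  expect_identical(names(bs1$se), names(f$estimates))

  # doubling every per-tree total shrinks the median SE by about 1/sqrt(2)
  ft2 <- expected_table(b1, f$estimates, 2 * ft$totals)
  f2 <- fit_mpt(b1, ft2, n_starts = 5, seed = 53)
  bs_big <- bootstrap_se(b1, ft2, B = 150, seed = 54, fit = f2)
  bs_ref <- bootstrap_se(b1, ft, B = 150, seed = 55, fit = f)
  ratio <- stats::median(bs_big$se / bs_ref$se)
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.2)

  # parameters pinned to constants carry no SE
  fixed <- apply_restrictions(b1, restr_fix("b.high", 0.2))
  ffx <- fit_mpt(fixed, ft, n_starts = 5, seed = 56)
  bfx <- bootstrap_se(fixed, ft, B = 25, seed = 57, fit = ffx)
  expect_false("b.high" %in% names(bfx$se))
  expect_error(bootstrap_se(b1, ft, B = 1), "B >= 2")
})

test_that("a restricted model never fits better than its parent", {
  b1 <- experiment_base_model("exp1")
  tot <- design_totals(experiment_design("exp1"))
  set.seed(60)
  for (i in 1:5) {
    ft <- simulate_table(b1, random_theta(b1, 0.15, 0.85), tot)
    f <- fit_mpt(b1, ft, n_starts = 5)
    for (h in names(hypothesis_catalogue("exp1"))) {
      sub <- hypothesis_submodel(b1, h, "exp1")
      fr <- fit_mpt(sub, ft, n_starts = 5,
                    start = expand_theta(b1, f$estimates)[free_parameters(sub)])
      expect_gte(fr$G2, f$G2 - 1e-6)
    }
  }
})
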