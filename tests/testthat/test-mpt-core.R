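test_that("category probabilities match hand-derived branch sums", {
  m <- two_source_model(credibility = "high")
  fp <- free_parameters(m)

  # perfect detection and source memory: the correct source is certain
  th <- stats::setNames(rep(0.5, length(fp)), fp)
  th["D_ad.high"] <- 1; th["d_ad.high"] <- 1
  p <- category_probabilities(m, th)
  expect_equal(unname(p$ad.high[c("ad", "test", "new")]), c(1, 0, 0))

  # no detection, no old-guessing: everything is called new
  th0 <- stats::setNames(rep(0.5, length(fp)), fp)
  th0[c("D_ad.high", "D_test.high", "D_new.high", "b.high")] <- 0
  p0 <- category_probabilities(m, th0)
  for (tn in names(p0)) expect_equal(unname(p0[[tn]]["new"]), 1)

  # all relevant parameters at .5: P(ad | ad tree) = .25 + .125 + .125 = .5
  th5 <- stats::setNames(rep(0.5, length(fp)), fp)
  expect_equal(unname(category_probabilities(m, th5)$ad.high[["ad"]]), 0.5)
})

test_that("tree probabilities are normalised at random parameter values", {
  set.seed(42)
  for (m in list(two_source_model(), three_source_model())) {
    for (i in 1:1000) {
      p <- category_probabilities(m, random_theta(m))
      sums <- vapply(p, sum, numeric(1))
      expect_true(all(abs(sums - 1) < 1e-12))
      expect_true(all(unlist(p) >= 0))
    }
  }
})

test_that("category probabilities agree with the recursive tree-walk oracle", {
  set.seed(7)
  models <- list(
    two_source_model(), three_source_model(),
    experiment_base_model("exp1"), experiment_base_model("exp2"),
    experiment_base_model("exp2", "parsimonious")
  )
  for (m in models) {
    for (i in 1:100) {
      th <- random_theta(m)
      a <- category_probabilities(m, th)
      b <- oracle_probs(m, th)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("restrictions collapse the free-parameter list and recompute df", {
  m <- two_source_model()
  expect_identical(degrees_of_freedom(m), -4L)          # 12 cats - 16 params
  m1 <- two_source_model(credibility = "high")
  expect_identical(degrees_of_freedom(m1), -2L)         # 6 cats - 8 params

  b <- apply_restrictions(m, base_restrictions("exp1"))
  expect_length(free_parameters(b), 10)
  expect_identical(degrees_of_freedom(b), 2L)

  # idempotence: applying the same set again changes nothing
  b2 <- apply_restrictions(b, base_restrictions("exp1"))
  expect_identical(free_parameters(b2), free_parameters(b))
  expect_identical(degrees_of_freedom(b2), degrees_of_freedom(b))

  # empty set is the identity
  expect_identical(free_parameters(apply_restrictions(m, list())),
                   m$parameters)

  # saturated toy: one free parameter per free category
  expect_identical(degrees_of_freedom(saturated_toy()), 0L)
})

test_that("restriction conflicts and unknown names are rejected", {
  m <- two_source_model()
  expect_error(
    apply_restrictions(m, list(restr_fix("b.high", 0.2),
                               restr_fix("b.high", 0.3))),
    "conflict")
  # conflict through an equality class
  expect_error(
    apply_restrictions(m, list(restr_equal("b.high", "b.low"),
                               restr_fix("b.high", 0.2),
                               restr_fix("b.low", 0.3))),
    "conflict")
  expect_error(apply_restrictions(m, restr_equal("b.high", "nope")),
               "unknown parameter")
  expect_error(restr_fix("b.high", 1.2), "outside")
})

test_that("theta expansion validates names and ranges", {
  b <- experiment_base_model("exp1")
  th <- random_theta(b)
  expect_error(expand_theta(b, th[-1]), names(th)[1])
  bad <- th; bad[1] <- 1.5
  expect_error(expand_theta(b, bad), "\\[0, 1\\]")
  full <- expand_theta(b, th)
  expect_identical(names(full), b$parameters)
  expect_equal(unname(full["D_test.high"]), unname(th["D_ad.high"]))
  expect_equal(unname(full["g_ad.low"]), unname(th["a_ad.low"]))
})

test_that("local identifiability is diagnosed from the Jacobian rank", {
  r <- check_local_identifiability(experiment_base_model("exp1"))
  expect_identical(r$rank, 10L)
  expect_true(r$identifiable)

  r2 <- check_local_identifiability(two_source_model(credibility = "high"))
  expect_lt(r2$rank, r2$n_free)
  expect_false(r2$identifiable)

  toy <- mpt_model(list(mpt_tree("t", list(
    mpt_branch("A", "p"), mpt_branch("B", "p", TRUE)))))
  expect_identical(check_local_identifiability(toy)$rank, 1L)

  b <- experiment_base_model("exp1")
  th <- stats::setNames(rep(0.5, 10), free_parameters(b))
  th[1] <- 1
  expect_warning(check_local_identifiability(b, th), "boundary")
})

test_that("model-specification text format round-trips", {
  txt <- c("# toy one-high-threshold model",
           "old  hit   D",
           "old  hit   (1-D) * g",
           "old  miss  (1-D) * (1-g)",
           "new  miss  (1-D2)",
           "new  hit   D2",
           "restrict: D = D2",
           "set: g = 0.5")
  f <- withr::local_tempfile(fileext = ".mpt")
  writeLines(txt, f)
  m <- read_mpt_model(f)
  expect_identical(names(m$trees), c("old", "new"))
  expect_length(free_parameters(m), 1)      # D (=D2); g fixed
  p <- category_probabilities(m, c(D = 0.8))
  expect_equal(unname(p$old[["hit"]]), 0.8 + 0.2 * 0.5)
  expect_equal(unname(p$new[["miss"]]), 0.2)

  # bundled files reproduce the built-in models
  ext <- system.file("extdata", package = "mptsource")
  m1 <- read_mpt_model(file.path(ext, "exp1_two_source.mpt"),
                       file.path(ext, "exp1_base.restr"))
  b1 <- experiment_base_model("exp1")
  expect_identical(degrees_of_freedom(m1), degrees_of_freedom(b1))
  set.seed(1)
  th <- random_theta(b1)
  p1 <- category_probabilities(m1, th[free_parameters(m1)])
  pb1 <- category_probabilities(b1, th)
  for (tn in names(pb1))
    expect_equal(p1[[tn]][names(pb1[[tn]])], pb1[[tn]], tolerance = 1e-12)

  m2 <- read_mpt_model(file.path(ext, "exp2_three_source.mpt"),
                       file.path(ext, "exp2_final_base.restr"))
  expect_identical(degrees_of_freedom(m2), 10L)

  # write_mpt_model/read_mpt_model round trip preserves probabilities
  # (category order in the parsed model follows first appearance in the
  # file, so compare cell-wise by name)
  f2 <- withr::local_tempfile(fileext = ".mpt")
  bp <- experiment_base_model("exp2", "parsimonious")
  write_mpt_model(bp, f2)
  mp <- read_mpt_model(f2)
  thp <- random_theta(mp)
  pa <- category_probabilities(mp, thp)
  pb <- category_probabilities(bp, thp)
  for (tn in names(pb))
    expect_equal(pa[[tn]][names(pb[[tn]])], pb[[tn]], tolerance = 1e-12)
})
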