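# Independent oracles used across the suite.

# Brute-force recursive tree walk: category probabilities computed by
# descending each branch's factor list recursively, independent of the
# package's product/compiled implementations.
oracle_probs <- function(model, theta) {
  full <- expand_theta(model, theta)
  walk <- function(params, comp) {
    if (length(params) == 0) return(1)
    th <- full[[params[1]]]
    f <- if (comp[1]) 1 - th else th
    f * walk(params[-1], comp[-1])
  }
  lapply(model$trees, function(tr) {
    p <- stats::setNames(numeric(length(tr$response_categories)),
                         tr$response_categories)
    for (br in tr$branches)
      p[br$terminal] <- p[br$terminal] + walk(br$params, br$comp)
    p
  })
}

# G-squared of a model at free-parameter values theta against a frequency
# table, computed from the oracle probabilities.
oracle_g2 <- function(model, theta, data) {
  probs <- oracle_probs(model, theta)
  g2 <- 0
  for (tn in names(data$counts)) {
    f <- data$counts[[tn]]
    n <- sum(f)
    p <- pmax(probs[[tn]][names(f)], 1e-300)
    pos <- f > 0
    g2 <- g2 + 2 * sum(f[pos] * log(f[pos] / (n * p[pos])))
  }
  g2
}

# random free-parameter draw strictly inside (0,1)
random_theta <- function(model, lo = 0, hi = 1) {
  fp <- free_parameters(model)
  stats::setNames(stats::runif(length(fp), lo, hi), fp)
}

# tiny three-category saturated model: p -> A, (1-p)q -> B, (1-p)(1-q) -> C
saturated_toy <- function() {
  mpt_model(list(mpt_tree("t", list(
    mpt_branch("A", "p"),
    mpt_branch("B", c("p", "q"), c(TRUE, FALSE)),
    mpt_branch("C", c("p", "q"), c(TRUE, TRUE))
  ))))
}

# small identifiable two-source model with three free parameters (D, b, a),
# source memory pinned to a constant; used for grid-search cross-checks
grid_toy_model <- function(d_value = 0.35) {
  apply_restrictions(two_source_model(credibility = "high"), list(
    restr_equal("D_ad.high", "D_test.high", "D_new.high"),
    restr_equal("a_ad.high", "g_ad.high"),
    restr_equal("d_ad.high", "d_test.high"),
    restr_fix("d_ad.high", d_value)
  ))
}

# exhaustive grid search of G2 over the free parameters (21 points each)
grid_min_g2 <- function(model, data, points = seq(0, 1, length.out = 21)) {
  fp <- free_parameters(model)
  grid <- do.call(expand.grid, stats::setNames(
    rep(list(points), length(fp)), fp))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    th <- stats::setNames(as.numeric(grid[i, ]), fp)
    g2 <- oracle_g2(model, th, data)
    if (is.finite(g2) && g2 < best) best <- g2
  }
  best
}

# exp1 ground-truth free-parameter vector with all components well inside
# [.1, .9], used by the recovery and calibration simulations
recovery_truth <- function() {
  base <- experiment_base_model("exp1")
  th <- default_generative_params("exp1")$theta[free_parameters(base)]
  pmin(pmax(th, 0.1), 0.9)
}
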