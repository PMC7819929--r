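#' Observed response frequencies per tree
#'
#' The unit the multinomial likelihood consumes: a count for every
#' (tree, response category) cell.  Totals per tree are derived from the
#' counts.  Fractional counts are permitted only when `integer = FALSE`
#' (used for expected-value tables, see [expected_table()]).
#'
#' @param counts named list: one named numeric vector of category counts per
#'   tree.
#' @param integer require counts to be nonnegative integers.
#' @return an object of class `mpt_freq` with elements `counts` and
#'   `totals`.
#' @export
frequency_table <- function(counts, integer = TRUE) {
  stopifnot(is.list(counts), length(counts) > 0, !is.null(names(counts)))
  for (tn in names(counts)) {
    x <- counts[[tn]]
    if (is.null(names(x))) stop("counts for tree '", tn, "' must be named by category")
    if (any(!is.finite(x)) || any(x < 0))
      stop("counts for tree '", tn, "' must be finite and nonnegative")
    if (integer && any(abs(x - round(x)) > 1e-8))
      stop("counts for tree '", tn, "' must be integers")
  }
  structure(list(counts = counts,
                 totals = vapply(counts, sum, numeric(1))),
            class = "mpt_freq")
}

#' @export
print.mpt_freq <- function(x, ...) {
  cat("MPT frequency table:", length(x$counts), "trees,",
      sum(x$totals), "observations\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.mpt_freq <- function(x, ...) {
  do.call(rbind, lapply(names(x$counts), function(tn) {
    data.frame(tree = tn, category = names(x$counts[[tn]]),
               count = as.numeric(x$counts[[tn]]), row.names = NULL)
  }))
}

#' Read / write frequency tables as CSV
#'
#' The on-disk format has columns `credibility,tree,category,count`, where
#' `tree` is the item type (`ad`, `test`, `unknown`, `new`); in-memory trees
#' are keyed `<type>.<credibility>`.
#'
#' @param path CSV file path.
#' @return for `read_freq_csv()`: an [frequency_table()].
#' @export
read_freq_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("credibility", "tree", "category", "count")
  if (!all(need %in% names(df)))
    stop("frequency CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$tree, df$credibility, sep = ".")
  counts <- lapply(split(seq_len(nrow(df)), key), function(i)
    stats::setNames(df$count[i], df$category[i]))
  frequency_table(counts, integer = FALSE)
}

#' @rdname read_freq_csv
#' @param x an [frequency_table()].
#' @export
write_freq_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$credibility <- sub("^.*\\.", "", df$tree)
  df$tree <- sub("\\.[^.]*$", "", df$tree)
  utils::write.csv(df[, c("credibility", "tree", "category", "count")],
                   path, row.names = FALSE)
  invisible(path)
}

# align a frequency table with a compiled model: stacked count vector and
# per-category tree totals, in the compiled category order
align_freq <- function(cm, data) {
  trees <- unique(cm$cat_tree)
  missing <- setdiff(trees, names(data$counts))
  if (length(missing))
    stop("data lacks counts for tree(s): ", paste(missing, collapse = ", "))
  f <- numeric(cm$n_cat)
  for (i in seq_len(cm$n_cat)) {
    x <- data$counts[[cm$cat_tree[i]]]
    extra <- setdiff(names(x), cm$cat_label[cm$cat_tree == cm$cat_tree[i]])
    if (length(extra))
      stop("response category not in model tree '", cm$cat_tree[i], "': ",
           paste(extra, collapse = ", "))
    f[i] <- if (cm$cat_label[i] %in% names(x)) x[[cm$cat_label[i]]] else 0
  }
  n_tree <- vapply(split(f, cm$cat_tree), sum, numeric(1))[cm$cat_tree]
  if (any(n_tree <= 0)) stop("every tree must have a positive total count")
  list(f = f, n = n_tree)
}

# G-squared and its gradient w.r.t. the logit-scale free parameters
g2_objective <- function(cm) {
  n_free <- length(cm$free)
  function(eta, f, n, gradient = FALSE) {
    thf <- stats::plogis(eta)
    full <- ifelse(is.na(cm$map), cm$fixed, thf[cm$map])
    full <- pmin(pmax(full, 1e-12), 1 - 1e-12)
    pb <- exp(cm$A %*% log(full) + cm$B %*% log1p(-full))
    p <- numeric(cm$n_cat)
    agg <- rowsum(pb, cm$branch_cat)
    p[as.integer(rownames(agg))] <- agg
    pfl <- pmax(p, 1e-12)
    pos <- f > 0
    g2 <- 2 * sum(f[pos] * log(f[pos] / (n[pos] * pfl[pos])))
    if (!gradient) return(g2)
    dcat <- numeric(cm$n_cat)
    dcat[pos] <- -2 * f[pos] / pfl[pos]
    w <- dcat[cm$branch_cat] * pb
    dfull <- as.numeric(crossprod(cm$A, w)) / full -
             as.numeric(crossprod(cm$B, w)) / (1 - full)
    gfree <- vapply(seq_len(n_free), function(k)
      sum(dfull[!is.na(cm$map) & cm$map == k]), numeric(1))
    list(value = g2, gradient = gfree * thf * (1 - thf))
  }
}

#' Fit an MPT model by maximum likelihood
#'
#' Minimises the likelihood-ratio statistic
#' \deqn{G^2(\theta) = 2\sum_c f_c \log\frac{f_c}{n\,p_c(\theta)}}
#' (with the convention \eqn{0\log 0 = 0}) over the free parameters, which is
#' equivalent to maximising the multinomial log-likelihood.  Optimisation
#' runs on logit-transformed parameters (so the \[0, 1\] box constraints are
#' handled smoothly) with analytic gradients and multiple random starting
#' points; the best converged solution is returned.  The goodness-of-fit
#' p-value comes from the \eqn{\chi^2} survival function at the model's
#' degrees of freedom.
#'
#' @param model a restricted, identifiable [mpt_model()] (df >= 0).
#' @param data an [frequency_table()] whose trees match the model's.
#' @param n_starts number of random starting points.
#' @param seed optional seed for the random starts (global RNG state is
#'   preserved).
#' @param tol relative convergence tolerance on G-squared.
#' @param start optional named vector of free-parameter values used as the
#'   first starting point.
#' @param maxit maximum BFGS iterations per start.
#' @return an object of class `mpt_fit`: `estimates` (free parameters),
#'   `estimates_full` (all model parameters after restriction expansion),
#'   `G2`, `df`, `p_value`, `log_likelihood`, `converged`, `n_starts_used`,
#'   and `se` (`NULL` until [bootstrap_se()] is attached).
#' @export
fit_mpt <- function(model, data, n_starts = 20, seed = NULL, tol = 1e-9,
                    start = NULL, maxit = 500) {
  stopifnot(inherits(model, "mpt_model"), inherits(data, "mpt_freq"))
  df <- degrees_of_freedom(model)
  if (df < 0)
    stop("model is over-parameterised (df = ", df,
         "); add identifying restrictions before fitting")
  cm <- compile_mpt(model)
  al <- align_freq(cm, data)
  obj <- g2_objective(cm)
  fn <- function(eta) obj(eta, al$f, al$n)
  gr <- function(eta) obj(eta, al$f, al$n, gradient = TRUE)$gradient
  n_free <- length(cm$free)

  starts <- with_seed(seed, {
    s <- replicate(n_starts, stats::qlogis(stats::runif(n_free, 0.025, 0.975)),
                   simplify = FALSE)
    if (!is.null(start)) {
      miss <- setdiff(cm$free, names(start))
      if (length(miss))
        stop("start lacks value(s) for: ", paste(miss, collapse = ", "))
      s <- c(list(stats::qlogis(pmin(pmax(start[cm$free], 1e-6), 1 - 1e-6))), s)
    }
    s
  })

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, fn, gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = tol)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all ", length(starts), " optimisation starts failed")
  theta <- stats::setNames(stats::plogis(best$par), cm$free)
  full <- expand_theta(model, theta)
  # exact log-likelihood at the optimum (multinomial, including constants)
  p <- unlist(category_probabilities(model, theta), use.names = FALSE)
  ll <- {
    tree_tot <- vapply(split(al$f, cm$cat_tree), sum, numeric(1))
    pos <- al$f > 0
    sum(lgamma(tree_tot + 1)) - sum(lgamma(al$f + 1)) +
      sum(al$f[pos] * log(pmax(p[pos], 1e-300)))
  }
  structure(list(
    estimates = theta,
    estimates_full = full,
    G2 = max(best$value, 0),
    df = df,
    p_value = if (df > 0) stats::pchisq(max(best$value, 0), df,
                                        lower.tail = FALSE) else NA_real_,
    log_likelihood = ll,
    converged = best$convergence == 0,
    n_starts_used = length(starts),
    se = NULL,
    model = model, data = data, seed = seed
  ), class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MPT fit: G2(%d) = %.2f, p = %s, converged: %s\n",
              x$df, x$G2,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 2),
              x$converged))
  est <- round(x$estimates, digits)
  if (!is.null(x$se)) {
    tab <- data.frame(estimate = est, se = round(x$se[names(est)], digits))
    print(tab)
  } else print(est)
  invisible(x)
}

# TRUE iff `sub` is nested in `parent`: same trees/parameters, and the
# parent's equality classes / constants are preserved (possibly coarsened)
is_nested_mpt <- function(parent, sub) {
  if (!identical(parent$parameters, sub$parameters)) return(FALSE)
  if (!identical(names(parent$trees), names(sub$trees))) return(FALSE)
  rp <- resolve_restrictions(parent)
  rs <- resolve_restrictions(sub)
  # every pair equal under the parent must be equal under the submodel;
  # compare class labels (map index or fixed value) parameter-wise
  lab <- function(r) ifelse(is.na(r$map), paste0("fix", r$fixed), paste0("f", r$map))
  lp <- lab(rp); ls <- lab(rs)
  for (cl in unique(lp)) {
    if (length(unique(ls[lp == cl])) > 1) return(FALSE)
  }
  # fixed values must be preserved exactly
  fixed_p <- !is.na(rp$fixed)
  if (any(fixed_p & (is.na(rs$fixed) | abs(rs$fixed - rp$fixed) > 1e-12)))
    return(FALSE)
  TRUE
}

#' Nested likelihood-ratio (delta G-squared) comparison
#'
#' Refits the restricted model on the same data and compares fit by
#' \eqn{\Delta G^2 = G^2_{restricted} - G^2_{full}}, referred to the
#' \eqn{\chi^2} distribution with \eqn{\Delta df} degrees of freedom.
#' Nesting is verified structurally (the restricted model's restriction set
#' must contain the full model's).  Tiny negative differences from finite
#' optimisation tolerance (> -1e-6) are clamped to zero.
#'
#' @param fit an `mpt_fit` of the full (parent) model.
#' @param restricted the nested [mpt_model()] (or an `mpt_fit` of it on the
#'   same data).
#' @param n_starts,seed passed to [fit_mpt()] when `restricted` is a model;
#'   the parent's estimates are always included as a starting point.
#' @return object of class `mpt_comparison`: `delta_G2`, `delta_df`,
#'   `p_value`, plus both fits.
#' @export
compare_mpt <- function(fit, restricted, n_starts = 20, seed = NULL) {
  stopifnot(inherits(fit, "mpt_fit"))
  if (inherits(restricted, "mpt_fit")) {
    rfit <- restricted
    rmodel <- rfit$model
  } else {
    rmodel <- restricted
    rfit <- NULL
  }
  if (!is_nested_mpt(fit$model, rmodel))
    stop("'restricted' is not nested in the fitted model")
  if (is.null(rfit)) {
    rfree <- free_parameters(rmodel)
    start <- expand_theta(fit$model, fit$estimates)[rfree]
    rfit <- fit_mpt(rmodel, fit$data, n_starts = n_starts, seed = seed,
                    start = start)
  }
  delta <- rfit$G2 - fit$G2
  if (delta < -1e-6)
    warning("restricted model fits better than the full model (delta G2 = ",
            signif(delta, 3), "); optimisation may not have converged")
  delta <- max(delta, 0)
  ddf <- rfit$df - fit$df
  if (ddf < 1) stop("restricted model adds no restrictions (delta df = ", ddf, ")")
  structure(list(delta_G2 = delta, delta_df = ddf,
                 p_value = stats::pchisq(delta, ddf, lower.tail = FALSE),
                 fit_full = fit, fit_restricted = rfit),
            class = "mpt_comparison")
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat(sprintf("delta G2(%d) = %.2f, p = %s\n", x$delta_df, x$delta_G2,
              format.pval(x$p_value, digits = 2)))
  invisible(x)
}

#' Parametric-bootstrap standard errors
#'
#' Draws `B` datasets from the fitted model's category probabilities at the
#' observed per-tree totals, refits each, and returns the per-parameter
#' standard deviation of the bootstrap estimates.  Parameters restricted to
#' constants have no sampling variability and are not reported.  Replicates
#' whose refit does not converge are dropped; more than 10% failures is an
#' error.
#'
#' @param model an identifiable [mpt_model()].
#' @param data an [frequency_table()].
#' @param B number of bootstrap replicates (>= 2).
#' @param seed seed controlling both the resampling and refits; fixed seed
#'   gives bit-identical results.
#' @param fit optional existing `mpt_fit` of `model` on `data` (refitted
#'   otherwise).
#' @param n_starts_refit random restarts per replicate, in addition to a
#'   start at the original estimates.
#' @return list of class `mpt_bootstrap`: `se` (named vector over free
#'   parameters), `B`, `n_failed`, `draws` (replicate-by-parameter matrix).
#' @export
bootstrap_se <- function(model, data, B = 1000, seed = NULL, fit = NULL,
                         n_starts_refit = 1) {
  stopifnot(B >= 2)
  if (is.null(fit)) fit <- fit_mpt(model, data, seed = seed)
  if (!fit$converged) stop("cannot bootstrap from a non-converged fit")
  probs <- category_probabilities(model, fit$estimates)
  trees <- names(data$counts)
  totals <- data$totals
  with_seed(seed, {
    draws <- matrix(NA_real_, B, length(fit$estimates),
                    dimnames = list(NULL, names(fit$estimates)))
    n_failed <- 0L
    for (b in seq_len(B)) {
      counts_b <- lapply(trees, function(tn) {
        p <- probs[[tn]]
        stats::setNames(as.numeric(
          stats::rmultinom(1, round(totals[[tn]]), p)), names(p))
      })
      names(counts_b) <- trees
      fb <- tryCatch(
        fit_mpt(model, frequency_table(counts_b),
                n_starts = n_starts_refit, start = fit$estimates),
        error = function(e) NULL)
      if (is.null(fb) || !fb$converged) n_failed <- n_failed + 1L
      else draws[b, ] <- fb$estimates
    }
    if (n_failed > 0.1 * B)
      stop("bootstrap failed: ", n_failed, " of ", B,
           " replicates did not converge")
    if (n_failed > 0)
      message(n_failed, " of ", B, " bootstrap replicates dropped")
    structure(list(se = apply(draws, 2, stats::sd, na.rm = TRUE),
                   B = B, n_failed = n_failed, draws = draws),
              class = "mpt_bootstrap")
  })
}

#' Serialize a fit to JSON
#'
#' @param fit an `mpt_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

fit_to_list <- function(fit) {
  list(
    estimates = as.list(fit$estimates),
    estimates_full = as.list(fit$estimates_full),
    se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
    G2 = fit$G2, df = fit$df, p_value = fit$p_value,
    log_likelihood = fit$log_likelihood,
    convergence = list(converged = fit$converged,
                       n_starts_used = fit$n_starts_used)
  )
}

# evaluate `code` under a temporary RNG state seeded with `seed`
# (global .Random.seed is restored afterwards); NULL seed = use current RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
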