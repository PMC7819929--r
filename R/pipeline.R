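#' Aggregate trial records into a frequency table
#'
#' Pools all participants' test-phase responses into one count per
#' (item type, response category) cell — the aggregate-data convention under
#' which a single G-squared is reported per experiment.  Trees are keyed
#' `<true_source>.<credibility>`.
#'
#' @param trials trial-record data.frame (see [simulate_experiment()]).
#' @param experiment `"exp1"` or `"exp2"`; fixes the admissible response
#'   categories.
#' @return an [frequency_table()].
#' @export
aggregate_trials <- function(trials, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  cats <- if (experiment == "exp1") c("ad", "test", "new")
          else c("ad", "test", "unknown", "new")
  tt <- trials[trials$phase == "test", , drop = FALSE]
  if (!nrow(tt)) stop("no test-phase records to aggregate")
  bad <- setdiff(unique(tt$response), cats)
  if (length(bad))
    stop("response(s) outside the ", experiment, " category set: ",
         paste(bad, collapse = ", "))
  key <- paste(tt$true_source, tt$credibility, sep = ".")
  counts <- lapply(split(tt$response, key), function(r) {
    stats::setNames(as.numeric(table(factor(r, levels = cats))), cats)
  })
  frequency_table(counts)
}

#' Proportion of items attributed to advertising
#'
#' For every participant and (credibility x true source) cell, the share of
#' items answered "ad"; the table reports the cross-participant mean and
#' standard error per cell.  By default the denominator is all items of the
#' cell (a "new" response counts as not attributed to advertising);
#' `denominator = "old"` conditions on items the participant called old.
#'
#' @param trials trial-record data.frame.
#' @param denominator `"all"` or `"old"`.
#' @return data.frame with columns `credibility`, `true_source`,
#'   `proportion`, `se`, `n_participants`; cells empty for some participant
#'   are dropped from that cell's average (and flagged by a reduced
#'   `n_participants`), not scored 0.
#' @export
attribution_proportions <- function(trials, denominator = c("all", "old")) {
  denominator <- match.arg(denominator)
  tt <- trials[trials$phase == "test", , drop = FALSE]
  if (denominator == "old") tt <- tt[tt$response != "new", , drop = FALSE]
  if (!nrow(tt)) stop("no test-phase records")
  per <- stats::aggregate(list(p = tt$response == "ad"),
                          by = list(participant = tt$participant,
                                    credibility = tt$credibility,
                                    true_source = tt$true_source),
                          FUN = mean)
  out <- stats::aggregate(list(proportion = per$p),
                          by = list(credibility = per$credibility,
                                    true_source = per$true_source),
                          FUN = mean)
  out$se <- stats::aggregate(list(se = per$p),
                             by = list(credibility = per$credibility,
                                       true_source = per$true_source),
                             FUN = function(x) stats::sd(x) / sqrt(length(x)))$se
  out$n_participants <- stats::aggregate(list(n = per$p),
                                         by = list(credibility = per$credibility,
                                                   true_source = per$true_source),
                                         FUN = length)$n
  out
}

#' Mean credibility ratings per cell
#'
#' Cell means and standard errors of the means, computed over participants'
#' cell means (each participant contributes one value per
#' phase x credibility x source cell).
#'
#' @param trials trial-record data.frame.
#' @param phase `"presentation"`, `"test"` or `"both"`.
#' @return data.frame with `phase`, `credibility`, `true_source`, `mean`,
#'   `sem`.
#' @export
rating_summary <- function(trials, phase = c("both", "presentation", "test")) {
  phase <- match.arg(phase)
  tt <- if (phase == "both") trials
        else trials[trials$phase == phase, , drop = FALSE]
  if (!nrow(tt)) stop("no records for the requested phase")
  per <- stats::aggregate(list(m = tt$rating),
                          by = list(participant = tt$participant,
                                    phase = tt$phase,
                                    credibility = tt$credibility,
                                    true_source = tt$true_source),
                          FUN = mean)
  out <- stats::aggregate(list(mean = per$m),
                          by = list(phase = per$phase,
                                    credibility = per$credibility,
                                    true_source = per$true_source),
                          FUN = mean)
  out$sem <- stats::aggregate(list(sem = per$m),
                              by = list(phase = per$phase,
                                        credibility = per$credibility,
                                        true_source = per$true_source),
                              FUN = function(x) stats::sd(x) / sqrt(length(x)))$sem
  out
}

#' Run the full model-based analysis
#'
#' Orchestrates the whole pipeline on one dataset: aggregation, descriptive
#' tables, base-model maximum-likelihood fit, the experiment's named nested
#' hypothesis tests, parametric-bootstrap standard errors, and the design's
#' prospective power statement.  For the three-source design, the two
#' model-validation tests (detection equal across sources; guessing equal
#' across recognition status) are run against the parsimonious base model,
#' and all substantive tests against the final base model, mirroring the
#' staged model-building sequence.  All p-values are reported unadjusted for
#' multiple testing.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{`experiment`}{`"exp1"` or `"exp2"` (required).}
#'     \item{`trials` / `trials_csv`}{trial-record data.frame or CSV path.}
#'     \item{`freq` / `freq_csv`}{alternatively, an aggregated
#'       [frequency_table()] or its CSV (descriptive tables are then
#'       skipped).}
#'     \item{`design`}{an [experiment_design()]; defaults to the
#'       experiment's standard design (used for the power statement).}
#'     \item{`seed`}{master seed; same config + seed gives an identical
#'       report, bootstrap included.}
#'     \item{`n_starts`}{random starts per fit (default 20).}
#'     \item{`bootstrap_B`}{bootstrap replicates (default 1000; set 0 to
#'       skip).}
#'     \item{`alpha`, `power_w`}{test level and effect size for the power
#'       statement (defaults .05, .03).}
#'     \item{`attribution_denominator`}{see [attribution_proportions()].}
#'   }
#' @return list of class `mpt_report`.
#' @export
run_full_analysis <- function(config) {
  experiment <- match.arg(config$experiment, c("exp1", "exp2"))
  design <- if (!is.null(config$design)) config$design
            else experiment_design(experiment)
  n_starts <- config$n_starts %||% 20
  B <- config$bootstrap_B %||% 1000
  alpha <- config$alpha %||% 0.05
  power_w <- config$power_w %||% 0.03
  seed <- config$seed

  trials <- NULL
  if (!is.null(config$trials)) trials <- config$trials
  else if (!is.null(config$trials_csv)) trials <- read_trials_csv(config$trials_csv)
  if (!is.null(trials)) freq <- aggregate_trials(trials, experiment)
  else if (!is.null(config$freq)) freq <- config$freq
  else if (!is.null(config$freq_csv)) freq <- read_freq_csv(config$freq_csv)
  else stop("config must supply trials, trials_csv, freq or freq_csv")

  with_seed(seed, {
    base <- experiment_base_model(experiment, "final")
    base_fit <- fit_mpt(base, freq, n_starts = n_starts)
    pars_fit <- if (experiment == "exp2")
      fit_mpt(experiment_base_model("exp2", "parsimonious"), freq,
              n_starts = n_starts)
    else NULL

    catalogue <- hypothesis_catalogue(experiment)
    comparisons <- lapply(names(catalogue), function(h) {
      parent_fit <- if (catalogue[[h]]$parent == "parsimonious") pars_fit
                    else base_fit
      sub <- apply_restrictions(parent_fit$model, catalogue[[h]]$restrictions)
      cmp <- compare_mpt(parent_fit, sub, n_starts = n_starts)
      cmp$hypothesis <- h
      cmp$parent <- catalogue[[h]]$parent
      cmp
    })
    names(comparisons) <- names(catalogue)

    boot <- NULL
    if (B >= 2) {
      boot <- bootstrap_se(base, freq, B = B, fit = base_fit)
      base_fit$se <- boot$se
    }

    report <- structure(list(
      experiment = experiment,
      frequency_table = freq,
      base_fit = base_fit,
      parsimonious_fit = pars_fit,
      comparisons = comparisons,
      attribution = if (!is.null(trials))
        attribution_proportions(trials,
          config$attribution_denominator %||% "all") else NULL,
      ratings = if (!is.null(trials)) rating_summary(trials) else NULL,
      power = design_power(design$n_participants, design$test_items,
                           w = power_w, alpha = alpha),
      metadata = list(seed = seed, n_starts = n_starts, bootstrap_B = B,
                      alpha = alpha,
                      p_adjustment = "none (unadjusted delta-G2 p-values)",
                      package_version =
                        as.character(utils::packageVersion("mptsource")))
    ), class = "mpt_report")
    report
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mpt_report <- function(x, ...) {
  cat("== Source-monitoring analysis report (", x$experiment, ") ==\n", sep = "")
  cat("\nBase model fit:\n"); print(x$base_fit)
  cat("\nHypothesis tests:\n")
  for (h in names(x$comparisons)) {
    cmp <- x$comparisons[[h]]
    cat(sprintf("  %-26s delta G2(%d) = %6.2f, p = %s\n", h, cmp$delta_df,
                cmp$delta_G2, format.pval(cmp$p_value, digits = 2)))
  }
  cat(sprintf("\nDesign power (w = %.2f, df = %d, alpha = %.2f, N = %d): %.3f\n",
              x$power$w, x$power$df, x$power$alpha, x$power$N, x$power$power))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (fit, tests, power, metadata) plus CSVs for the
#' frequency table and, when available, the attribution and rating tables.
#'
#' @param report an `mpt_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(
    experiment = report$experiment,
    base_fit = fit_to_list(report$base_fit),
    parsimonious_fit = if (!is.null(report$parsimonious_fit))
      fit_to_list(report$parsimonious_fit) else NULL,
    comparisons = lapply(report$comparisons, function(cmp)
      list(delta_G2 = cmp$delta_G2, delta_df = cmp$delta_df,
           p_value = cmp$p_value, parent = cmp$parent)),
    power = report$power,
    metadata = report$metadata
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_freq_csv(report$frequency_table, file.path(dir, "frequencies.csv"))
  if (!is.null(report$attribution))
    utils::write.csv(report$attribution, file.path(dir, "attribution.csv"),
                     row.names = FALSE)
  if (!is.null(report$ratings))
    utils::write.csv(report$ratings, file.path(dir, "ratings.csv"),
                     row.names = FALSE)
  invisible(dir)
}
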