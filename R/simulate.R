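#' Experimental design of a source-monitoring study
#'
#' Encodes the two study designs the simulator reproduces.  Defaults:
#' \describe{
#'   \item{`exp1`}{122 participants; two labelled sources (advertisement,
#'     brand testing); 20 studied items per credibility-by-source cell
#'     (40 high + 40 low at study); 40 new items per credibility at test
#'     (80 old + 80 new = 160 test items).}
#'   \item{`exp2`}{111 participants; three sources (advertisement, brand
#'     testing, no label); 13 studied items per credibility-by-source cell
#'     (39 + 39 at study); 39 new per credibility (78 old + 78 new = 156
#'     test items).}
#' }
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_participants,items_per_cell,new_per_credibility overrides of the
#'   design defaults.
#' @return list of class `mpt_design`.
#' @export
experiment_design <- function(experiment = c("exp1", "exp2"),
                              n_participants = NULL,
                              items_per_cell = NULL,
                              new_per_credibility = NULL) {
  experiment <- match.arg(experiment)
  def <- if (experiment == "exp1")
    list(n_participants = 122L, sources = c("ad", "test"),
         items_per_cell = 20L, new_per_credibility = 40L)
  else
    list(n_participants = 111L, sources = c("ad", "test", "unknown"),
         items_per_cell = 13L, new_per_credibility = 39L)
  if (!is.null(n_participants)) def$n_participants <- as.integer(n_participants)
  if (!is.null(items_per_cell)) def$items_per_cell <- as.integer(items_per_cell)
  if (!is.null(new_per_credibility))
    def$new_per_credibility <- as.integer(new_per_credibility)
  def$experiment <- experiment
  def$credibility <- c("high", "low")
  def$studied_per_credibility <- def$items_per_cell * length(def$sources)
  def$test_items <- 2L * (def$studied_per_credibility + def$new_per_credibility)
  structure(def, class = "mpt_design")
}

#' @export
print.mpt_design <- function(x, ...) {
  cat(sprintf(paste0("Design %s: %d participants, sources {%s}, ",
                     "%d studied + %d new per credibility, %d test items\n"),
              x$experiment, x$n_participants, paste(x$sources, collapse = ", "),
              x$studied_per_credibility, x$new_per_credibility, x$test_items))
  invisible(x)
}

#' Generative parameters for the simulator
#'
#' Bundles a full memory-parameter vector for the experiment's
#' source-monitoring model with a rating model (per phase x credibility x
#' source cell mean, common SD, discretised to the -3..+3 scale).
#'
#' The defaults are an illustrative fixture in the empirically plausible
#' range for this paradigm (item detection around .75-.85, weak source
#' memory, old-guessing .2-.35, a stronger advertisement-guessing bias for
#' low-credibility statements, higher rated credibility for high-credibility
#' statements and trustworthy sources); they are simulation ground truth for
#' testing the pipeline, not estimates from any real dataset.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return list of class `mpt_genparams` with elements `experiment`,
#'   `theta` (named vector over all model parameters), `rating_means`
#'   (nested list `phase$credibility[source]`) and `rating_sd`.
#' @export
default_generative_params <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  theta <- c()
  if (experiment == "exp1") {
    cell <- list(
      high = c(D = .77, d_ad = .32, d_test = .37, b = .21, g_ad = .39),
      low  = c(D = .83, d_ad = .02, d_test = .32, b = .33, g_ad = .61))
    for (cr in names(cell)) {
      v <- cell[[cr]]
      th <- c(D_ad = v[["D"]], D_test = v[["D"]], D_new = v[["D"]],
              d_ad = v[["d_ad"]], d_test = v[["d_test"]], b = v[["b"]],
              a_ad = v[["g_ad"]], g_ad = v[["g_ad"]])
      names(th) <- paste0(names(th), ".", cr)
      theta <- c(theta, th)
    }
    rating_means <- list(
      presentation = list(high = c(ad = 0.66, test = 1.37),
                          low  = c(ad = -1.56, test = -1.13)),
      test = list(high = c(ad = 0.64, test = 0.91, new = 0.75),
                  low  = c(ad = -1.65, test = -1.46, new = -1.50)))
  } else {
    cell <- list(
      high = list(D = .74, d_ad = .08, d_test = .24, d_unknown = .04, b = .23,
                  guess = c(ad = .32, test = .38, unknown = .30)),
      low  = list(D = .80, d_ad = .08, d_test = .14, d_unknown = .00, b = .33,
                  guess = c(ad = .52, test = .24, unknown = .24)))
    for (cr in names(cell)) {
      v <- cell[[cr]]
      st <- simplex_to_stick(v$guess)
      th <- c(D_ad = v$D, D_test = v$D, D_unknown = v$D, D_new = v$D,
              d_ad = v$d_ad, d_test = v$d_test, d_unknown = v$d_unknown,
              b = v$b, a1 = st[["s1"]], a2 = st[["s2"]],
              g1 = st[["s1"]], g2 = st[["s2"]])
      names(th) <- paste0(names(th), ".", cr)
      theta <- c(theta, th)
    }
    rating_means <- list(
      presentation = list(high = c(ad = 0.71, unknown = 0.83, test = 1.20),
                          low  = c(ad = -1.40, unknown = -1.48, test = -1.16)),
      test = list(high = c(ad = 0.63, unknown = 0.65, test = 0.72, new = 0.70),
                  low  = c(ad = -1.51, unknown = -1.54, test = -1.49,
                           new = -1.50)))
  }
  structure(list(experiment = experiment, theta = theta,
                 rating_means = rating_means, rating_sd = 1.5),
            class = "mpt_genparams")
}

# discrete ratings: normal truncated to (-3.5, 3.5) by inverse-CDF sampling,
# rounded to the integer grid -3..+3
sample_ratings <- function(n, mean, sd) {
  lo <- stats::pnorm(-3.5, mean, sd)
  hi <- stats::pnorm(3.5, mean, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  pmax(pmin(round(x), 3L), -3L)
}

#' Simulate a trial-level source-monitoring experiment
#'
#' For each participant, studied items are drawn afresh from a pool of 80
#' statements per credibility class and randomly assigned to the sources;
#' presentation-phase records carry a credibility rating, and test-phase
#' records (studied items intermixed with new ones) carry a rating plus the
#' old/new-and-source response sampled from the generative processing tree
#' of the item's type.  A "new" response encodes the no-source path; a
#' source judgment exists only for items judged old.
#'
#' @param design an [experiment_design()].
#' @param params an `mpt_genparams` object; defaults to
#'   [default_generative_params()] for the design's experiment.
#' @param seed simulation seed (global RNG state preserved); identical seeds
#'   give identical datasets.
#' @return data.frame of trial records with columns `participant`, `phase`
#'   (`presentation`/`test`), `item`, `credibility`, `true_source`, `rating`,
#'   `response` (`NA` in the presentation phase).
#' @export
simulate_experiment <- function(design, params = NULL, seed = NULL) {
  stopifnot(inherits(design, "mpt_design"))
  if (is.null(params)) params <- default_generative_params(design$experiment)
  stopifnot(inherits(params, "mpt_genparams"))
  if (params$experiment != design$experiment)
    stop("generative parameters are for ", params$experiment,
         " but the design is ", design$experiment)
  model <- if (design$experiment == "exp1") two_source_model()
           else three_source_model()
  missing <- setdiff(model$parameters, names(params$theta))
  if (length(missing))
    stop("generative theta lacks parameter(s): ", paste(missing, collapse = ", "))
  probs <- category_probabilities(model, params$theta)
  pool_n <- 80L
  n_study <- design$studied_per_credibility
  if (n_study + design$new_per_credibility > pool_n)
    stop("design requires more items than the 80-statement pool per credibility")

  with_seed(seed, {
    recs <- vector("list", design$n_participants)
    for (pp in seq_len(design$n_participants)) {
      pres <- list(); test <- list()
      for (cr in design$credibility) {
        ids <- sample.int(pool_n, n_study + design$new_per_credibility)
        studied <- ids[seq_len(n_study)]
        new_ids <- ids[n_study + seq_len(design$new_per_credibility)]
        src <- rep(design$sources, each = design$items_per_cell)
        pres[[cr]] <- data.frame(
          item = paste0(cr, "_", studied), credibility = cr,
          true_source = src, stringsAsFactors = FALSE)
        test[[cr]] <- data.frame(
          item = paste0(cr, "_", c(studied, new_ids)), credibility = cr,
          true_source = c(src, rep("new", design$new_per_credibility)),
          stringsAsFactors = FALSE)
      }
      pres <- do.call(rbind, pres); test <- do.call(rbind, test)
      pres <- pres[sample.int(nrow(pres)), , drop = FALSE]
      test <- test[sample.int(nrow(test)), , drop = FALSE]
      pres$participant <- pp; pres$phase <- "presentation"; pres$response <- NA_character_
      test$participant <- pp; test$phase <- "test"; test$response <- NA_character_
      recs[[pp]] <- rbind(pres, test)
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL

    # ratings, cell-wise
    out$rating <- NA_integer_
    for (ph in c("presentation", "test")) for (cr in design$credibility) {
      mm <- params$rating_means[[ph]][[cr]]
      for (src in names(mm)) {
        i <- out$phase == ph & out$credibility == cr & out$true_source == src
        out$rating[i] <- sample_ratings(sum(i), mm[[src]], params$rating_sd)
      }
    }

    # test responses, tree-wise from the generative category probabilities
    for (cr in design$credibility) for (src in c(design$sources, "new")) {
      tn <- paste0(src, ".", cr)
      i <- which(out$phase == "test" & out$credibility == cr &
                   out$true_source == src)
      p <- probs[[tn]]
      out$response[i] <- sample(names(p), length(i), replace = TRUE, prob = p)
    }
    out[, c("participant", "phase", "item", "credibility", "true_source",
            "rating", "response")]
  })
}

#' Expected frequency table under known parameters
#'
#' Deterministic counterpart of sampling: counts are per-tree totals times
#' the model's category probabilities (fractional counts allowed).  Fitting
#' the generating model to its own expected table recovers the parameters
#' with G-squared approximately 0.
#'
#' @param model an [mpt_model()].
#' @param theta named free-parameter values.
#' @param totals named numeric vector of per-tree observation totals.
#' @return an [frequency_table()] with real-valued counts.
#' @export
expected_table <- function(model, theta, totals) {
  probs <- category_probabilities(model, theta)
  missing <- setdiff(names(probs), names(totals))
  if (length(missing))
    stop("totals lack tree(s): ", paste(missing, collapse = ", "))
  counts <- lapply(names(probs), function(tn) probs[[tn]] * totals[[tn]])
  names(counts) <- names(probs)
  frequency_table(counts, integer = FALSE)
}

#' Sample a frequency table from the model
#'
#' Draws one multinomial sample per tree at the given totals — the
#' aggregated-data shortcut to [simulate_experiment()] plus
#' [aggregate_trials()] when only response frequencies are needed.
#'
#' @inheritParams expected_table
#' @param seed RNG seed (global state preserved).
#' @return an integer-valued [frequency_table()].
#' @export
simulate_table <- function(model, theta, totals, seed = NULL) {
  probs <- category_probabilities(model, theta)
  missing <- setdiff(names(probs), names(totals))
  if (length(missing))
    stop("totals lack tree(s): ", paste(missing, collapse = ", "))
  with_seed(seed, {
    counts <- lapply(names(probs), function(tn) {
      p <- probs[[tn]]
      stats::setNames(as.numeric(stats::rmultinom(1, totals[[tn]], p)),
                      names(p))
    })
    names(counts) <- names(probs)
    frequency_table(counts)
  })
}

#' Per-tree totals implied by a design
#'
#' @param design an [experiment_design()].
#' @return named vector: participants times items for every tree of the
#'   design's model.
#' @export
design_totals <- function(design) {
  tot <- c()
  for (cr in design$credibility) {
    t_src <- stats::setNames(
      rep(design$n_participants * design$items_per_cell, length(design$sources)),
      paste0(design$sources, ".", cr))
    t_new <- stats::setNames(design$n_participants * design$new_per_credibility,
                             paste0("new.", cr))
    tot <- c(tot, t_src, t_new)
  }
  tot
}

#' Read / write trial records as CSV
#'
#' Plain-CSV serialisation of the trial-record data.frame produced by
#' [simulate_experiment()] (columns `participant,phase,item,credibility,
#' true_source,rating,response`).
#'
#' @param path CSV file path.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("participant", "phase", "item", "credibility", "true_source",
            "rating", "response")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' @rdname read_trials_csv
#' @param trials trial-record data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}
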