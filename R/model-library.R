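#' The two-source source-monitoring model
#'
#' Two-high-threshold source-monitoring trees for items labelled as coming
#' from an advertisement ("ad"), from an independent brand-testing
#' institution ("test"), and for new items, duplicated over high- and
#' low-credibility statement classes.  Per credibility level the model has
#' eight parameters: item detection `D_ad`, `D_test`, `D_new`; source memory
#' `d_ad`, `d_test`; the old-guessing rate `b`; and the source-guessing
#' probabilities `a_ad` (for recognised items) and `g_ad` (for unrecognised
#' items guessed old).  Unrestricted, the model is over-parameterised: each
#' credibility level offers only six free response categories for its eight
#' parameters, so identifying restrictions (see [base_restrictions()]) are
#' required before fitting.
#'
#' @param credibility credibility levels to instantiate; trees and parameters
#'   are suffixed with the level name.
#' @return an [mpt_model()] with `3 * length(credibility)` trees of three
#'   response categories (`ad`, `test`, `new`) each.
#' @export
two_source_model <- function(credibility = c("high", "low")) {
  trees <- list()
  for (cr in credibility) {
    p <- function(nm) paste0(nm, ".", cr)
    guess_old <- function(Dsrc) list(
      mpt_branch("ad",   c(Dsrc, p("b"), p("g_ad")), c(TRUE, FALSE, FALSE)),
      mpt_branch("test", c(Dsrc, p("b"), p("g_ad")), c(TRUE, FALSE, TRUE)),
      mpt_branch("new",  c(Dsrc, p("b")),            c(TRUE, TRUE))
    )
    trees <- c(trees, list(
      mpt_tree(paste0("ad.", cr), c(list(
        mpt_branch("ad",   c(p("D_ad"), p("d_ad"))),
        mpt_branch("ad",   c(p("D_ad"), p("d_ad"), p("a_ad")), c(FALSE, TRUE, FALSE)),
        mpt_branch("test", c(p("D_ad"), p("d_ad"), p("a_ad")), c(FALSE, TRUE, TRUE))
      ), guess_old(p("D_ad"))), response_categories = c("ad", "test", "new")),
      mpt_tree(paste0("test.", cr), c(list(
        mpt_branch("test", c(p("D_test"), p("d_test"))),
        mpt_branch("ad",   c(p("D_test"), p("d_test"), p("a_ad")), c(FALSE, TRUE, FALSE)),
        mpt_branch("test", c(p("D_test"), p("d_test"), p("a_ad")), c(FALSE, TRUE, TRUE))
      ), guess_old(p("D_test"))), response_categories = c("ad", "test", "new")),
      mpt_tree(paste0("new.", cr), c(list(
        mpt_branch("new", p("D_new"))
      ), guess_old(p("D_new"))), response_categories = c("ad", "test", "new"))
    ))
  }
  mpt_model(trees)
}

#' The three-source source-monitoring model
#'
#' Extends the two-source model with an item class presented without any
#' source label ("unknown"), adding per credibility level the parameters
#' `D_unknown` (detection), `d_unknown` (memory that no source was given)
#' and a third guessing option.  Source guessing over the three options
#' \{ad, test, unknown\} is parameterised by two binary stick-breaking
#' parameters so every branch stays a product of \eqn{\theta}/\eqn{1-\theta}
#' factors: `a1` = P(guess "ad"), `a2` = P(guess "test" | not "ad") for
#' recognised items, and likewise `g1`, `g2` for unrecognised items guessed
#' old.  [guess_simplex()] converts the stick-breaking pair to the three
#' guessing probabilities.
#'
#' @inheritParams two_source_model
#' @return an [mpt_model()] with `4 * length(credibility)` trees of four
#'   response categories (`ad`, `test`, `unknown`, `new`) each.
#' @export
three_source_model <- function(credibility = c("high", "low")) {
  trees <- list()
  cats <- c("ad", "test", "unknown", "new")
  for (cr in credibility) {
    p <- function(nm) paste0(nm, ".", cr)
    # three-way guess given stem factors (params, comp)
    guess3 <- function(stem_p, stem_c, g1, g2) list(
      mpt_branch("ad",      c(stem_p, g1),     c(stem_c, FALSE)),
      mpt_branch("test",    c(stem_p, g1, g2), c(stem_c, TRUE, FALSE)),
      mpt_branch("unknown", c(stem_p, g1, g2), c(stem_c, TRUE, TRUE))
    )
    src_tree <- function(src, Dp, dp) {
      mpt_tree(paste0(src, ".", cr), c(
        list(mpt_branch(src, c(Dp, dp))),
        guess3(c(Dp, dp), c(FALSE, TRUE), p("a1"), p("a2")),
        guess3(c(Dp, p("b")), c(TRUE, FALSE), p("g1"), p("g2")),
        list(mpt_branch("new", c(Dp, p("b")), c(TRUE, TRUE)))
      ), response_categories = cats)
    }
    trees <- c(trees, list(
      src_tree("ad",      p("D_ad"),      p("d_ad")),
      src_tree("test",    p("D_test"),    p("d_test")),
      src_tree("unknown", p("D_unknown"), p("d_unknown")),
      mpt_tree(paste0("new.", cr), c(
        list(mpt_branch("new", p("D_new"))),
        guess3(c(p("D_new"), p("b")), c(TRUE, FALSE), p("g1"), p("g2")),
        list(mpt_branch("new", c(p("D_new"), p("b")), c(TRUE, TRUE)))
      ), response_categories = cats)
    ))
  }
  mpt_model(trees)
}

#' Convert stick-breaking guessing parameters to simplex probabilities
#'
#' The three-source model stores the guess over \{ad, test, unknown\} as two
#' binary parameters; this returns the implied probabilities, which is how
#' guessing is conventionally reported.
#'
#' @param s1 probability of guessing "ad".
#' @param s2 probability of guessing "test" given not "ad".
#' @return named numeric vector `(ad, test, unknown)` summing to 1.
#' @export
guess_simplex <- function(s1, s2) {
  c(ad = s1, test = (1 - s1) * s2, unknown = (1 - s1) * (1 - s2))
}

#' @rdname guess_simplex
#' @param p named or positional probability vector `(ad, test, unknown)`
#'   summing to 1.
#' @return for `simplex_to_stick()`: vector `(s1, s2)`.
#' @export
simplex_to_stick <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stop("simplex probabilities must sum to 1")
  s1 <- p[[1]]
  s2 <- if (s1 < 1) p[[2]] / (1 - s1) else 0.5
  c(s1 = s1, s2 = s2)
}

#' Named base restriction sets
#'
#' Identifying restriction sets for the bundled models, per credibility
#' level:
#' \describe{
#'   \item{`exp1`}{two-source base model: `D_ad = D_test = D_new` (the
#'     two-high-threshold assumption plus detection equal across sources) and
#'     `a_ad = g_ad` (source guessing independent of recognition status);
#'     10 free parameters, df = 2.}
#'   \item{`exp1_unrestrictedD`}{only `a_ad = g_ad`; retained for studying
#'     the identification problem — the resulting model is still
#'     over-parameterised (df = -2) and cannot be fitted.}
#'   \item{`exp2_parsimonious`}{three-source parsimonious base model: only
#'     `D_unknown = D_new`; 22 free parameters, df = 2.}
#'   \item{`exp2_final`}{three-source final base model: detection equal
#'     across all four item types and `a = g` on both stick-breaking
#'     parameters; 14 free parameters, df = 10.}
#' }
#'
#' @param name one of `"exp1"`, `"exp1_unrestrictedD"`,
#'   `"exp2_parsimonious"`, `"exp2_final"`.
#' @param credibility credibility level suffixes the set is instantiated for.
#' @return list of restrictions suitable for [apply_restrictions()].
#' @export
base_restrictions <- function(name = c("exp1", "exp1_unrestrictedD",
                                       "exp2_parsimonious", "exp2_final"),
                              credibility = c("high", "low")) {
  name <- match.arg(name)
  out <- list()
  for (cr in credibility) {
    p <- function(nm) paste0(nm, ".", cr)
    out <- c(out, switch(name,
      exp1 = list(
        restr_equal(p("D_ad"), p("D_test"), p("D_new")),
        restr_equal(p("a_ad"), p("g_ad"))
      ),
      exp1_unrestrictedD = list(
        restr_equal(p("a_ad"), p("g_ad"))
      ),
      exp2_parsimonious = list(
        restr_equal(p("D_unknown"), p("D_new"))
      ),
      exp2_final = list(
        restr_equal(p("D_ad"), p("D_test"), p("D_unknown"), p("D_new")),
        restr_equal(p("a1"), p("g1")),
        restr_equal(p("a2"), p("g2"))
      )
    ))
  }
  out
}

#' Build a base model for one of the two experimental designs
#'
#' Convenience wrapper: the two-source model with the `exp1` base
#' restrictions, or the three-source model with either the parsimonious or
#' the final base restrictions.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param base for `"exp2"`, which base restriction set to use.
#' @return a restricted [mpt_model()].
#' @export
experiment_base_model <- function(experiment = c("exp1", "exp2"),
                                  base = c("final", "parsimonious")) {
  experiment <- match.arg(experiment)
  base <- match.arg(base)
  if (experiment == "exp1")
    apply_restrictions(two_source_model(), base_restrictions("exp1"))
  else
    apply_restrictions(three_source_model(),
                       base_restrictions(paste0("exp2_",
                         if (base == "final") "final" else "parsimonious")))
}

#' Catalogue of named hypothesis tests
#'
#' The equality restrictions behind every nested likelihood-ratio test the
#' analysis pipeline reports, keyed by hypothesis name.  Each entry records
#' the restrictions to add and the base model it is tested against
#' (`"final"` for tests run on the base model, `"parsimonious"` for the two
#' model-validation tests of the three-source design that motivate the final
#' base model).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return named list; each element has `restrictions` and `parent`.
#' @export
hypothesis_catalogue <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  eq <- function(...) list(restr_equal(...))
  if (experiment == "exp1") {
    list(
      D_credibility       = list(restrictions = eq("D_ad.high", "D_ad.low"),
                                 parent = "final"),
      d_ad_vs_d_test_high = list(restrictions = eq("d_ad.high", "d_test.high"),
                                 parent = "final"),
      d_ad_vs_d_test_low  = list(restrictions = eq("d_ad.low", "d_test.low"),
                                 parent = "final"),
      g_ad_credibility    = list(restrictions = eq("g_ad.high", "g_ad.low"),
                                 parent = "final")
    )
  } else {
    list(
      D_sources = list(
        restrictions = c(eq("D_ad.high", "D_test.high", "D_unknown.high"),
                         eq("D_ad.low", "D_test.low", "D_unknown.low")),
        parent = "parsimonious"),
      a_equals_g = list(
        restrictions = c(eq("a1.high", "g1.high"), eq("a2.high", "g2.high"),
                         eq("a1.low", "g1.low"), eq("a2.low", "g2.low")),
        parent = "parsimonious"),
      D_credibility          = list(restrictions = eq("D_ad.high", "D_ad.low"),
                                    parent = "final"),
      d_ad_vs_d_test_high    = list(restrictions = eq("d_ad.high", "d_test.high"),
                                    parent = "final"),
      d_ad_vs_d_test_low     = list(restrictions = eq("d_ad.low", "d_test.low"),
                                    parent = "final"),
      d_test_vs_d_unknown_high = list(restrictions = eq("d_test.high", "d_unknown.high"),
                                      parent = "final"),
      d_test_vs_d_unknown_low  = list(restrictions = eq("d_test.low", "d_unknown.low"),
                                      parent = "final"),
      d_ad_vs_d_unknown_high = list(restrictions = eq("d_ad.high", "d_unknown.high"),
                                    parent = "final"),
      d_ad_vs_d_unknown_low  = list(restrictions = eq("d_ad.low", "d_unknown.low"),
                                    parent = "final"),
      g_ad_credibility       = list(restrictions = eq("g1.high", "g1.low"),
                                    parent = "final")
    )
  }
}

#' Derive the submodel for a named hypothesis
#'
#' Adds the hypothesis' equality restrictions to `model`.  The difference in
#' free-parameter counts between `model` and the returned submodel is the
#' degrees of freedom of the corresponding nested test.
#'
#' @param model the parent [mpt_model()] (usually a base model).
#' @param hypothesis a name from [hypothesis_catalogue()].
#' @param experiment which catalogue to look the name up in.
#' @return the restricted [mpt_model()].
#' @export
hypothesis_submodel <- function(model, hypothesis,
                                experiment = c("exp1", "exp2")) {
  cat_ <- hypothesis_catalogue(match.arg(experiment))
  if (!hypothesis %in% names(cat_))
    stop("unknown hypothesis '", hypothesis, "'; available: ",
         paste(names(cat_), collapse = ", "))
  apply_restrictions(model, cat_[[hypothesis]]$restrictions)
}
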