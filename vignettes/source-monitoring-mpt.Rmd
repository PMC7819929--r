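---
title: "Source-monitoring MPT models for advertisement memory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-monitoring MPT models for advertisement memory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptsource)
```

## The measurement problem

When people misremember where a piece of information came from, a product
claim that was labelled as an advertisement can later be treated as if it
had come from a trustworthy source. Raw source-attribution rates confound
three distinct processes: recognising a statement as previously seen (item
recognition), retrieving its source label (source memory), and
reconstructing a plausible source when memory fails (guessing). Multinomial
processing tree (MPT) models of source monitoring disentangle these
processes from the observed response frequencies of an old/new plus
source-judgment test.

`mptsource` implements this measurement model for two designs: two labelled
sources (advertisement vs. an independent brand-testing institution) and
three sources (those two plus statements shown without any label), each
crossed with the statements' a priori credibility (high vs. low). It covers
the whole analysis chain — model construction, maximum-likelihood fitting,
nested hypothesis tests, bootstrap standard errors, prospective power — plus
a trial-level simulator so that every stage can be validated without any
real dataset.

## The model

Each item type (true source × credibility) has its own processing tree over
the response categories. For an advertisement item of one credibility
level, with detection probability $D_{Ad}$, source memory $d_{Ad}$,
old-guessing $b$ and source-guessing probabilities $a_{Ad}$ (recognised) and
$g_{Ad}$ (unrecognised but guessed old):

$$
\begin{aligned}
P(\text{"ad"}) &= D_{Ad} d_{Ad} + D_{Ad}(1-d_{Ad})a_{Ad} + (1-D_{Ad})\,b\,g_{Ad}\\
P(\text{"test"}) &= D_{Ad}(1-d_{Ad})(1-a_{Ad}) + (1-D_{Ad})\,b\,(1-g_{Ad})\\
P(\text{"new"}) &= (1-D_{Ad})(1-b)
\end{aligned}
$$

with analogous trees for brand-testing items and for new items (where
detection means correctly calling the item new — the two-high-threshold
assumption). The trees are duplicated per credibility level with suffixed
parameter names (`D_ad.high`, `D_ad.low`, ...), and no cross-credibility
equalities are part of any base model.

In the three-source variant the guess over {ad, test, unknown} is a
three-way simplex. Internally it is held as two binary *stick-breaking*
parameters per guess node — `a1` = P(guess ad) and `a2` = P(guess test |
not ad), likewise `g1`, `g2` — so every branch remains a product of
$\theta$ / $(1-\theta)$ factors, the canonical binary-MPT form.
`guess_simplex()` converts to the reported probabilities. The recognition
status equality ("a = g") is imposed on the stick parameters; this is
equivalent to equality on the simplex (the map between the two
parameterisations is a bijection away from the boundary), and either way it
costs two restrictions per credibility level, which the tests assert.

### Identifiability and restrictions

Per credibility level the two-source model has eight parameters but only
six free response categories, so the unrestricted model is not
identifiable. The standard identifying base model imposes
$D_{Ad}=D_{Test}=D_{New}$ and $a_{Ad}=g_{Ad}$ within each credibility
level, leaving 10 free parameters against 12 free categories: df = 2. The
three-source model is exactly saturated when unrestricted (24 parameters,
24 free categories); its parsimonious base model imposes only
$D_{Unknown}=D_{New}$ (df = 2), and the final base model additionally
equates detection across all item types and guessing across recognition
status (14 free parameters, df = 10). `degrees_of_freedom()` computes
these counts on the restricted model, and `check_local_identifiability()`
verifies local identifiability numerically via the rank of the
finite-difference Jacobian of the category probabilities (central
differences, step $10^{-6}$; rank from singular values with a relative
threshold of $10^{-10}$).

Restrictions are equality classes (resolved by union–find, so chained and
overlapping equalities compose) plus constants; a parameter class forced to
two distinct constants is a hard error, and applying a restriction set
twice is a no-op.

## Estimation

Models are fitted to frequency tables pooled over participants
(aggregate-data MPT fitting, matching the convention under which a single
goodness-of-fit statistic is reported per experiment). The objective is

$$G^2(\theta) = 2\sum_{c} f_c \log\frac{f_c}{n\,p_c(\theta)},$$

with $0\log 0 = 0$, equivalent to maximising the multinomial
log-likelihood. Numerical choices:

* optimisation runs on logit-transformed free parameters, so the \[0, 1\]
  box constraints never bind and BFGS can be used with analytic gradients
  (the branch-product structure makes $\partial p_c/\partial\theta_j$
  cheap);
* 20 uniform-random starting points by default (`n_starts`), drawn in
  (.025, .975) to avoid degenerate starts; the best converged solution
  wins, and an explicit `start` (e.g. the parent model's estimates when
  refitting a nested submodel) is always added as an extra start;
* convergence tolerance $10^{-9}$ (relative, on $G^2$); expected
  probabilities are floored at $10^{-12}$ inside logarithms; observed zero
  cells contribute zero to $G^2$;
* a model with df < 0 refuses to fit; a tree with total count 0 is an
  error; if no start converges the result is flagged, never silently
  returned.

Nested comparisons (`compare_mpt()`) refit the restricted model, verify
nesting *structurally* (the submodel's restriction partition must coarsen
the parent's and preserve its constants), and clamp tiny negative
$\Delta G^2$ above $-10^{-6}$ to zero — larger negative values trigger a
warning, since they indicate a failed refit rather than rounding.

Standard errors are parametric bootstrap (`bootstrap_se()`): resample B
frequency tables from the fitted category probabilities at the observed
per-tree totals, refit, and take per-parameter standard deviations. B
defaults to 1000; replicates that fail to converge are dropped with a
message, and more than 10% failures is an error. Whether a published
bootstrap was parametric or nonparametric, and with which B, is often left
unstated; parametric with B = 1000 is this package's documented choice.
Parameters pinned to constants carry no sampling variability and are not
reported. Fisher-information SEs are deliberately not offered — the
bootstrap is the method of record here.

## Power

Prospective power for chi-square-family tests uses Cohen's effect size
$w = \sqrt{\sum_c (p^{alt}_c - p^{null}_c)^2/p^{null}_c}$ and the
noncentral chi-square distribution with $\lambda = N w^2$. For the
guessing-parameter tests, $N$ is interpreted as participants × test items —
122 × 160 = 19,520 (two-source design) and 111 × 156 = 17,316
(three-source design) — and df = 1 for a single equality restriction. Both
designs reach power ≥ .95 for w = 0.03 at α = .05;
`min_detectable_w(.95, 19520)` ≈ 0.0258, i.e. the conventional "small
effect" of w = 0.03 is comfortably detectable. `min_detectable_w()` inverts
the power function by bisection to $10^{-6}$.

## The simulator

`simulate_experiment()` generates trial-level records with the statistical
structure the analysis assumes:

* the two study designs as defaults — 122 participants, 20 items per
  credibility × source cell at study and 40 new items per credibility at
  test (160 test items); or 111 participants, 13 items per cell over three
  sources and 39 new per credibility (156 test items) — with per-participant
  random item assignment from an 80-statement pool per credibility class;
* test responses sampled by walking the generative processing tree of the
  item's type; a source judgment exists only for items judged old ("new"
  encodes the no-source path), and the "unknown" response exists only in
  the three-source design;
* ratings drawn from a normal distribution truncated to (−3.5, 3.5)
  (inverse-CDF sampling) and rounded to the integer −3..+3 scale. Cell
  SDs are a free knob with default 1.5, a typical single-item spread for
  7-point rating scales in this literature.

The default generative memory parameters are an illustrative fixture in the
empirically plausible range for this paradigm (detection .74–.83, source
memory .00–.37, old-guessing .21–.33, and a stronger
advertisement-guessing bias for low-credibility statements); they are
simulation ground truth for testing the pipeline, not estimates from any
real dataset. All participants share one parameter vector: the model is fit
to pooled frequencies, so participant heterogeneity is outside the
measurement model; simulating it is a documented extension point, not a
feature. Consequently, passing tests show that the pipeline recovers the
generative process *it assumes*; they cannot show robustness to
participant-level variability, item effects, or sequential dependencies
that real data may contain.

Reproducibility: every randomised function takes a `seed` and restores the
global RNG state afterwards; identical seeds give byte-identical datasets,
fits and bootstrap draws. `run_full_analysis()` seeds one stream from its
master seed, so a config plus seed pins the entire report.

## The pipeline and its hypothesis battery

`run_full_analysis()` aggregates trials, fits the experiment's base model,
and runs a named catalogue of nested tests
(`hypothesis_catalogue()`): detection across credibility, source memory
contrasts within each credibility level, and the advertisement-guessing
bias across credibility; for the three-source design the two
model-validation tests (detection equal across item types; guessing equal
across recognition status) run against the parsimonious base model, and all
substantive tests against the final base model — the staged model-building
sequence. Reported p-values are unadjusted for multiple testing, and the
report metadata says so.

The attribution descriptive (`attribution_proportions()`) counts, per
participant and credibility × source cell, the share of items attributed to
advertising. Its default denominator is **all** items of the cell — a
"new" response counts as not-attributed — because misattribution rates are
discussed for all statement types; conditioning on items the participant
called old is available via `denominator = "old"`. This choice is genuinely
open and the flag documents both readings.

## Problem sizes used in the test suite

The simulation-based checks run at the full designs' observation counts
(e.g. 19,520 test observations for the two-source design) with 100
replicates for parameter recovery (estimates within ±0.05 of truth in
median), 1,000 replicates for the 1-df type-I error calibration
(5% ± 2 points), 400 replicates for the null distribution of
$\Delta G^2(1)$ against $\chi^2(1)$, and bootstrap blocks of 100–150
replicates; these sizes give stable Monte-Carlo error for the stated
tolerances while keeping the default suite fast. Simulation checks that
only need aggregate frequencies use `simulate_table()` (one multinomial
draw per tree), which is distributionally identical to trial-level
simulation followed by aggregation because the generator is homogeneous
across participants.

## Known limitations

* Aggregate-data fitting only: no hierarchical/latent-trait MPT, no
  Bayesian estimation.
* No AIC/BIC model weights — comparisons are $G^2$-based likelihood-ratio
  tests of nested models, as is standard for this model family.
* The rating model is descriptive (discretised normal); it does not model
  the joint distribution of ratings and memory responses.
* Designs other than 2–3 sources × 2 credibility classes are expressible
  through `mpt_model()` and the text format, but the convenience layer
  (catalogue, simulator) covers only the two bundled designs.
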