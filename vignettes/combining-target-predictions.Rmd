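---
title: "Combining miRNA target prediction databases: methods and design notes"
author: "mirfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining miRNA target prediction databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfuse)
```

## The problem

Sequence-based miRNA target predictors disagree wildly: each algorithm
publishes its own scored list of (miRNA, gene) pairs, on its own scale, at
its own coverage, with a large and unknown false-positive fraction.
Experimentally validated interactions exist but cover only a small corner
of the prediction space. `mirfuse` turns a heterogeneous collection of
prediction databases plus a gold standard of validated interactions into a
single, better-ranked interaction list, and quantifies how much each input
database can be trusted along the way.

Everything operates on three objects: `scored_db` (one source's
interactions with raw and normalized scores), `gold_standard` (the union of
validated (miRNA, gene) pairs — set semantics, per-pair source provenance),
and the `universe` — every pair predicted by at least one database, which
is the population for all statistics. Validated pairs that no database
predicts are *not* in the universe; they are permanent false negatives in
evaluation.

## Harmonization and score normalization

Databases disagree on identifiers (miRNA synonyms, transcript- vs
gene-level targets) and on score semantics. `harmonize()` applies alias
dictionaries (miRBase-aliases dialect for miRNAs, a two-column map for
transcripts/genes) and collapses transcript-level rows to genes. Where the
collapse creates duplicate pairs we keep the most confident score — the
direction-aware maximum — because the downstream convention is "1 is the
highest confidence" and a gene is at least as likely a target as its
best-supported transcript. Matching is exact and case-preserving: silent
case folding would hide dictionary gaps that the user should fix.

Two normalizations map raw scores to [0, 1]:

* `normalize_minmax()` — linear rescale; energy-like scores
  (`lower_is_better`, e.g. hybridization free energies) are flipped so 1 is
  always best.
* `normalize_rank_cdf()` — one minus the empirical CDF position, i.e.
  `rank_from_worst / n`. This removes the influence of dense scoring
  regions entirely; the output grid depends only on `n` and the tie
  pattern. Ties take the maximum rank of their group, so the transform is
  deterministic and permutation-invariant, and every value lies in (0, 1]
  with the best pair at exactly 1.

## Database reliability: the enrichment z-score

For each database we sort by normalized score and, at every distinct score
threshold, test whether the top list is enriched in validated pairs using
the upper-tail hypergeometric probability with the universe as population.
The database's statistic is the *minimum* p-value over the sweep,
summarized as `z = qnorm(log p)` evaluated in log space. Two numerical
points matter:

* p-values routinely underflow doubles (the realistic regime is
  p ≈ e^-2000), so `log_hypergeom_tail()` accumulates the tail with
  log-gamma terms combined by log-sum-exp, and the normal quantile is taken
  directly from the log p-value (`qnorm(log.p = TRUE)` uses an asymptotic
  tail inversion, so even p = e^-4000 maps to a finite z).
* ties in the score enter the threshold together — per-row cuts through a
  tie group would depend on row order.

No multiple-testing correction is applied across the sweep. The minimum
over thresholds is optimistic by construction; the z-score is meaningful
for *ranking* databases against each other (they all enjoy the same
optimism), not as a calibrated significance level. Under a score-label
null the selected minimum sits around z ≈ −1.3 rather than 0 for exactly
this reason. When several thresholds tie at the minimum we keep the
smallest top list, the most conservative selected set.

## WSP: precision-weighted score summation

For each database, interactions are sorted best-to-worst (ties broken
lexicographically by pair id — a label-blind rule, so no validation status
leaks into positions) and the accumulated precision TP/(TP+FP) is computed
at every position, counting from the top of the list through the position
itself. The weight of a position is the accumulated precision minus the
database's expected precision (its overall validated fraction — what a
random ordering achieves), floored at zero so segments performing at or
below random contribute nothing rather than negatively. The combined score
of a pair is

    WSP(pair) = sum over databases containing the pair of
                norm_score * weight at the pair's own position

Pairs outside a database contribute zero from it. The weight is
per-position, not a database-level scalar: a database can be reliable at
the top of its list and useless below, and the weighting tracks that. An
uninformative database has weights near zero everywhere, which is what
makes WSP robust to noise inputs: appending a pure-noise database to an
informative ensemble leaves the ranking essentially unchanged (Spearman
> 0.999 in the shipped tests). Expected precision is computed within the
database, not the universe, because it corrects for how hard that
database's own list is.

## LRS: calibrated probabilities fused by logistic regression

Per database, the score-sorted list is cut into equal-count bins (default
50; equal-count cannot produce empty bins under skewed scores) and the
validated fraction per bin is interpolated with a cubic smoothing spline
(smoothing chosen by generalized cross-validation unless `spar` is given).
Evaluation clamps the input to the fitted score range and the output to
[0, 1]; with fewer than four distinct bin midpoints the fit degrades
gracefully to linear interpolation, and to a constant for a single
midpoint. Before smoothing, the bins satisfy the exact identity
`sum(count x fraction) = validated pairs in the database`.

Each pair then gets one feature per database — its calibrated probability
of being validated, or 0 where the database does not predict the pair (no
evidence) — plus all pairwise products of those features. The cross-terms
absorb redundancy between databases that largely copy each other's
predictions; with 0-fill a cross-term is nonzero exactly when both
databases support the pair. The features are fused by an unpenalized
logistic maximum-likelihood fit of the validation label over the universe
(ridge or lasso via glmnet is available by configuration, and the model
falls back to ridge automatically if the likelihood separates). Databases
are canonicalized by sorted name, so predictions are invariant to input
order. A consequence of the unpenalized fit with intercept is the logistic
score equation: the mean predicted probability equals the universe's
validated fraction exactly (to solver tolerance), which the tests assert
at 1e-6.

`lrs_config(features = "score")` bypasses the calibration and fuses the
raw normalized scores instead. That variant exists because it makes the
model's coefficients directly interpretable against a known generative
process (the parameter-recovery tests use it); the default remains the
calibrated probabilities, which is also what the cross-terms are defined
on.

`cross_validated_auc()` refits *everything* — bins, splines, logistic
model — inside each training fold and scores the held-out fold, which is
the honest estimate of ranking performance. Fitting and evaluating on the
same gold standard is optimistic; on the shipped ensembles the optimism
(full-data AUC minus 5-fold CV AUC) is below 0.01, because the model has
few parameters relative to the number of pairs.

## Evaluation

`roc_curve()` sweeps thresholds over distinct scores (ties cross
together); the trapezoid AUC equals the Mann–Whitney rank statistic with
midranks, and the tests pin that equivalence at 1e-9. True negatives
cannot be observed for target predictions — there is no database of
non-interactions — so negatives are relative to the universe and AUC must
be read comparatively, not absolutely. `precision_curve()` avoids the
true-negative problem entirely: it reports the validated fraction among
the top-k predictions minus the universe's validated fraction (what random
ordering attains), so 0 means "no better than random" at every depth and
curves of differently sized methods are comparable. The union and
intersection baselines get binary scores over the universe; the
intersection is precise but tiny, and the corrected precision curve is
where that trade-off is visible.

A caution that the tests make explicit: both WSP weights and the LRS fit
use the same gold standard the curves are computed against. In-sample AUC
is therefore optimistic even for an uninformative ensemble (~0.53 rather
than 0.50, partly because the accumulated precision at a position includes
the interaction itself). The unbiased null readout is AUC against held-out
truth — true pairs the gold standard never confirmed — which the null
tests use, and the cross-validated AUC is the unbiased readout for the
informative case.

## The synthetic ensemble generator

`generate_ensemble()` draws a grid of miRNA x gene cells, a set of truly
regulatory pairs, a gold standard (each true pair validated independently
with probability `validation_coverage`, default 0.6 — experimental
validation is far from exhaustive), and per-database interaction lists:
`n_true` pairs sampled from the truth, `n_false` from the complement, with
scores drawn from truth-conditioned Beta distributions. Beta families are
used because P(true score > false score) — the database's expected AUC —
is a one-dimensional integral (`expected_auc()`), and for the convenience
parameterization Beta(a, 1) against uniform it is exactly a/(a+1). That
gives every evaluation test an analytic oracle. A single master seed
derives per-database substreams, so ensembles are byte-reproducible.

What the generator does *not* emulate: sequence features, seed-match
classes, conservation, expression context, or correlated errors between
algorithms that share a starting set (real predictors are far from
independent; here inter-database dependence arises only through shared
true pairs). Passing tests on these ensembles shows the machinery is
correct and behaves as designed under known conditions — not that any
particular real database collection will reach a given AUC.

Problem sizes used in the shipped tests and the acceptance script were
chosen to make the statistical assertions stable at desk scale: universes
of roughly 5,000–20,000 pairs, databases of 600–8,000 interactions,
20-seed replication for comparative claims and 100-seed replication for
null-behavior claims.

## Degenerate inputs and numerical choices

* A database with a single distinct score normalizes to all-1 with a
  warning; it carries no ranking information.
* Duplicate pairs within one source (including after transcript collapse)
  keep the most confident score, logged; the sources do not document their
  own resolution rules.
* Score ties: grouped in every sweep (reliability, ROC); broken
  lexicographically where a total order is required (WSP positions,
  binning).
* `glm` convergence tolerance is 1e-12 with up to 200 iterations so the
  score-equation identity holds to 1e-6; separation triggers an automatic
  ridge fallback.
* All stochastic steps (generator, fold assignment) take explicit integer
  seeds.

## Limitations

The gold standard is treated as noiseless positive labels; false
validations and literature bias are not modeled. The reliability z-score
inherits the optimism of minimum-p selection and should only be compared
across databases evaluated on the same universe. LRS output is calibrated
against the training gold standard's base rate, so the probabilities are
relative, and both combiners require a gold standard with coverage in
every database they are asked to weight.
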