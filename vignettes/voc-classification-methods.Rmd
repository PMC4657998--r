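---
title: "Methods: urinary VOC classification with nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary VOC classification with nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vocclass)
```

## The problem and the data model

Urine headspace GC-MS produces, per patient, a list of detected volatile
organic compounds (VOCs).  In case/control biomarker studies of prostate
cancer the informative signal is largely *which* compounds are detected
rather than how much, so the pipeline's data model is a sample × feature
table of presence/absence flags (`feature_table`), a two-class label per
sample (cancer / control, with cancer the positive class throughout), and
optional continuous covariates — here serum PSA in ng/mL, the clinical
comparator.

Two processing rules define the modelling table:

* **Binarization** (`binarize`): a compound is *present* when its processed
  relative abundance strictly exceeds a threshold, 0 by default — any
  positive abundance in a processed table counts as a detection.  The rule
  is idempotent, so already-binary tables pass through unchanged.
* **Dual prevalence filter** (`prevalence_filter`): compounds present in
  fewer than 20 % of samples *in both classes* (rare) or in more than 90 %
  *in both classes* (ubiquitous) are removed before modelling.  Both
  comparisons are strict and both are conjunctions over the two classes: a
  compound rare among controls but common among cases is exactly the kind
  of feature the analysis wants, and is kept.  Prevalences are exact
  per-class fractions; missing cells are rejected rather than imputed,
  because the analysis defines no imputation procedure.

## Feature selection

Four wrappers are run on the filtered binary table and the classifier panel
is their **union** (`consensus_union`) — any feature selected by at least
one approach, in the table's column order:

1. `boruta_select` — an all-relevant shadow-feature scheme around a random
   forest.  Each iteration appends a column-permuted ("shadow") copy of
   every undecided feature, fits a forest, and scores a *hit* for each real
   feature whose importance exceeds the maximum shadow importance.  Hits
   accumulate and a two-sided binomial test against p = 0.5 at level
   `alpha = 0.01` confirms or rejects features; leftovers after `max_iter`
   (default 100) are tentative and excluded.  Importance is the
   permutation importance normalised by its standard error
   (`MeanDecreaseAccuracy / importanceSD`), the documented default of the
   reference implementation of this scheme; the raw mean decrease is
   noticeably less sensitive for weak presence/absence effects.
2. `step_lda_select` — greedy forward stepwise selection by
   cross-validated LDA accuracy on a fold plan fixed up front.  Forward
   direction was chosen (over backward/both) for determinism and speed;
   the stop rule is *strict* improvement, so signal-free data terminates
   quickly.  Ties break by column order.
3. `rfe_select(ranker = "forest")` and
4. `rfe_select(ranker = "bagged_trees")` — recursive feature elimination:
   rank once by Gini importance on the full set, then evaluate nested
   top-k subsets by k-fold CV and return the smallest subset within one
   standard error of the best accuracy.  The bagged-tree ranker is the
   same ensemble with `mtry = p` (every feature available at each split),
   which is how a bagged CART ensemble arises as a special case of the
   forest.

Determinism: every selector is reproducible given its seed.  The stepwise
selector is additionally invariant to sample order when handed an explicit
per-sample fold plan, because LDA and the fold accuracies depend on the
data only as a set.  The forest-based selectors consume random numbers in a
row-order-dependent way (bootstrap indices, split sampling), so for them
the reproducibility contract is seed-determinism, not order-invariance.

## Classifiers

**Fisher LDA** (`fit_lda`) is implemented from first principles: pooled
within-class covariance $S$, weights $w = (S + \lambda I)^{-1}(\mu_1 -
\mu_0)$, score $s(x) = w^\top x - w^\top(\mu_0 + \mu_1)/2 +
\log(\pi_1/\pi_0)$, predict cancer iff $s \ge 0$, and positive-class
probability $\operatorname{plogis}(s)$ (the exact two-Gaussian posterior
under the equal-covariance model).  Numerical choices:

* **Ridge** $\lambda = 10^{-6} \cdot \overline{\operatorname{diag}(S)}$ by
  default.  Binary features in 60-sample training folds regularly produce
  singular pooled covariances; a diagonal ridge scaled to the mean variance
  fixes the conditioning without visibly moving the boundary.
* **Empirical class priors** by default.  With a 59/43 cohort this makes a
  signal-free LDA predict the majority class most of the time — the
  high-sensitivity / low-specificity operating point typical of this kind
  of study, and the reason the PSA-only permutation null sits near the
  majority rate 59/102 ≈ 0.58 rather than 0.5.
* **PSA preprocessing**: for LDA only, covariate columns are
  log-transformed and z-scored with training-fold statistics (PSA spans
  0.8–647 ng/mL; untransformed it would dominate the pooled covariance).
  The forest receives raw values — trees are invariant to monotone
  transforms.

**Random forest** (`fit_forest`) wraps the canonical CRAN implementation of
Breiman's algorithm (bootstrap samples, Gini splits on `mtry` random
candidate features, trees to purity), seeded for exact reproducibility.
Vote fractions are the positive-class score; exact 50/50 vote ties go to
the class with the larger training prior.

## Validation engines

`repeated_kfold_cv` is the flat scheme: 30 repeats × 10 stratified folds,
one metric record per *fold* (300 records).  Fold-level summaries are the
natural reading of six-number accuracy tables whose minima are values like
0.10 = 1/10 — only attainable on single folds of ~10 samples.

`repeated_double_cv` is the nested scheme: 30 outer repeats × 3 outer
folds; within each outer calibration set an inner loop (30 repeats × 10
folds) picks hyperparameters (forest `mtry`, LDA ridge), the tuned model is
refit on the calibration set, and the 3 outer test folds are pooled into
one confusion matrix → one record per *outer repeat*.  Per-repeat pooled
test sets (~34 samples each fold, 102 pooled) are what make per-repeat
sensitivities like 0.35 representable.

The **inner tuning grid** for the forest is
`floor(seq(sqrt(p), p, length.out = 3))` (for a 4-feature panel: 2, 3, 4),
mirroring the reference ML framework's documented default of three `mtry`
values from 2 to p.  `mtry = 1` is deliberately excluded: with one random
candidate per split the trees barely use the data and their votes collapse
toward the training majority; measured on permuted labels, an `mtry = 1`
forest scores 0.564 mean accuracy against 0.516 at `mtry = 2`, and an
accuracy-driven tuner then picks the degenerate setting almost every
permuted repeat, inflating the null by ~0.03 and breaking its calibration
against the fixed-marginal chance agreement.  The LDA grid is the ridge
multiplier {1e-6, 1e-3}; the two candidates give indistinguishable
accuracy on binary panels and tuning them is inert.

**Monte-Carlo permutation nulls** (`monte_carlo_null`): at the start of
each repeat the class labels are randomly permuted — class sizes 59/43 are
preserved exactly — and the *full* scheme (fold construction, inner
tuning, refitting) runs on the permuted labels.  The feature panel is held
fixed rather than re-selected per permutation, because the procedure being
nulled permutes only the labels of an analysis whose panel was chosen once.
The reference level for these nulls is the fixed-marginal chance agreement
$p^2 + q^2$ (`chance_agreement`), which for 59/43 is 0.5123; this quantity
is sometimes rounded to 52 % in the biomarker literature, but
$(59^2 + 43^2)/102^2$ has no reading that gives exactly 0.52, so the exact
value is reported.
An empirical-prior classifier's null sits slightly *above* this level
(majority leaning), and a PSA-only LDA null sits near the majority rate
itself; both behaviours are asserted by the test suite.

`selection_mode = "nested"` re-runs feature selection inside every outer
calibration set.  The default is `full_data` — panel chosen once before
CV — matching a design that reports a single final panel; the test suite
demonstrates on signal-free data why nested selection is the honest
variant (full-data selection followed by CV scores above chance, nested
rdCV does not).  Degenerate cases: an inner training fold that loses a
class is skipped and logged; an empty nested selection falls back to all
filtered features.

**Fold construction** (`make_folds`): sizes differ by at most one;
stratified mode (default) distributes each class's surplus to the
currently smallest folds so both the per-class counts and the overall
sizes stay within one.  A class smaller than the fold count degrades to a
plain partition with a warning.

Seeds cascade: master seed → per-repeat seed → per-fold model seed
(`derive_seed`), so a single repeat can be reproduced in isolation and
identical master seeds give bit-identical metric streams.

## Synthetic cohorts

`generate_cohort` emulates the *structure* the analysis assumes, not any
real patient data: 59 cancer / 43 control samples; 150 binary VOC features
drawn independently per sample given class; 4 planted discriminative
features — three present in 60 % of controls but 30 % of cases
(down-regulated, the direction this literature reports most often) and one
reversed — 20 rare (< 20 % both classes) and 20 ubiquitous (> 90 % both
classes) features positioned to be removed by the prevalence filter; 106
background features with a shared class-independent prevalence drawn from
(0.25, 0.85); and log-normal PSA with class medians 6.2 / 10.2 ng/mL and
log-SDs 0.75 / 1.1, heuristics chosen so simulated ranges at n ≈ 50
resemble 0.8–30 and 3.4–647 ng/mL.  PSA is independent of the VOC flags
within class, and features are independent given class: the planted effect
sizes give a detectable-but-imperfect signal (observed accuracies in the
0.6–0.7 range rather than ~1), which is the regime the validation
machinery is meant to discriminate from chance.

What passing tests on these cohorts do *not* show: robustness to VOC-VOC
correlation, batch or storage effects, urine-dilution artefacts, or any
real joint distribution of PSA with the volatilome.  The generator is a
calibration instrument for the pipeline, not a simulator of urine.

## Problem sizes used by the test-suite

The suite runs the production-scale schemes (30 repeats) only where a
calibration claim depends on them; engine unit tests use 2–3 repeats and
40–150 trees, selector recovery uses 150-tree ensembles over 20 cohorts,
and oracle checks use closed forms on 30–60 samples.  These sizes are the
package's choice of a fast, convincing default; all engines accept the
full-scale settings unchanged.

## Known limitations

* Two classes only; no multiclass discriminants, no probability
  calibration beyond the LDA posterior / vote fraction.
* The permutation null permutes labels of the whole scheme; permuting only
  held-out labels (a cheaper variant that appears in some pipelines) is
  not implemented.
* Accuracy is the tuning criterion, as in the design this follows; under
  class imbalance a kappa-based tuner would be less majority-leaning.
* `selection_mode = "full_data"` is the default for fidelity, not because
  it is recommended practice — use `"nested"` for honest error estimates
  when the panel is not fixed a priori.
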