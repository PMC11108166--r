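---
title: "Evaluating binary classifiers on small datasets: repeated nested CV and permutation testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating binary classifiers on small datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rncv)
```

## The problem

With a few dozen observations, the score of a binary classifier is a
noisy and easily biased quantity. Three failure modes dominate:

* **Optimistic selection bias.** Tuning hyperparameters or selecting
  features on the same data that produces the reported score inflates
  it, sometimes drastically.
* **Fold-draw variance.** On small data, the result of a single
  cross-validation depends visibly on how the folds happened to be
  drawn; a single train/test split is worse still.
* **Coincidentally good scores.** Even with no feature–label dependency
  at all, small datasets regularly yield scores well above chance. A
  score alone carries no information about how likely that is.

This package combines the three established remedies into one
evaluation: *nested* cross-validation isolates model selection from
evaluation, *repetition* across fold seeds averages out the fold draw,
and a *permutation test* attaches to every evaluation an empirical
probability that the score would arise with the feature–label link
severed — the analogue of a p-value for the null hypothesis "there is no
exploitable dependency in this dataset".

## The evaluation procedure

**Nested CV (nCV).** An outer stratified $n$-fold CV (default
$n = 10$) estimates generalisation performance. Within each outer
training partition, an exhaustive grid search evaluates every
hyperparameter combination with an inner stratified $k$-fold CV
(default $k = 5$), fitting the full pipeline per inner fold. The best
combination (ties: first in declaration order) is refitted on the whole
outer training partition and scored once on the held-out fold. The nCV
score is the mean over outer folds. The positive class is always the
minority class of the full dataset, which keeps asymmetric metrics
comparable across evaluations; exact ties resolve to the class that
sorts first.

**Repeated nCV (rnCV).** The nCV is repeated $r$ times (default 5) with
different fold seeds and the repeat means are averaged. By construction
the rnCV score is *exactly* the arithmetic mean of its component nCV
scores — the package asserts this identity in its tests. The spread
(min, max, sd) of the repeat means is reported as a direct measure of
fold-draw sensitivity.

**The pipeline.** Inside every training partition, in this order:
mutual-information feature selection (optional), standardisation,
random oversampling of the minority class (optional), SVM. Every
statistic is computed from the training rows only; test rows pass
through the frozen transforms and are never oversampled. The default
grid spans $C \in \{0.1, 1, 10\}$,
$\gamma \in \{0.1, \mathrm{scale}, \mathrm{auto}\}$ and the four
kernels (linear, RBF, polynomial, sigmoid) — 36 combinations — plus
10–30 selected features in steps of 5 when selection is tuned.
`scale` resolves $\gamma$ to $1/(d \cdot \mathrm{Var}(X))$ with the
population variance of the matrix that actually reaches the kernel
(i.e. after standardisation and oversampling), `auto` to $1/d$. With
tuning off the defaults are $C = 1$, RBF, $\gamma = \mathrm{scale}$.

**The permutation test.** $N$ label permutations of the whole dataset
are drawn once. The original data and every permuted copy are evaluated
with the *same* repeat seeds and fold machinery, and the probability is
the add-one estimate

$$p = \frac{1 + \#\{\text{permuted scores} \ge \text{original}\}}{1 + N},$$

with ties counting against the original. The floor is $1/(N+1)$ — with
$N = 50$ the smallest reportable probability is $1/51 \approx 0.02$ —
and $p = 0$ is unattainable, as it should be for an empirical test.
Because the same permutations feed both the per-seed nCV probabilities
and the rnCV probability, the difference between the two is entirely
attributable to the aggregation: averaging repeats before the
comparison damps the fold-draw noise on both sides, so the rnCV
probability is typically lower (never anti-conservative — the test
remains valid, as the calibration test on null data checks). $N = 25$
is enough for qualitative sweeps and $N = 50$ for single-dataset
reports, but small $N$ systematically *overestimates* $p$; for
publication-grade p-values use $N \ge 999$.

## Metrics

Eight metrics are supported for both tuning and evaluation (the two
always use the same metric): accuracy, balanced accuracy, precision,
recall, F1, MCC, Cohen's kappa and AUC. All but AUC are computed from
the fold's confusion matrix; AUC uses the SVM's signed decision values
(oriented towards the positive class) with mid-rank tie handling —
computing it from hard labels would collapse it onto balanced accuracy.
Two conventions matter:

* **Zero denominators give 0.** A degenerate prediction (e.g. all
  negative) makes MCC, precision, recall, F1 or kappa formally
  undefined; returning 0 keeps such classifiers at chance level and
  keeps permutation scores well defined. MCC dropping to exactly zero
  in a report is the typical signature of this convention.
* **Normalisation.** For cross-metric comparison, MCC and kappa are
  mapped from $[-1, 1]$ onto $[0, 1]$ via $(x+1)/2$; other metrics are
  already on $[0, 1]$.

Confusion matrices from all outer folds of all repeats are averaged
entry-wise (fractional entries allowed); the averaged entries sum to
$n / n_\mathrm{outer}$.

## The synthetic generator

`generate_balanced_gaussian()` draws class 1 as
$\lfloor n/2 \rfloor$ observations with 10 i.i.d. $N(0, 1)$ features
and class 2 as the remainder with $N(0.2, 1)$ features, then shuffles
the rows. The 0.2 mean shift over 10 features gives a Mahalanobis
separation of $\sqrt{10} \cdot 0.2 \approx 0.63$, i.e. a Bayes-optimal
accuracy of only about 0.62: deliberately weak signal, the regime where
evaluation methodology matters most. `generate_ensemble()` derives one
child seed per (size, replicate) from a master seed, so whole studies
reproduce from a single integer.

What the generator does *not* emulate: correlated or heterogeneous
features, categorical columns, class imbalance, label noise, and
features of differing importance. Passing the synthetic acceptance
suite therefore demonstrates the correctness and calibration of the
*evaluation machinery*, not robustness of any conclusion to real-data
pathologies — on real data the feature-selection and oversampling
stages, idle here, carry weight.

## Design and numerical choices

Choices the underlying procedure leaves open were fixed as follows:

* **Odd dataset sizes** split as $\lfloor n/2 \rfloor$ for class 1,
  remainder for class 2 — a fixed rule keeps generation deterministic.
* **Stratified folds**: within each class, rows are shuffled
  (seeded) and dealt round-robin; the leftover rows rotate across folds
  starting at a seeded offset, so fold sizes differ by at most one and
  every fold holds at least one row of each class. If the minority
  class has fewer rows than folds the call *fails*; choosing a smaller
  fold count is a deliberate, visible decision left to the caller.
* **Mutual-information estimator**: plug-in estimate on the
  contingency table, with continuous features discretised into at most
  10 quantile bins (columns with ten or fewer distinct values are used
  as-is). This is deterministic, which a nearest-neighbour MI estimator
  is not; ties rank the lower column index first.
* **Seed discipline**: one repeat seed governs all stochastic stages of
  its repeat (fold draws, oversampling draws, the refit's
  oversampling); child seeds derive via a modular multiply–add mix kept
  below $2^{31}$. Identical seeds reproduce every number bit-identically.
* **When tuning is ablated but selection is not**, the feature count is
  fixed to the default 10 (the smallest grid value) and the ranking is
  still computed per training partition — the ablation removes the
  *search*, not the stage. With both ablated, no inner CV runs at all.
* **Grid-search fit sharing**: the linear kernel does not involve
  $\gamma$, so its (C, $\gamma$) duplicates share one fit per inner
  fold. This is exact — scores are duplicated, declaration-order
  tie-breaking is unaffected — and saves one sixth of the grid's fits.
* **SVM backend**: the SVM is libsvm via e1071. Because this package
  refits tiny models at very high frequency, it calls e1071's
  registered C routines directly with pre-marshalled arguments
  (dense, two-class, no scaling — standardisation happens upstream),
  falling back to the public `e1071::svm()` when the symbols are not
  resolvable. The test suite asserts exact agreement of decision values
  between the two paths across random cases and all four kernels.

## Problem sizes in the shipped studies

The packaged tests and the acceptance script run scaled-down versions
of the full ensemble studies: 16 datasets of size 50 for the
probability-band and nCV-vs-rnCV comparisons (25 permutations, 5
repeats, the full 36-combination grid), and 50 null datasets of size 40
with a single-repeat nCV and the fixed default pipeline for the
type-I-error calibration check — the calibration property of a
permutation test does not depend on which (deterministic) pipeline is
being permuted, so the cheap fixed pipeline is used there. Larger
ensembles shrink the sampling error of these checks but change nothing
qualitatively.

## A worked example

```{r example, eval = FALSE}
ds <- generate_balanced_gaussian(50, seed = 1)
pt <- permutation_test(ds, pipeline_config(), metric = "mcc",
                       n_outer = 10, k_inner = 5, repeat_seeds = 1:5,
                       n_permutations = 50, seed = 1)
pt
compare_ncv_vs_rncv(pt)
```

The report shows the rnCV score with its repeat spread and the two
probabilities. A score near zero with $p \gg 0.05$ means the evaluation
found no evidence of exploitable structure — the expected outcome for a
single weak-signal dataset of this size; across an ensemble of such
datasets the *mean* probability is what falls in a narrow, reproducible
band.

## Known limitations

* Binary classification only; multi-class problems are out of scope.
* The classifier is an SVM; the evaluation machinery is
  classifier-agnostic in principle, but no other learner is wired in.
* Random oversampling is the only imbalance treatment (SMOTE-style
  synthesis is deliberately not implemented).
* Missing values are rejected, never imputed.
* The MI ranking's quantile binning is a simple stand-in for more
  refined estimators; for serious feature selection on mixed data,
  stronger methods are advisable.
* Permutation counts shipped in the defaults trade accuracy for time;
  they overestimate the probability and are meant for qualitative use.
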