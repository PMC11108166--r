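# rncv

Trustworthy evaluation of binary classifiers on **small tabular
datasets**: repeated nested cross-validation with an empirical
null-hypothesis probability from a shared-permutation test.

## Why

With tens of observations rather than thousands, three things go wrong
with the usual "train/test split + report a score" workflow:
hyperparameter tuning and feature selection leak into the reported
score; the score depends visibly on how the folds (or the single split)
were drawn; and scores well above chance arise regularly even when the
features carry no information about the labels at all. This package is
for practitioners — in education research, clinical pilot studies,
any small-*n* discipline — who need to know not just *what* a
classifier scored but *how probable that score is under no
feature–label dependency*.

## What it computes

* **Nested CV (nCV)**: an outer stratified 10-fold CV for evaluation
  around an inner stratified 5-fold exhaustive grid search over an SVM
  pipeline (mutual-information feature selection → standardisation →
  random oversampling → SVM; every statistic fitted on training rows
  only). The positive class is always the minority class of the full
  dataset.
* **Repeated nested CV (rnCV)**: the nCV repeated across fold seeds
  (default 5); the reported score is the mean of repeat means (an exact
  identity), and the repeat spread quantifies fold-draw sensitivity.
* **Shared-permutation test**: *N* whole-dataset label permutations are
  drawn once and evaluated with the identical machinery; the
  probability of the null hypothesis is

  $$p = \frac{1 + \#\{\text{permuted} \ge \text{original}\}}{1 + N},$$

  with floor 1/(N+1) — at N = 50 the best attainable probability is
  ≈ 0.02. Because permutations are shared, the per-seed nCV
  probabilities and the rnCV probability differ only by the
  aggregation method, and the rnCV probability is typically the lower
  (more powerful) of the two.
* **Eight metrics** — accuracy, balanced accuracy, precision, recall,
  F1, MCC, Cohen's κ, AUC — used consistently for both tuning and
  evaluation, with confusion-matrix averaging across folds and
  repeats, plus ensemble sweeps with percentile-bootstrap CIs and
  ablation studies of the pipeline components.

## Worked example

```r
library(rncv)

ds <- generate_balanced_gaussian(50, seed = 1)   # 10 features, Δmean = 0.2
ds
#> <rncv_dataset 'gaussian_n50_seed1': 50 x 10, classes class1:class2 (25:25)>

pt <- permutation_test(ds, pipeline_config(), metric = "mcc",
                       n_outer = 10, k_inner = 5, repeat_seeds = 1:5,
                       n_permutations = 25, seed = 1)
pt
#> <permutation test (25 permutations): mcc = 0.0775, p_rncv = 0.3462, p_ncv_averaged = 0.4077>

compare_ncv_vs_rncv(pt)
#>       score    score_min score_max   score_sd    p_rncv p_ncv_averaged
#> 1 0.0774915 -0.009175171 0.2466326 0.09944147 0.3461538      0.4076923
```

Reading the numbers: the rnCV estimates MCC ≈ 0.08 on a dataset whose
class means differ by only 0.2 per feature — barely above chance, and a
single nCV could have returned anything from −0.01 to 0.25 depending on
the fold draw (`score_min`/`score_max`). The permutation test puts the
probability of the null hypothesis at 0.35: this *single* dataset gives
no significant evidence of exploitable structure, which is exactly the
honest answer at n = 50 with this little signal. Note the rnCV
probability (0.346) is smaller than the averaged single-nCV probability
(0.408) — averaging repeats before the comparison makes the test more
powerful, at no cost in validity. The averaged confusion matrix is in
`pt$original$confusion`; its entries sum to n / n_outer = 5.

A command-line front end with subcommands `generate`, `evaluate`,
`sweep`, `ablation` and `metrics-report` ships in `inst/cli/rncv.R`:

```sh
Rscript inst/cli/rncv.R evaluate --dataset data.csv --label outcome \
    --metric mcc --permutations 50 --seed 1
```

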