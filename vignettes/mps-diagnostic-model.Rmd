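---
title: "Building a diagnostic gene score: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a diagnostic gene score: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsdiag)
```

# The problem

Given bulk expression profiles of diseased and healthy tissue (the motivating
application is hypertrophic cardiomyopathy versus normal myocardium), we want
a small gene signature and a single per-sample score that separates cases
from controls and transfers to an independent cohort. `mpsdiag` implements
one complete recipe for this:

1. **Preprocess** probe-level data to one row per gene (highest-median
   probe), then standardize each gene to a Z-score (the *Gene_Score*).
2. **Screen** differentially expressed genes (DEGs) by fold change and
   Welch-test significance.
3. **Select** characteristic genes by iterative random-forest elimination:
   genes with negative out-of-bag (OOB) permutation importance are deleted
   and the forest refitted until no importance is negative; ten independent
   cycles vote, and genes appearing in more than three terminal sets are
   kept.
4. **Train** a feed-forward neural network with a single hidden node on the
   characteristic-gene Z-scores, then **collapse** it to a linear score:
   each gene's weight is the product of its input-to-hidden weight and the
   hidden-to-output weight (*Gene_Weight*), and the molecular prediction
   score of a sample is
   $$\mathrm{MPS} = \sum_g \mathrm{Gene\_Score}_g \cdot \mathrm{Gene\_Weight}_g.$$
5. **Evaluate** by ROC/AUC on the training cohort and on an independent
   validation cohort, aligning the signature to the genes the validation
   cohort actually measures.

Every stage is exposed as a function; `run_all()` orchestrates the whole
flow from a single seeded configuration, and the numbered scripts under
`analysis/` run it stage by stage on simulated cohorts.

# The synthetic cohorts

Real accession data are deliberately out of scope: the package ships a
generator whose output has known ground truth, so every stage is testable.
`synthetic_spec()` describes a cohort on the log2 scale: per-gene baseline
means drawn uniformly from `[4, 14]` (a typical microarray log2 range,
which also makes the probe-median collapse non-trivial), i.i.d. Gaussian
noise with `noise_sd` (default 1 log2-unit), and `n_informative` genes whose
case mean is shifted by `effect_size`, half up and half down — emulating the
mix of up- and downregulated disease genes in real case/control series.

The default study conditions, used by the end-to-end tests and the
acceptance script, are 500 genes, 40 cases vs 40 controls, and 20
informative genes at 2 log2-units with unit noise: a strong but not trivial
signal, sized so a full run finishes in seconds. The generator separates the
*structure* seed (which genes are informative, baseline means) from the
*sampling* seed, so a validation cohort can share the planted biology of the
training cohort while being statistically independent — the usual
train/validate design. A Gaussian noise model on the log2 scale is an
assumption, not a property of any particular platform; the generator does
not emulate batch effects, missing values, count-type mean-variance
relationships, or correlated co-expression modules. Passing tests therefore
demonstrate correctness of the machinery and calibrated behaviour under this
model, not performance on any real dataset.

# Differential screening

The screen classifies each gene as `up`, `down` or `stable`:
`up` requires $\log_2\mathrm{FC} \ge \log_2(1.5)$ **and** $p < 0.05$,
`down` the mirrored condition. Because the input is already log2-scale,
the fold change is the difference of group means. Both thresholds are
arguments; the boundary conventions ($\ge$ for fold change, strict $<$ for
p) are fixed.

The test is a self-implemented Welch two-sample t-test, vectorised over
genes, checked against `stats::t.test` in the test suite. A moderated
(variance-shrinkage) test would be the usual choice for small cohorts, but
it brings hyperparameters of its own; the plain Welch test keeps the screen
self-contained and exactly reproducible from the formulas. Degenerate genes
are handled by convention: if both groups have zero variance, $p = 1$ when
the means agree and $p = 0$ when they differ. Raw p-values are used by
default (no multiple-testing correction), matching the screening design this
pipeline reproduces; `adjust = "BH"` is available. On null data the flagged
fraction at $p < 0.05$ sits inside the binomial band around 5% — the type-I
calibration the acceptance checks assert.

# Random-forest consensus selection

Forests are fitted with `randomForest` (500 trees, $\lfloor\sqrt p\rfloor$
candidate variables per split, Gini splitting). The importance driving
elimination, however, is computed by this package: for every tree that
splits on a gene, the tree's accuracy on its own OOB samples is compared
with the accuracy after permuting that gene's values *within those OOB
samples*; the importance is the mean decrease over all trees. This is the
raw (unscaled) mean decrease accuracy — the scaled variant divides by a
standard error that plays no role in the elimination rule. Trees that never
split on a gene contribute exactly zero. The implementation walks the stored
tree structures in vectorised R and is verified in the tests both against
`predict(rf, predict.all = TRUE)` (exact agreement of tree traversals) and
against `randomForest`'s own unscaled `MeanDecreaseAccuracy` (rank
agreement; the two use different permutation draws, so exact equality is
not expected).

Elimination deletes genes with *strictly negative* importance — zeros are
kept — and refits until none remain, which must happen within
`gene count + 1` iterations because the set strictly shrinks. Each of the 10
consensus cycles runs this loop under its own seed (cycle seeds are
`base_seed + 0 … + 9`; per-iteration forest and permutation seeds are
derived deterministically from the cycle seed), so cycles genuinely differ
yet the whole selection is reproducible bit for bit. "Appeared more than
three times" is read literally as $\ge 4$ of 10 cycles
(`min_appearances = 4`, configurable). If no gene reaches the threshold the
selection errors out rather than returning an empty signature.

# The one-hidden-node network and its linearization

The network is logistic-sigmoid in both the hidden and the output unit,
trained on mean binary cross-entropy (squared error is available) by
full-batch gradient descent: at most 200 iterations (the conventional
`maxit` for this architecture), base learning rate 0.1, stopping early when
the loss improves by less than `1e-8`. The loss function is a declared
choice — the design this package reproduces specifies only a generic
per-sample loss — as are the optimizer, the uniform $[-0.5, 0.5]$
initialization, and the zero default weight decay; all are surfaced in
`training_config()`. If a gradient step would increase the loss, the step is
halved until it does not (plain backtracking), which guarantees the recorded
loss history is non-increasing without changing the descent direction.
Back-propagated gradients are validated against finite-difference quotients
(`gradient_check()`, central differences at $\varepsilon = 10^{-6}$ agree to
better than $10^{-5}$; this check runs in the test suite, not merely as an
offered utility).

With one hidden node the trained network collapses to a linear score:
dropping both biases and the monotone activations leaves
$\mathrm{Gene\_Weight}_g = W^{(1)}_g \cdot W^{(2)}$. This is the unique
reading of "delete the biases and hidden-layer weights" that yields one
weight per gene. Because the discarded links are monotone, the MPS ranking
equals the network-output ranking exactly when the biases are zero, and in
practice the two AUCs agree closely on trained nets (the acceptance checks
allow a 0.05 gap; the end-to-end runs typically show 0). Case is encoded as
1, so a positive weight means higher expression pushes toward disease. With
more than one hidden node the collapse is undefined and
`extract_gene_weights()` refuses.

# Scoring and evaluation

`zscore()` standardizes with the sample ($n-1$) standard deviation and
errors on zero-variance genes. By default each cohort is standardized with
its own statistics — scoring a validation cohort does not require the
training cohort to be present, which matches how transferred signatures are
usually applied; the stricter alternative (training-fitted means/sds via
`reference_stats`) is one configuration switch. Signature genes missing from
a validation cohort are dropped and reported, never imputed.

`roc_curve()` sweeps thresholds over the unique scores in descending order
(case-positive: predict case when score $\ge$ threshold), so tied scores
form a single vertex, and integrates by the trapezoid rule.
`auc_mannwhitney()` computes the same quantity as a rank statistic with ties
half-credited; the two routes agree to $10^{-12}$ on random instances with
and without ties, which is the package's AUC correctness argument (plus a
`pROC` cross-check in the tests). An AUC below 0.5 is reported as-is with a
warning — silent score flipping would hide sign errors in the weights.

`tf_subnetwork()` filters a TRRUST-dialect regulator→target edge table to
edges pointing at characteristic genes (optionally: touching them at either
endpoint); it is plain deterministic filtering, sorted output, self-loops
kept but flagged.

# Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the full pipeline at the
default study conditions (500 genes, 80 samples, 10 consensus cycles of
500-tree forests) in well under a minute on one core; the type-I calibration
uses 10,000 null genes. One master seed drives every stage through derived
sub-seeds, and re-running any configuration reproduces every output file bit
for bit — the run manifest records the resolved configuration and all stage
seeds needed to do so.

# Known limitations

* The synthetic model is Gaussian, independent across genes; real
  co-expression, batch structure and platform effects are absent.
* Selection precision is bounded by the DEG screen: false-positive DEGs
  that genuinely correlate with the labels in the training sample can
  survive consensus voting; an independent cohort is what exposes them.
* On null data the pipeline may legitimately end with an empty selection
  (an error by contract) when no gene clears the consensus threshold.
* The linearized score discards the output nonlinearity; it preserves
  rankings (hence ROC/AUC), not calibrated probabilities.
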