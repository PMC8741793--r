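---
title: "Methods: multi-omics classification of atopic dermatitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics classification of atopic dermatitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adclassify)
```

## The problem

Atopic dermatitis (AD) is a chronic inflammatory skin disease of early
childhood whose clinical diagnosis requires dermatological expertise.
Host–microbe interactions in the gut are implicated in AD, which motivates
predicting case–control status from two stool-derived molecular profiles:
a gut-epithelial transcriptome (microarray probe intensities, tens of
thousands of features) and a gut microbiota profile (phylum/genus-level
16S relative abundances, a few hundred features). The statistical
challenge is the usual one for omics classifiers: far more features than
samples (a cohort of ~161 children), so the pipeline is built around
cross-validated feature selection, regularisation by jittering, and a
strictly held-out test set.

`adclassify` implements that pipeline end to end: data alignment and
imputation, stratified splitting, min-max normalization, a chi-square
feature scorer implemented from its matrix definition, recursive feature
elimination and forest-importance rankers, two cross-validated selection
plans, four integration strategies for fusing the modalities, four
classifier families with probability-threshold tuning, and
confusion-matrix / ROC evaluation. A synthetic cohort generator with
planted signal makes every stage testable without access to any cohort.

## Cohort assembly

Each modality is a sample-by-feature table. Alignment applies three rules:

* samples with transcriptome data and a label are kept;
* a kept sample lacking a microbiota row is flagged and later filled by
  **mean imputation** (each missing cell gets the feature's mean over the
  observed samples), which is unbiased when values are missing completely
  at random (MCAR) — a reasonable stance for a single dropped assay;
* samples with only microbiota data are dropped: imputing ~45,000 probe
  intensities from nothing would dominate the sample's signal.

Imputation runs **before** normalization, so imputed rows participate in
the per-feature min/max like any other sample; this mirrors the order in
which the steps are naturally performed (alignment, then scaling). The
sample order of the cohort follows the transcriptome table, which makes
alignment deterministic.

## Preprocessing

**Stratified split.** The cohort is split into training and test sets so
that the case:control ratio is preserved: each class contributes its
largest-remainder share of the test size. For 161 samples (88 cases / 73
controls) and a test size of 30, this forces 131 training samples and a
test set of 16 cases + 14 controls. Within-class sampling is uniform and
seed-determined.

**Min-max normalization.** Per feature,
$x' = (x - \min x) / (\max x - \min x)$, mapping every feature onto
$[0, 1]$. Non-negativity matters downstream: the chi-square scorer treats
values as mass and is undefined for negative input. A constant feature
maps to 0 everywhere (the formula is 0/0 there; the zero convention keeps
chi-square defined and drops the feature from contention). By default the
training and test sets are normalized **together**, replicating the
classical workflow this package mirrors; because joint scaling lets
held-out rows influence the transform, a `train_only` scope is also
provided, which fits min/max on the training rows and applies it to both.
Both modes are tested; selection itself never sees held-out rows in
either mode.

**Jittering.** Gaussian noise $s \sim N(0, \sigma^2 I)$ with
$\sigma^2 = 1$ is added to the training transcriptome block as a
regulariser. The notation is ambiguous about whether the intensity $I$
is a variance or a standard deviation; the default convention reads
**variance = I** (so sd $= \sqrt I$), and `sd_equals_I` selects the
alternative. The default intensity is 0 (off); the worked configurations
use $I = 0.001$, the level that performed best in the study this package
follows. Jitter is never applied to microbiota data — roughly 70% of
taxon cells are zero, and additive noise would destroy that structure.
In the orchestrated pipeline jitter is applied to the normalized training
block (noise on the unit scale), immediately before feature selection;
since the operation is plain matrix addition it can equally be applied
pre-normalization by calling `add_jitter()` directly.

## Feature scoring and selection

**Chi-square scorer.** For binary labels expanded to a one-hot indicator
$Y \in \{0,1\}^{n \times 2}$ and non-negative data $X$:

$$f_{obs} = Y^T X, \qquad
  f_{exp} = \text{class\_prob}^T \cdot \text{feature\_count}, \qquad
  \chi^2_j = \sum_{c=1}^{2} \frac{(f_{obs,cj} - f_{exp,cj})^2}{f_{exp,cj}}$$

i.e. per feature, a two-cell goodness-of-fit statistic comparing how the
feature's total mass distributes over the classes against the class
frequencies. This is authored directly from the matrix formulas (it is
the pipeline's core scorer); the test suite cross-checks it against
`stats::chisq.test` goodness-of-fit calls on random matrices to 1e-10.
Zero-mass features score 0 by convention.

**Other rankers.** Recursive feature elimination (RFE) repeatedly refits
a base model exposing per-feature weights — absolute ridge-logistic
coefficients, linear-SVM weights $|w| = |\alpha^T SV|$, or forest
importances — and removes the weakest 10% (at least one) of the remaining
features until one is left; rank is reverse elimination order. An rbf
SVM has no per-feature weights and is rejected with a pointer to the
linear kernel. Forest importance ranking reads mean Gini decrease from a
seeded `randomForest`.

**Ties.** All score ties break lexicographically on feature ID, and in
RFE the lexicographically later ID is eliminated first, so rankings are
total orders and bit-reproducible.

**The k-schedule.** Candidate feature counts start at all features and
shrink by 10% per step — `k -> max(1, floor(0.9 k))` — down to 1. The
source procedure states the 10% reduction without a rounding rule; floor
with a guard of 1 keeps the sequence strictly decreasing, finite and
duplicate-free (44,608, 40,147, 36,132, ...).

**Plan B (default).** One stratified five-fold CV on the training set.
Per fold, features are ranked on the fold-training block (the ranking
does not depend on k, so it is computed once per fold); for each candidate
k the classifier is refit on the top k and scored by F1 on the fold's
validation block. The chosen k maximises mean validation F1, ties
resolving toward **smaller** k (parsimony). The final set is the top-k of
the ranking on the full training set. Plan B is the default because the
final worked configuration in the source procedure selects its 35 probes
this way.

**Plan A.** A 5-by-5 nested CV: each outer training split runs the Plan-B
search internally to pick its k, ranks on the whole outer split, and
contributes a top-k set; the final set is the intersection of the five
sets. An empty intersection (never reported by the source, but possible)
falls back to features present in at least four of the five sets and is
flagged loudly in the result.

**Importance floor.** `threshold_select()` rescales scores by their
maximum and keeps features at or above a floor (0.95 in the worked
configuration, which yields the 35-probe set). The floor is interpreted
on max-rescaled chi-square scores, since the published importance plot
carries no units; this interpretation is documented rather than assumed
silently.

**Integration strategies.** (1) microbiota only, (2) transcriptome only,
(3) concatenate columns then run one selection (early fusion),
(4) select per modality then concatenate (late fusion). Strategy 4 with
targets 35 + 50 reproduces the 85-feature combined classifier. Provenance
records each retained feature's modality.

## Models and thresholding

Four families behind one interface: ridge-penalised logistic regression
(`glmnet`, $\lambda = 1/n$ by default, mirroring the L2 default of the
scikit-learn implementation the source used; an unpenalised fit is
undefined at $p > n$), SVM with linear or rbf kernel (`e1071`, with
Platt-scaled probability outputs; the internal calibration CV is seeded
for determinism), random forest (100 trees), and gradient-boosted trees
(`xgboost`, 100 rounds, depth 6, single-threaded for reproducibility).
Hyperparameters were not reported by the source, so library defaults are
used and every value is overridable through `classifier_spec()`.

A sample is called a case when its predicted probability **strictly
exceeds** the threshold $p_t$ (default 0.5). `tune_threshold()` picks
$p_t$ from a grid (default 0.1–0.9 by 0.1) by cross-validated F1, ties
resolving toward 0.5 and then toward the smaller value; 0.3 is the value
the worked configurations use.

## Evaluation

Confusion counts follow the case-control layout (a = TP, b = FN, c = FP,
d = TN), and the four metrics are the printed formulas: precision
$a/(a+c)$, recall $a/(a+b)$, accuracy $(a+d)/n$, F1 $2a/(2a+b+c)$.
Zero-denominator metrics return 0 with an explicit `degenerate` flag
rather than raising, so CV sweeps survive degenerate folds. The ROC curve
sweeps the unique predicted probabilities in descending order (positive
call at probability ≥ threshold) with sentinels at (0,0) and (1,1); AUC
is the trapezoidal area of that exact step curve, which the suite verifies
equals the Mann–Whitney pairwise-ranking probability to 1e-10.

## The synthetic cohort generator

No cohort data are deposited, so `generate_cohort()` stands in.
Its defaults are the study conditions: 88 cases and 73 controls, 44,608
probes, 366 taxa, one sample missing each modality; 35 planted
differential probes and 50 planted differential taxa (the sizes of the
selected feature sets). Where the source states no distributional facts,
the choices are conventions of the field, made once and documented here:

* **Transcriptome:** per-probe Gaussian on the log scale, exponentiated
  (log-normal intensities, mean log 6, sd-log 0.3–0.8), so min-max
  normalization is exercised on skewed positive data. Signal probes shift
  the case mean by `probe_effect` log-scale standard deviations
  (Cohen's d; default 1.0, a moderate-to-strong single-feature effect).
* **Microbiota:** per-taxon gamma draws with log-normal concentrations,
  normalised per sample to sum to one (Dirichlet-style composition), then
  an independent Bernoulli zero mask (default rate 0.7, in the range
  typical of genus-level tables) applied after normalization. Signal taxa
  scale case concentrations by `taxa_effect` (default 3).
* Ground-truth signal IDs are emitted for tests only; the pipeline never
  reads them.

What the generator does **not** emulate: probe cross-hybridisation,
phylogenetic correlation between taxa, compositional renormalisation
after zeroing, or age confounding. Planted-signal cohorts are therefore
*easier* than the real one — with 35 probes at d = 1.0 the synthetic
classifier approaches perfect test metrics — so passing tests demonstrate
correctness and recoverability of the machinery, not expected clinical
performance.

## Numerical and design choices

* All randomness is seeded; `run_experiment()` derives stage seeds
  (split, selection, model, jitter) from one master seed and writes them
  to a YAML run log from which `replay_run()` re-executes the experiment
  bit-identically.
* Selection operations receive only the training partition; the suite
  verifies bit-identical selection under mutation of held-out rows.
* Jittered training data are clipped at 0 before chi-square scoring
  (noise can dip a normalized value below zero).
* Constant features normalize to 0 and hence score 0; duplicate feature
  IDs are rejected at construction, and feature IDs must be unique across
  modalities before fusion.
* Problem sizes in the test suite and acceptance script are chosen for
  desk-scale runtimes: oracle checks use 100 random small matrices,
  planted-recovery experiments use 1,000 probes at n = 160 over 5
  generations, and the end-to-end acceptance run uses the full
  161 × 44,608 + 366 cohort shape with fixed selection targets (35 + 50),
  which keeps the cross-validated stages inexpensive.

## Worked example

```{r example, eval = FALSE}
cfg <- experiment_config(
  synthetic = synthetic_config(seed = 1),
  strategy = "select_then_combine",
  n_transcriptome = 35L, n_microbiota = 50L,
  model_family = "svm_rbf",
  jitter_intensity = 0.001, p_t = 0.3,
  seed = 1
)
report <- run_experiment(cfg)
report
tidy(report)
autoplot(report)
```

## Limitations

* The real cohort is not available; nothing here reproduces the published
  feature identities (probes/taxa), only the procedure that selects them.
* The exact train/test partition and fold seeds of the original analysis
  are unrecoverable; seeds are exposed but make no claim of matching.
* Joint normalization (the faithful default) leaks min/max statistics
  from the test set; use `normalization_scope = "train_only"` when that
  is unacceptable.
* No confidence intervals are attached to AUC or F1, and no alternative
  imputation schemes (kNN, MICE) are provided.
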