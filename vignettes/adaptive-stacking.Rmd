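---
title: "Adaptive stacking: diversity-aware ensemble construction for binary risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive stacking: diversity-aware ensemble construction for binary risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adastack)
```

## The problem and the model

Stacked generalization combines several base classifiers by training a
second-stage *meta-learner* on their predictions. Which base classifiers to
combine is usually decided ad hoc, typically by taking the strongest models.
The error-ambiguity decomposition says that is only half the story: the
ensemble's error equals the average member error *minus* the members'
ambiguity (diversity), so members should be accurate **and** make different
mistakes. `adastack` operationalises this for binary tabular classification,
with survey-style health data — binary risk indicators, ordinal scales, one
continuous measure, a balanced binary outcome such as diabetes status — as
the reference use case.

The construction has four stages:

1. **Accuracy screen.** Every candidate family in the zoo is evaluated by
   k-fold cross-validated F1 on the training split; the selection threshold
   λ is the mean of those F1 values (or an explicit number), and only models
   with F1 strictly above λ survive. With a heterogeneous zoo this keeps the
   better-than-average half.
2. **Diversity pruning.** On the survivors' out-of-fold correctness
   patterns, the pairwise Q-statistic
   \(Q_{ik} = (N_{11}N_{00} - N_{01}N_{10}) / (N_{11}N_{00} + N_{01}N_{10})\)
   measures dependence: |Q| near 1 means the two models succeed and fail on
   the same samples and one of them is redundant. While any pair exceeds the
   cutoff τ_Q, the pair member with lower cross-validated accuracy is
   dropped (greedy, largest |Q| first). This rule reproduces the reference
   behaviour in which, of three highly dependent boosting models, the most
   accurate one is retained.
3. **Out-of-fold stacking.** For each surviving base, k stratified
   fold-models are trained; each predicts its held-out fold, and the blocks
   are stacked vertically into one out-of-fold column per base — no training
   sample is ever predicted by a model that saw it. The same fold-models
   predict the test split and their k prediction vectors are averaged
   element-wise.
4. **Meta-learner traversal.** Each candidate family is evaluated by k-fold
   CV F1 on the stacked training matrix; the argmax is refitted on the full
   matrix. A fixed logistic-regression meta-learner is available as the
   traditional-stacking baseline.

Evaluation uses the confusion-count metrics (accuracy, precision, recall,
F1 as the harmonic mean of precision and recall) plus AUC in the
rank/Mann–Whitney formulation, which is exact under ties.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `f1_threshold` | `"mean"` | accuracy screen level λ; `-Inf` disables |
| `q_cutoff` (τ_Q) | 0.9 | prune pairs with \|Q\| above this; 1 disables. 0.9 flags only near-duplicates; no published cutoff exists, and lower values trade member accuracy for diversity |
| `folds` (k) | 5 | CV folds for selection, stacking and meta-traversal |
| `train_fraction` | 0.8 | stratified train/test split (8:2) |
| `meta_candidates` | `"selected"` | traverse the surviving families; `"all"` or fixed `"lr"` available |
| `meta_feature_type` | `"proba"` | probabilities carry more information than hard labels; a label mode exists |
| attribution `cutoff` | 0.1 | mean-\|Shapley\| feature filter on the log-odds scale |

Survival is strict (`F1 > λ`) so that, with an explicit λ equal to a
model's F1, that model is excluded. Ties in pruning drop the later model in
matrix order; meta-traversal ties break by higher CV accuracy, then
candidate order. Selection metrics are pooled out-of-fold estimates on one
shared fold assignment — shared folds are what make two models' correctness
patterns comparable sample by sample, and out-of-fold (rather than
resubstitution) correctness avoids rewarding overfit agreement.

## The model zoo

Ten families sit behind one train/predict-probability contract: k-nearest
neighbours (`class`), RBF support vector machine with Platt-scaled
probabilities (`e1071`), random forest (`randomForest`), logistic
regression (`stats::glm`), CART decision tree (`rpart`), a single-hidden-
layer perceptron (`nnet`, 100 units by default), and four gradient-boosting
variants served by the `xgboost` library configured as the algorithm each
name denotes: `gbdt` (exact greedy, depth-3 trees, η = 0.1), `xgboost`
(library defaults), `lightgbm` (histogram binning with leaf-wise/loss-guide
growth, 31 leaves), and `catboost` (histogram depth-wise growth with strong
L2 regularisation and column subsampling). No hyperparameter tuning is
performed; defaults are conventional values and everything is overridable
per spec. All fits are seeded; each spec derives a distinct seed from the
master seed.

## Feature filtering by Shapley attributions

A GBDT (100 trees, depth 3, η = 0.1 — conventional defaults, configurable)
is fitted to the label and every feature's global contribution is the mean
absolute per-sample Shapley attribution of the model's raw margin
(log-odds), the standard reading of global attribution bars. Features below
the cutoff (default 0.1 on that scale) are dropped; the filter is fitted on
the training split only and the surviving feature list is frozen for the
test split, a deliberate divergence from pipelines that filter before
splitting, to avoid selection leakage.

Attributions come from the tree-path-dependent Tree SHAP implementation
built into `xgboost`. Two numerical caveats are documented rather than
hidden: (i) the additive decomposition holds on the margin scale to
single-precision accuracy (~1e-6), and (ii) path-dependent Tree SHAP
weights tree branches by training *cover*, which for logistic loss is
hessian-weighted; it therefore coincides with the interventional
(uniform-background) Shapley value exactly only for additive ensembles with
unit-hessian losses. The test suite exploits this: depth-1 squared-error
ensembles are compared against an exhaustive \(O(2^N)\) interventional
Shapley oracle to machine precision, while deeper logistic models are
checked through local accuracy, determinism, null-signal and
duplicated-feature symmetry properties.

## The synthetic generator

`simulate_brfss()` emulates the 21-feature diabetes-health-indicators
schema (14 binary indicators, ordinal GenHlth 1–5, MentHlth/PhysHlth 0–30,
Age 1–13, Education 1–6, Income 1–8, continuous BMI 12–98, balanced binary
label, public-dataset column names). Labels are drawn first at the
configured balance; features are drawn conditional on the label: binary
indicators from a logistic model whose log-odds shift by the feature's
effect between classes, ordinal scales by binning a label-shifted latent
normal at equal-probability cut points, BMI from a label-shifted log-normal
clipped to range. Default effect sizes mimic the direction and relative
strength of known diabetes risk associations (general health, BMI, age and
blood pressure strong; the care-access indicators and alcohol near zero, so
the default table reproduces the qualitative outcome of the reference
feature filter). A latent shift of size *e* against noise σ = 1 yields a
per-feature AUC of Φ(e/√2) before discretisation, which the tests use as a
closed-form check.

What the generator does **not** model: the real survey's feature–feature
correlation structure (features are conditionally independent given the
label), missing data, and sampling weights. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal — not performance claims on the real survey, whose headline numbers
additionally depend on unreported hyperparameters.

## Problem sizes and numerical conventions

The test fixtures use a few hundred rows with a reduced-capacity zoo
(logistic regression, tree, KNN, small boosted ensembles) and 3–5 folds;
generator-validation tests use 2,000–4,000 rows. These sizes are chosen so
that planted-signal checks have comfortable statistical margins while the
whole suite stays quick; the construction itself is size-agnostic.

Degenerate cases follow explicit conventions, each flagged with a warning:
0/0 metric denominators return 0 (keeps selection well-defined for
classifiers that never predict a class); a zero Q denominator — e.g. a
perfect classifier in the pair — returns Q = 0 (keeps the pruning loop
total); constant features min–max-normalize to 0. Min–max normalization is
fitted on training rows only. An empty post-threshold survivor set or an
all-removed feature filter is an error that names its pipeline stage, not a
silent fallback. F1 for the published precision/recall pair is checked via
exact integer confusion counts rather than floating division of printed
decimals.

## Known limitations

- Two layers only; no regression targets; no online updating.
- The `lightgbm`/`catboost` family keys are xgboost-backed implementations
  of those boosting styles, not bindings to the upstream libraries; with
  default settings on small tabular data all four boosting variants can be
  highly correlated, which the Q-pruning stage will then collapse — that is
  the intended behaviour, not a defect.
- Q-statistics are computed from hard-label correctness only, per the
  method's definition, even when the stack itself consumes probabilities.
- KNN resolves distance ties stochastically; predictions are seeded for
  reproducibility but remain tie-dependent across data permutations.
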