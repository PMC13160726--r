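---
title: "Progressive residual fusion for block-missing clinical data: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive residual fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical risk models for elderly populations routinely face *modular*
missingness: variables arrive in examination panels (a DXA scan yields the
whole bone-mineral-density panel or none of it; a blood draw yields the
whole biochemistry panel or none of it), and different patients complete
different subsets of panels. Complete-case modelling discards most of the
cohort; single-block modelling discards most of the information; global
imputation invents values for whole panels at once.

`profuse` implements a third strategy: a *progressive fusion chain*. The
variables are grouped into an ordered sequence of modality blocks
$x^{(1)}, \dots, x^{(T)}$, block 1 being the most widely available (for
the motivating application: demographics, then bone mineral density, bone
turnover markers, biochemistry, hemoglobin, HbA1c). Stage 1 fits an
ordinary probabilistic classifier

$$\hat y^{(1)} = f_1(x^{(1)}),$$

and each later stage refines the running prediction with the next block:

$$\hat y^{(t)} = f_t\!\left(x^{(1:t)},\ \hat y^{(t-1)}\right),
  \qquad t = 2, \dots, T.$$

Stage $t$ is trained only on the samples observed for blocks $1..t$
("stage eligibility"), with minority-class oversampling per stage because
the eligible subsets drift in class balance. At prediction time each
sample runs to the deepest stage its observed *prefix* of blocks permits:
a patient with only demographics receives the stage-1 estimate; a fully
examined patient receives the depth-$T$ estimate. A gap stops the chain —
stage $t$ consumes $x^{(1:t)}$, so a sample missing block $t$ cannot use
block $t+1$ even if observed. The consequences of that rule are
quantified below ("Known limitations").

## The residual stage, and why the package's default differs from the obvious one

The recursion above leaves $f_t$ underdetermined. The package implements
three refinement modes.

**`prob_residual` (default).** Stage $t$ regresses the probability-scale
residual $r = y - \hat y^{(t-1)}$ on $[x^{(1:t)}, \hat y^{(t-1)}]$ and
outputs $\hat y^{(t)} = \operatorname{clip}(\hat y^{(t-1)} + \hat r)$.
Its decisive property: the *population-optimal* corrector is
$E[y \mid x] - \hat y^{(t-1)}$, which is exactly zero when the new block
carries no information and the prior is calibrated. An uninformative
stage is therefore a fixed point of the chain.

**`logit_residual`.** Stage $t$ regresses
$r = \operatorname{logit}(\operatorname{clip}(y, \varepsilon)) -
\operatorname{logit}(\hat y^{(t-1)})$ and outputs
$\sigma(\operatorname{logit}(\hat y^{(t-1)}) + \hat r)$. This looks like
the more literal "residual on the logit scale", but it is intrinsically
mis-calibrated: with hard labels clipped at $\varepsilon$, the optimal
corrector given a calibrated prior $p$ is
$|\operatorname{logit}\varepsilon| \,(2p - 1) - \operatorname{logit} p$,
which is far from zero *even when the new block is pure noise* — the mode
systematically sharpens probabilities toward 0/1. Empirically a constant
new block moves held-out probabilities by ≈0.12 mean absolute difference
regardless of sample size. The mode is retained for comparison, and its
accuracy-level behaviour is still sound (hard labels at threshold 0.5 are
insensitive to sharpening), but it is not the default. This is a
deliberate deviation from the "regress logit-scale residuals" design that
a first reading of the recursion suggests; the derivation above is the
reason.

**`stacking`.** Stage $t$ re-classifies $y$ from
$[x^{(1:t)}, \hat y^{(t-1)}]$. Simple and strong, but a tree-based stage
approximates the prior by step functions, so it cannot reduce to the
identity on an uninformative block either.

Two further mechanisms make the default mode behave as the fixed-point
argument promises at finite $n$:

* **Cross-fitted ("honest") priors.** If stage $t$ trains against the
  in-sample predictions of stage $t-1$, those priors hug the labels
  (stage $t-1$ saw these rows), so probability-scale residuals are near
  zero and the new block's signal is masked. `fit_chain()` therefore
  refits the previous stage on half-splits and feeds each training row a
  prior from the half-model that did not see it; inference always uses
  the actual full previous-stage model. (The half-refits consume the
  in-sample prefix below stage $t-1$ — a second-order approximation that
  trades exactness for tractability.)
* **1-SE early stopping of the residual ensemble.** The residual
  regression's tree count is chosen by 2-fold staged validation MSE under
  the one-standard-error rule, with "no correction at all" as an explicit
  candidate. A block with no supportable evidence yields the identity
  stage exactly; a block with real signal clears the bar and keeps its
  trees. This is the same conservatism as `rpart`'s and `glmnet`'s 1-SE
  conventions, applied to stage depth.

## Stage models

No tree-ensemble, SVM or random-forest package is assumed to exist in the
installation environment, so the learners are part of the package, built
on one exact-greedy least-squares regression tree in C++:

| family | implementation | resolved defaults |
|---|---|---|
| `gbt` | gradient boosting, logistic loss + per-leaf Newton step (classification) or squared loss (regression) | 100 trees, learning rate 0.1, depth 3, `min_split` 10, `min_leaf` 5 |
| `decision_tree` | single tree; variance splitting on 0/1 responses is equivalent to Gini | depth 30, `min_split` 2, `min_leaf` 1 |
| `knn` | exact Euclidean k-NN, probability = neighbour vote share | k = 10 |
| `naive_bayes_gaussian` | per-class Gaussian factors | variance smoothing 1e-9 |
| `logistic` | ridge-penalised IRLS, intercept unpenalised | λ = 1 |
| `svm_poly` | polynomial-kernel ridge classifier + Platt-scaled probabilities | degree 3, coef0 1, γ = 1/p, λ = 1 |

The 100-tree / 0.1-learning-rate boosted ensemble mirrors the strongest
baseline configuration of the motivating study; the shallow depth-3 tree
is a package choice (standard for boosting, and it keeps a six-stage
chain fit at cohort scale in seconds). `svm_poly` deserves a note: with
no quadratic-programming solver available, the "SVM with polynomial
kernel" slot is filled by a kernel ridge classifier with Platt scaling —
a margin-style method with the same kernel and calibrated probabilities,
with every resolved hyperparameter recorded in the fitted config.
Continuous features are standardised (train statistics only) for the
distance/margin/linear families and never for trees.

## The synthetic cohort generator

The generator emulates the *structure* the method assumes, with defaults
transcribed from the published baseline table of a 1,287-record
hip-fracture case/control cohort: per-class means and SDs for 26
continuous variables, per-class proportions for 4 binary variables,
two categorical variables, six modality blocks, prevalence 643/1287, and
per-block availability from the published block-level sample counts
(class-independent by default; a `class_dependent` switch uses the
published per-class counts, under which e.g. the fracture class has BMD
available for only 27% of samples).

What it deliberately does **not** emulate:

* **Joint dependence.** Continuous variables are independent Gaussians
  within class (only marginal moments are published). An optional
  within-block equicorrelation exists for stress tests. Real BMD panels
  are strongly internally correlated.
* **Category frequencies.** Marital-status and ethnicity frequencies are
  not published; plausible values for an elderly urban Chinese cohort are
  used, identical across classes, so they carry no signal.
* **Missingness dependence.** Blocks are masked *independently* per
  sample given the class. Real examination pathways are closer to
  monotone (patients who get a blood draw tend to get the full workup);
  this difference matters — see "Known limitations".
* **Physiological support.** Gaussian draws may be negative for
  physically positive variables; a truncation switch exists for realism
  demos but models do not care.

Two transcription notes: the published table prints a control-cohort
total-hip T-score mean of +0.7553 where every sibling value is negative —
likely a sign typo, but the printed value is kept (it only strengthens
that block's signal); and the published hemoglobin per-class counts
(206 + 425) do not sum to the block total (751), so availability is
exposed as free parameters with both variants available.

A green test on this generator therefore establishes that the chain
machinery extracts block-wise signal under the stated class-conditional
structure — not that the package reproduces the real cohort's numbers,
which are not publicly available.

`plant_signal(params, block, d)` rewrites a block's continuous variables
to unit-SD Gaussians separated by `d` standard deviations and flattens
the block's binary/categorical class differences, so `d` is exactly the
block's signal; `d = 0` makes a block pure noise. This is the lever used
by the monotonicity, no-harm and ordering tests.

## Evaluation suite

Standard definitions throughout: confusion metrics at threshold 0.5 (tie
→ positive; undefined precision reported as 0 with a flag); AUC as the
pairwise concordance probability with ties at ½ (rank form, verified
against exhaustive enumeration in the tests); percentile bootstrap CI
with 2,000 stratified resamples at 95% by default (the source study
reports a CI but no method; stratification keeps every resample
two-class); Brier score; ECE with 10 equal-width right-closed bins
(binning unstated in the source; declared, not inferred); decision-curve
net benefit $TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and
treat-none on the grid $p_t = 0.01, \dots, 0.50$ (the degenerate 0 is
excluded).

## Baseline regimes and imputation

Three regimes frame the comparison: `max_sample` (block-1 features, all
rows), `complete_case` (all features, fully observed rows; a typed error
below 10 training samples per class), and `imputed` (random-forest
chained imputation in the missForest style). The 70/30 split is
stratified by default — the source protocol does not say; stratification
stabilises small-fold class balance and a switch restores simple
splitting. Imputation is fit on training rows only, with a
`impute_whole_table` sensitivity switch reproducing the
impute-before-split reading. Imputation forests are bagged trees with
*no* feature subsampling and leaves of size 1: imputation wants
conditional-mean fidelity, not decorrelation, and this is what lets an
exactly duplicated column be reproduced to 1e-6.

## Numerical and procedural choices

* Probability clipping ε = 1e-6 on every emitted probability; no
  non-finite value can surface.
* Every stochastic component derives its own sub-seed from the run seed
  through a labelled hash (`seed_stream`), so components are
  independently reproducible and adding one never perturbs another.
* Modality ordering: greedy forward selection over the non-pinned blocks
  (the study pins demographics and BMD at positions 1–2), scored by
  stratified 5-fold accuracy within the training table; ties keep
  declaration order; the test set never enters.
* Sequential ablation is prefix truncation of the fitted chain (no
  refit); single-removal ablation retrains with one block deleted and the
  surviving order intact. Accuracy is the ablation criterion, matching
  the source tables; full metric reports are still emitted.
* CLI outputs never embed timestamps; a rerun with the same config
  byte-reproduces every file, and the manifest records the config hash
  and the full seed set.

## Known limitations

* **The strict-prefix rule discards non-prefix information, and under
  independent block availability that is a lot.** With the published
  class-dependent availabilities (~0.2–0.8 per block) masked
  independently, about half of all samples have an availability *gap* —
  on synthetic cohorts the mean number of observed blocks is ≈3.6 but
  the mean usable prefix is ≈2.4. An imputation-based model uses those
  observed-but-unreachable blocks; the chain does not. In the package's
  20-seed regime-dominance experiment the imputed-regime boosted ensemble
  accordingly beats the chain (mean held-out accuracy 0.939 vs 0.913),
  the opposite of the source study's finding on its real cohort — whose
  missingness was evidently far more nested (455/1287 complete cases,
  against ~0.5% expected under independent masking). The experiment
  documents this honestly rather than adjusting the generator to
  manufacture a win; the corresponding acceptance test is red and says so
  in its failure message.
* Under class-dependent availability the complete-case regime is
  infeasible outright (about one complete fracture-class training sample
  expected at n = 2000); it is reported as infeasible, which itself
  mirrors the feature-count/sample-size trade-off the method targets.
* The depth-monotonicity and no-harm experiments set availability to 1:
  under independent masking essentially no fracture-class sample survives
  to depth 6, which would make depth-wise comparison vacuous.
* Honest priors are cross-fitted one stage deep; levels below the
  previous stage enter in-sample. The residual-stage early stopping is
  conservative by construction (1-SE rule): on weak true signal it will
  sometimes select the identity stage.
* No time-to-event or multi-class outcomes; no per-patient reordering of
  blocks; no deep-learning stage families.
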