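---
title: "Labeling and predicting nociceptors from MEA spike trains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeling and predicting nociceptors from MEA spike trains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
conventions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices that matter when reproducing results.

## 1. The response metric and its null

Each sorted unit contributes one number per recording: the **max-bin
absolute change in mean firing rate**. The baseline window (default
`[0, 300)` s) and the treatment window (default `[300, 600)` s) are parsed
into 30-s bins; within each window the bin with the greatest spike count
defines that window's representative MFR, and

ΔMFR = max-bin MFR(treatment) − max-bin MFR(baseline)   [Hz].

Conventions that affect the number:

* **Half-open windows `[t0, t1)` everywhere.** A spike exactly at the
  treatment time belongs to the treatment window; nothing is counted
  twice.
* **Trailing partial bins are dropped, never rescaled**, so the max-count
  comparison always runs over equal-width bins. A window shorter than one
  bin is an error.
* **Ties between bins break toward the earliest bin**; bin indices are
  1-based (R convention).
* The **sign of ΔMFR is preserved**: an agonist responder is positive, a
  silenced unit negative. The metric is an absolute difference (Hz), not a
  percent change — percent change explodes for near-quiescent units and is
  deliberately out of scope.

The **null distribution** of ΔMFR comes from untreated sister cultures
run through the same arithmetic with a *pseudo-treatment* boundary at the
same clock time: with no compound added, ΔMFR fluctuations reflect only
the natural transience of the culture. The null is pooled across all
untreated wells (single aggregate fit), matching the pooled-plate scale of
the workflow.

## 2. Kernel density labeling

The null is summarised by a plain Gaussian-kernel density estimator

f̂(x) = (1/(n·h)) Σᵢ K((x − xᵢ)/h),

where the xᵢ are the n untreated ΔMFR values. Choices:

* **Bandwidth.** Silverman's rule of thumb in its robust form,
  h = 0.9·min(SD, IQR/1.349)·n^(−1/5). The robust form is the canonical
  rule for possibly heavy-tailed data (max-bin differences of bursty
  units are heavy-tailed); `fit_kde(reference, bandwidth =)` overrides
  it. If the IQR is zero while the SD is not, the SD alone is used; a
  sample with zero spread is an **error** — the caller must not silently
  substitute a bandwidth.
* **Threshold.** Every treated unit *and* every untreated unit is scored
  under the fitted model. The cutoff is the 10th percentile
  (linear-interpolation empirical percentile, `quantile(type = 7)`) of the
  *untreated units' own density scores*, and the comparison is strict
  (`density < threshold`): a unit must fall below the bulk of the null to
  be labeled. Raising the percentile can only grow the labeled set.
* **Directionality.** The density criterion alone is two-sided — a
  strongly silenced unit also has low density under the null. Because the
  labeling stimulus is an agonist and responders are expected to fire
  *more*, the default adds `require_positive_delta = TRUE`. The flag is
  exposed so the literal density-only rule is one switch away;
  `label_units()` records both the threshold and the fitted model as
  attributes.
* **Self-calibration.** Applying the rule to the untreated set itself
  labels (up to percentile interpolation and ties) exactly the threshold
  fraction — the property the test suite checks at n ≈ 620.

Numerical contracts: `kde_density()` agrees with the direct summation of
the estimator to ≤ 1e-12 relative error (it *is* the direct summation,
evaluated in blocked vectorised form), densities are non-negative, and the
numerical integral over [min − 10h, max + 10h] lies in [0.999, 1.001].

## 3. Baseline phenotype features

Features are computed from the **entire baseline period**, never from the
30-s response bins — the response defines the label, the baseline defines
the phenotype, and keeping them on disjoint statistics avoids the label
leaking into the training features.

* **`mfr_hz`** — spike count / window length.
* **`isicv`** — sample SD (n−1 denominator; configurable to population)
  of consecutive inter-spike intervals over their mean. 0 for clock-like
  firing, ≈1 for Poisson, >1 for bursty. Undefined below 3 spikes.
* **`sync_median`, `sync_skewness`** — the median and adjusted
  Fisher–Pearson skewness G1 = √(n(n−1))/(n−2) · m₃/m₂^1.5 of the unit's
  pairwise spike-synchronization values against every other unit in the
  same well. Pairs never cross wells. Zero-variance pairwise values give
  skewness 0 by convention; fewer than 3 valid pairs leave the features
  undefined.

**Spike synchronization** is the adaptive-coincidence measure: for each
spike the coincidence window τ is half the minimum of the four adjacent
ISIs (its own preceding/following and its nearest counterpart's
preceding/following); the spike is coincident iff its nearest counterpart
lies strictly within τ; the pair's value is the mean coincidence indicator
over all spikes of both trains. It is symmetric, bounded in [0, 1], 1 for
identical trains, and parameter-free — the coincidence window adapts to
the local firing rate. At the train boundaries the distance to the window
edge serves as the surrogate ISI (auxiliary-spike convention), which makes
single-spike trains well defined. A pair with an empty train is undefined
and excluded from aggregation.

A subtlety worth knowing: the measure's *chance level* depends on firing
regularity. Independent near-regular trains sit near 0.3 (quasi-periodic
spikes lock to each other), independent bursty trains near 0.1 (burst-
internal ISIs shrink τ). Interpreting synchrony contrasts between groups
of different regularity therefore requires planted common input to be
strong enough to dominate this chance-level gradient — which drove the
generator parameterisation below.

**Exclusion policy.** Units failing a feature precondition (fewer than 3
baseline spikes, fewer than 3 valid pairs, no baseline spikes at all) are
excluded from the feature table and listed with reasons in the
`exclusions` attribute — never imputed. Silent zeros would manufacture
spurious subtype contrasts.

## 4. The synthetic study generator

`synth_config()` defines the study conditions; `generate_study()` emits a
treated and an untreated session plus per-unit ground truth. Design:

* **Gamma-renewal trains** with per-unit rate (log-normal by subtype) and
  shape k (ISI CV = 1/√k), so ISICV is a controllable subtype feature
  rather than a by-product.
* **Synchrony by mother-process thinning**: each well owns a Poisson
  mother process (default 1.5 Hz); a unit copies each mother spike with
  its per-unit probability p (jittered by Gaussian SD 1.5 ms) and fires an
  independent renewal component carrying the rest of its rate. Responders
  draw p from a dense Beta(6, 2); non-responders from a sparse, right-
  skewed Beta(0.4, 2.3) — most barely participate, a few strongly.
* **Planted response**: in treated sessions, ground-truth responders
  multiply their *total* rate by `response_gain` (default 4) from
  treatment time plus a uniform [0, 10] s onset latency (droplet
  diffusion); the mother contribution is unchanged, so the renewal
  component absorbs the gain. Untreated sessions have no rate change and
  all-non-responder ground truth, but the same phenotype mixture — the
  untreated culture is just as heterogeneous.
* **Scale**: 14 wells per condition, units per well uniform in 26–62
  (mean 44), so a default study totals ~620 units per condition — a
  realistic full-plate screening run; prevalence defaults to 0.3682
  (independent Bernoulli per unit), a typical TRPV1-positive fraction.
  Rates: responders median 2.0 Hz, non-responders 0.6 Hz (sdlog 0.5);
  shapes: k = 0.4 vs 0.9.

At these defaults ground-truth responders show higher baseline MFR, ISICV
and median pairwise synchrony (Mann–Whitney p < 0.05 at n ≥ 150/group),
the contrasts the downstream analysis assumes. Two honest caveats:

* The pairwise-synchrony **skewness** contrast is *not* reproduced: the
  chance-level gradient described in §3 dominates the within-unit pairwise
  distribution, so non-responders do not come out right-skewed relative to
  responders at these defaults. The feature stays in the classifier (its
  direction is irrelevant to AUC), but tests assert only the three
  reproduced contrasts.
* The generator emulates renewal statistics, common input and a
  multiplicative rate response. It does **not** emulate waveform shape,
  electrode mixing or sorting errors, network bursts with refractoriness,
  adaptation, or dose–response structure. Passing tests therefore show
  the *pipeline* recovers what was planted under the stated statistical
  structure — not that real cultures satisfy that structure.

Determinism: every public entry point takes a seed; sub-seeds for
simulate/train/evaluate stages derive from the master seed through a fixed
affine map (kept below 2³¹), so identical configs produce byte-identical
artifacts.

## 5. The imbalance-aware classifier panel

With ~37% nociceptors the classes are moderately imbalanced; the core
learner handles this by resampling, the reference panel by weighting.

**RUSBoost** (`train_rusboost()`): per boosting round, the majority class
is randomly undersampled to a 1:1 ratio with the minority; a CART tree
(depth ≤ 3 by default, Gini, no complexity pruning) is fitted on the
resample under the current boosting weights; the weighted error ε is
computed on the *full* training set; the learner weight is
α = learning_rate · log((1−ε)/ε); misclassified examples are upweighted
by e^α and the weight vector renormalised. Rounds reaching ε ≥ 0.5 are
discarded and resampled (bounded retries), a perfect round stops boosting
early. Scores are the logistic transform of the additive margin
F(x) = Σₘ αₘ(2pₘ(x) − 1) — the standard probability calibration for
adaptive boosting — so `score ≥ 0.5` coincides with a positive weighted
vote and the confidence scale `max(score, 1 − score)` is meaningful for
the retention curve.

**Reference models** (`train_reference_models()`): logistic regression
(`glm`), LDA (`MASS::lda`, equal priors), a KNN random-feature-subspace
ensemble (`class::knn`, 15 subspaces of 2 of the 4 features, vote
fractions reweighted by class weight) and a small feed-forward network
ensemble (5 × `nnet`, 8 hidden units, decay 0.1). All four upweight the
minority class by inverse prevalence. Every model exposes the same
`score_units()` interface with scores in [0, 1].

**Hyperparameters.** Documented search spaces: tree depth 1–8, rounds
50–500, learning rate 0.01–1 (log scale), undersample ratio fixed 1:1;
k 1–25 and subspace dimension 2–3 for KNN; hidden sizes 4–64 (log scale)
for the FNN. `tune_hyperparameters()` runs seeded random search over these
spaces (flagged `method = "random_search"` in its output), scoring
candidates by inner 5-fold CV AUC. Tuning is *non-nested* — tuned once on
the training partition, then cross-validated — and flagged as such; with
four features and ~600 units the documented defaults are close to optimal
and `run_pipeline()` uses them unless given a budget.

**Validation.** `crossval_auc()` runs stratified k-fold (default 10; class
proportions within one unit per fold) and returns per-fold AUC for each
family; `compare_models()` applies the Kruskal–Wallis rank test (tie-
corrected) at α = 0.05 and reports "no model outperforms" when p ≥ α.
`split_holdout()` holds out whole wells (default 2) so within-well
synchrony structure cannot leak across the split; the no-leakage property
is verifiable by group-id disjointness and asserted in tests.

**Evaluation.** `evaluate_holdout()` reports the confusion matrix at the
0.5 score threshold, accuracy, per-class F1, AUC (midrank concordance:
ties count one half) with the full ROC curve, impurity-decrease feature
importances aggregated over the ensemble by learner weight, and the
confidence–retention curve. Because a natural-prevalence holdout and a
class-balanced one answer different questions, the report carries both
(the balanced subsample is seeded). Positive class is `nociceptor`
throughout.

## 6. Problem sizes and runtime envelope

The test suite and acceptance script are sized to run on a laptop-class
single core: the full default study (~620 + ~620 units, ~13k within-well
pairs) builds its feature table in ~30 s; the five-model 10-fold CV adds
~20 s; enumeration oracles (synchronization, Mann–Whitney, AUC
concordance, stump splits) run on ≤ 6-spike trains, ≤ 8-per-group samples
and ≤ 200-unit score sets. Property tests use fixed seeds; statistical
assertions state explicit bands (e.g. null calibration 10% ± 2 points at
n ≈ 620, type-I error ≤ 0.06 at nominal 0.05 over 2000 replicates).

## 7. Known limitations

* KDE labels are themselves noisy ground truth (≈1% false positives by
  construction at the 10th percentile, more under weak responses);
  classifier metrics inherit that noise.
* The percentile rule labels a *fixed fraction* of a same-distribution
  sample by design; it is a calibrated outlier detector, not an estimator
  of prevalence when the true responder fraction is near 0 or 1.
* The synchronization chance level confounds regularity with coupling
  (§3); group contrasts in synchrony should be read jointly with ISICV.
* The boosted ensemble's probability calibration is the canonical
  logistic margin map, not isotonic/Platt recalibration on held-out data;
  confidence cutoffs are comparable within a model, not across models.
* Multi-class subtyping (more than one nociceptor form), dose–response
  modeling and graph-structured models of inter-unit correlation are out
  of scope.
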