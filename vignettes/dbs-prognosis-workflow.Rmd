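---
title: "Decision-tree prognosis workflows for pallidal DBS in childhood dystonia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree prognosis workflows for pallidal DBS in childhood dystonia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsdt)
```

## The clinical problem and the model

Pallidal deep brain stimulation (DBS) reliably helps children with isolated
genetic or idiopathic dystonia, but in acquired dystonia (dystonic cerebral
palsy and related etiologies) the benefit ranges from meaningful improvement
to none, and families must decide about surgery with little prognostic
guidance. This package implements a prognostic workflow built around binary
classification trees, chosen for three properties that matter in this
setting: they combine features non-linearly, they handle categorical
clinical features (etiology, neurophysiology status) natively without
numeric re-encoding, and every prediction is a short, auditable chain of
clinical conditions.

Six candidate features are considered: sex, etiology (six groups), baseline
dystonia severity on the Burke-Fahn-Marsden motor scale (BFMDRS-m, 0-120,
higher = more severe), cranial MRI class, and two neurophysiological tests
-- central motor conduction time (CMCT, corticospinal tract integrity) and
somatosensory evoked potentials (SEP, sensory pathway integrity). Each test
is recorded per limb (up to four) and coded to a patient-level status:
*abnormal* if any limb is abnormal, *NA* if no limb gave a technically
satisfactory recording, *normal* otherwise. The *NA* status is an ordinary
categorical level in the learning analyses, not a missing value: whether a
test could be completed is itself clinical information.

The outcome is the percentage improvement in BFMDRS-m from baseline to one
year after surgery, `100 * (baseline - followup) / baseline`, binarized
either at a strict `> 0%` rule (any improvement; used for the
acquired-dystonia analyses) or at the inclusive `>= 20%` literature cutoff
(used for the whole-cohort analysis). Both rules are exposed as a mode flag
because the two analyses genuinely use different boundary conventions. A
change of `>= 2` points on the Canadian Occupational Performance Measure
(COPM) is available as an alternative outcome definition.

## Tree induction

`fit_tree()` performs standard greedy recursive partitioning. Splits
maximize the weighted impurity decrease with the Gini index by default (the
de facto CART criterion; entropy is available). Continuous candidate
thresholds are midpoints between consecutive distinct sorted values, and a
value exactly at a threshold routes left (`<=`). Categorical splits
enumerate all `2^(m-1) - 1` binary partitions of the observed levels
exactly -- with at most six levels per feature this is at most 31
candidates, so exact enumeration is cheap and avoids any ordinal or one-hot
encoding. A split is admissible only if both children contain at least
`min_leaf` patients (default 10, the minimum end-node size used throughout
the search analyses). Growth stops at purity, at `max_depth`, when a node
is smaller than `2 * min_leaf`, or when no admissible split has positive
gain.

Determinism is a design requirement, so all ties are broken by fixed rules:
equal-gain splits prefer the earlier schema feature, then the lower
threshold, then the lexicographically smallest left level set; leaves with
tied class counts predict the *unfavorable* class, the conservative choice
for surgical counseling (configurable via `tie_label`). A categorical level
never seen at a node during training is routed with the node's majority
child and a warning.

Two consequences of the greedy positive-gain rule are worth knowing. First,
a perfectly balanced interaction (an exact XOR) gives every root split zero
gain, so the learner correctly declines to split; the interaction tests
therefore use class-balanced but cell-unbalanced configurations. Second,
hyperparameters are fixed defaults (`min_leaf = 10`, unlimited depth, Gini)
rather than tuned by an outer optimizer: at cohort sizes of order 100 a
stochastic hyperparameter search adds variance without reproducibility, and
the minimum-leaf constraint is the parameter that actually controls
complexity here.

## Feature-subset search and benchmarking

`run_search()` evaluates every non-empty subset of the features -- 63
subsets for the 6-feature schema, 31 when CMCT is excluded for the
SEP-fallback analysis -- with repeated k-fold cross-validation
(`repeated_kfold_cv()`, default 10-fold, 100 iterations). Each iteration
allocates every patient uniformly at random to one of `k` near-equal folds
(unstratified, matching random patient allocation; a stratified option
exists but is off by default). The iteration's accuracy pools correct
out-of-sample predictions across folds (`correct / n`) rather than
averaging per-fold accuracies, which is insensitive to unequal fold sizes;
the alternative aggregation is available as `aggregate = "fold_mean"`.
Subset results are reported as mean accuracy with the standard error over
iterations.

Every subset is evaluated under its own seed derived deterministically from
the master seed and the subset index (`derive_seed()`), so the whole search
reproduces bit-identically and adding or removing subsets does not perturb
the others. The benchmark is the majority-class classifier, whose accuracy
is the majority class proportion; a subset is only interesting if it beats
this baseline by more than its standard error. Subsets are ranked by mean
accuracy (ties: fewer features, then enumeration order), and the reported
feature frequencies count appearances in the top 10 models rather than
trusting a single winner -- with ~100 patients the identity of the single
best tree is fold-allocation noise, but the features shared by the whole
top group are stable.

`outcome_threshold_sweep()` repeats the search while moving the outcome
threshold from 0 to 5% to check that feature selection is robust to the
scale's limited inter-rater reliability. A threshold that leaves either
outcome class smaller than `2 * min_leaf` cannot support a single
admissible split, so it is flagged as performance degradation and skipped.

## The fixed counseling tree and the Monte Carlo cutoff sweep

The two features that consistently dominate the search -- CMCT and baseline
severity -- define a fixed two-node counseling tree (`fixed_tree_predict()`):
abnormal CMCT predicts an unfavorable prognosis outright; with normal CMCT
the prognosis is favorable iff baseline BFMDRS-m is *strictly above* a
severity cutoff. Equality at the cutoff is unfavorable; the strict rule is
a deliberate convention (the favorable/unfavorable phrasing is stated as
`>` / `<` and leaves the boundary open).

The cutoff is not a single number to be estimated but a dial the family and
clinician set. `mc_threshold_sweep()` quantifies the trade-off: patients
with CMCT unavailable are removed first (`filter_feature_available()`),
then `reps = 1000` resamples of `n_sample = 100` patients are drawn with
replacement from the pool, and sensitivity and specificity are computed at
every cutoff on a 0.5-point grid spanning the observed baselines. Per
cutoff the sweep reports the mean and one standard error (sample SD across
resamples divided by `sqrt(reps)`) -- the error bars on the published-style
curves. A resample with no positives (or no negatives) leaves sensitivity
(specificity) undefined; such resamples are excluded from that metric's
summary and counted in a diagnostics field rather than imputed.

The first split imposes hard limits independent of the cutoff
(`node1_bounds()`): sensitivity can never exceed `1 - P(abnormal CMCT |
favorable outcome)` and specificity can never fall below `P(abnormal CMCT |
poor outcome)`. These bounds hold *exactly within every resample* by
construction, and the sweep asserts this on every draw
(`bounds_respected`). `roc_points()` returns the per-cutoff
`(1 - specificity, sensitivity)` locus; no interpolated AUC is reported,
since ranking cutoffs by AUC is not the decision being supported.

## The synthetic cohort generator

The patient data behind this workflow are access-restricted, so
`generate_cohort()` produces synthetic cohorts with the statistical
structure the analyses assume, and the entire test suite runs against them.
The generator *defines* the study conditions; its defaults are fixed once:

* `n = 96` acquired-dystonia patients (or 133 with the genetic/idiopathic
  groups in `"full"` mode, 96/133 acquired), etiology drawn from the
  referral-table mix (`referral_etiology_table()`).
* CMCT status: not-available with probability 18/96, abnormal 0.20;
  SEP: not-available 0.4375 (54/96 with SEP among acquired), abnormal 0.30.
  Statuses are expanded to limb-level recordings that re-code to the drawn
  status exactly.
* Baseline BFMDRS-m: truncated normal, mean 70, SD 25, range [5, 120],
  rounded to the 0.5-point scoring resolution. No distributional
  information about the real baselines is published; these are field-
  plausible placeholders, and no test depends on them narrowly.
* Outcome: `pct = mu0 + beta_cmct * 1[abnormal CMCT] + beta_sev * max(0,
  baseline - s0) + N(0, noise_sd)` with `mu0 = 7`, `beta_cmct = -25`,
  `beta_sev = 0.8`, `s0 = 80`, `noise_sd = 18`. The hinge plants a
  recoverable severity cutoff at 80 points; the intercept is calibrated so
  about 60% of patients improve at the strict `> 0%` rule (the follow-up
  score is rounded to 0.5 points, which creates an atom at exactly 0%
  change counting as not improved -- the calibration accounts for this).
* Sex and MRI are pure noise by construction, so a sound search must *not*
  select them.

The generator emulates marginals and one planted dependence structure; it
does not model longitudinal trajectories beyond one year, COPM generative
structure, CMCT-SEP correlation, or site effects. Passing recovery tests on
these cohorts therefore shows the machinery is sound -- it does not
validate the clinical findings on real data, which require the restricted
cohort.

## Numerical and reproducibility choices

* Gains are compared with an absolute tolerance of `1e-12`; within it,
  the deterministic tie-break order applies.
* Every stochastic stage takes a seed; sub-seeds derive from
  `(master seed, stream index)` via a Lehmer-style map bounded by
  `2^31 - 1`. RNG state is saved and restored around all seeded code.
* Report files are written with fixed column order, fixed number
  formatting, no quoting and `\n` line endings, and JSON with unlimited
  digits, so identical configuration plus seed yields byte-identical
  outputs; the run manifest (config + seed + package version) is sufficient
  to reproduce any report.
* Zero denominators (metrics, percentage improvement at baseline 0) are
  errors or explicit `NA`s, never silent zeros.

Problem sizes in the shipped tests are chosen for a laptop-scale run:
parameter-recovery searches use cohorts of 500 with 20 CV iterations, and
Monte Carlo sweeps use the full 1000 resamples on pools of ~78; the split
oracle is verified exhaustively on 200 random 30-row tables.

## Known limitations

* Greedy induction, no cost-complexity pruning, surrogate splits,
  multiclass outcomes or ensembles -- interpretability of a single small
  tree is the point, and `min_leaf` is the complexity control.
* Accuracy is the only ranking criterion in the subset search, so the
  search inherits accuracy's insensitivity to error asymmetry; the
  sensitivity/specificity machinery exists precisely to expose that
  trade-off for the final tool.
* The search's repeated-CV standard errors describe fold-allocation
  variability, not sampling variability of the cohort itself.
* With ~100 patients, all conclusions about feature value are exploratory;
  the workflow is built to be re-run as multi-center data accumulate.
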