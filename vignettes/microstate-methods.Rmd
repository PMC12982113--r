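---
title: "Microstate analysis and response prediction: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis and response prediction: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
library(dplyr)
```

## The problem

Resting-state EEG can be described as a sequence of *microstates*: brief
(roughly 50–100 ms) intervals during which the scalp voltage topography stays
quasi-stable before switching abruptly to another configuration. Four
canonical classes (A–D) recur across healthy adults. In chronic insomnia the
temporal statistics of these classes — how much time each covers, how long an
average visit lasts, how often visits occur, and which class tends to follow
which — are candidate markers of hyperarousal and of treatment response.

`microstatr` implements the full analysis chain for such a study: a
synthetic-EEG generator with known ground truth, the standard preprocessing
chain, polarity-invariant microstate segmentation with two-level template
estimation, per-subject temporal metrics, group statistics, and a
baseline-feature treatment-response prediction stage. Because clinical EEG of
this kind is rarely shareable, every stage is testable end-to-end against the
generator's known truth.

## The segmentation model

Let $v_t \in \mathbb{R}^{C}$ be the average-referenced scalp vector at sample
$t$. The **global field power** is the spatial population standard deviation
$\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_c (v_{tc}-\bar v_t)^2}$; its local
maxima are moments of maximal topographic signal-to-noise. Segmentation
operates only on maps at GFP peaks (minimum peak separation 10 ms by
default).

**Modified K-means.** Microstate topographies are polarity-free: a map and
its negation describe the same state. Peak maps are therefore assigned to
the template maximizing the *squared* spatial correlation (Pearson across
channels of average-referenced maps, i.e. the cosine for zero-mean unit-norm
vectors), and each template is updated to the dominant eigenvector of the
sum of outer products of its assigned maps — the principal orientation,
which is defined only up to sign. Iteration stops when assignments stabilise
or the relative change in global explained variance (GEV) falls below
$10^{-6}$ (at most 300 iterations); an emptied cluster is re-seeded from the
worst-fit map. The best of 100 random restarts by GEV is kept, where

$$\mathrm{GEV} = \frac{\sum_{p} \mathrm{GFP}_p^2\, r_p^2}{\sum_p \mathrm{GFP}_p^2},$$

with $r_p$ the spatial correlation of peak $p$ with its winning template.

**Two levels.** Each subject's peak maps are clustered into $k = 4$ classes;
all subject templates are pooled and re-clustered across participants to
give group templates, which are labelled A–D by exhaustively matching all
$4!$ permutations against canonical archetype maps (ties broken
lexicographically) and then back-fitted to every subject's GFP peaks by
maximum absolute spatial correlation.

**From peaks to metrics.** Back-fitting labels only the peaks, but durations
are reported in milliseconds of continuous time. We adopt the standard
nearest-peak expansion: the boundary between two consecutive peaks lies at
their temporal midpoint, and the record edges belong to the first/last peak.
Maximal same-label runs are episodes, giving per class the **coverage** (%
of analyzed time), **duration** (mean episode length, ms) and **occurrence**
(episodes per second), plus the **organizational transition matrix**
(OrgTM): each ordered pair $X \to Y$ as a percentage of all observed
episode transitions (diagonal zero, entries summing to 100). No minimum
duration smoothing and no correlation threshold are applied by default, so
coverages sum to 100 exactly and coverage $=$ occurrence $\times$ duration
holds per class up to boundary effects; an optional `min_abs_corr` threshold
exists because published healthy-control coverages summing below 100 suggest
some tools leave poorly fitting time unassigned.

## The synthetic generator

The generator defines the study conditions under which the package is
validated:

* **Recording conditions.** 26 channels on a 10–20 montage (the vertex
  electrode Cz serves as recording reference and is not a data channel),
  256 Hz after downsampling, about 150 s of artifact-free eyes-closed data
  per subject.
* **Dynamics.** A Markov chain over four states with zero-diagonal
  row-stochastic transition matrix; segment (dwell) lengths are gamma with
  shape 2 and per-state mean 70 ms by default. The gamma choice (rather
  than the geometric dwell a first-order chain would imply) gives the
  unimodal positive dwell distributions seen in empirical microstate
  histograms; the mean is the calibrated quantity.
* **Signal.** The active template is modulated by a 10 Hz carrier (random
  phase per segment, log-normal amplitude, eyes-closed alpha dominance), so
  GFP peaks arrive at roughly twice the carrier frequency; spatially white
  Gaussian sensor noise is added with RMS(signal)/RMS(noise) = `snr`
  (default 2) on the average-referenced recording.
* **Topographies.** Canonical archetypes built as smooth gradients over the
  electrode positions: A runs left-posterior to right-anterior, B is its
  left-right mirror, C is a symmetric fronto-occipital gradient, D a
  fronto-central maximum. All are average-referenced, unit-norm and
  mutually distinct (max pairwise $|r| < 0.9$).
* **Cohort.** 19 controls and 41 patients by default; patient effects are
  applied to dwell means and transition probabilities (rows re-normalized),
  never to the topographies — mirroring the empirical finding that group
  template maps do not differ. Fourteen planted responders receive a
  partial post-treatment reversal of those effects plus baseline dwell
  shifts (the planted feature–response association). Clinical scales are
  drawn with the published group means and a planted pre-to-post
  improvement; the emitted PSQI columns recover the planted responder
  labels exactly under the 50%-reduction rule with either boundary
  comparator.

What the generator does **not** emulate: ocular/muscle artifacts, bad
channels, electrode drift, line noise (beyond what the notch test
synthesizes explicitly), the alternating eyes-open/closed block structure of
real acquisitions (a single continuous eyes-closed record is emitted), and
any spatial noise correlation. Passing closure tests therefore demonstrate
correctness of the analysis chain, not robustness to real-world artifacts;
artifact handling on real data is delegated to the `artifact_stage` hook.

## Preprocessing conventions

Resampling to 256 Hz is polyphase with anti-alias filtering. Filters are
4th-order Butterworth applied forward–backward (zero phase): band-pass
1–45 Hz, band-stop 48–52 Hz for line interference, and a secondary 2–20 Hz
band before microstate analysis, followed by re-referencing to the common
average. The filter family is a package choice — the conventional one —
since only the band edges are prescribed by the protocol being modelled.
Manual epoch rejection is replaced by an optional peak-to-peak amplitude
screen on 2-s epochs (disabled by default; synthetic data is clean), and
decomposition-based artifact removal is exposed only as a pluggable hook
because manual component curation is not reproducible computation.

## Group statistics

* **TANOVA.** Per class, each group is summarized by the polarity-free
  principal orientation of its subject maps (dominant eigenvector — exactly
  invariant to subject order and map sign); the statistic is the mean over
  group pairs of $1-|r|$ between these group maps, and the p-value comes
  from permuting group membership, $p = (1+\#\{\mathrm{null}\ge
  \mathrm{obs}\})/(1+n_{\mathrm{perm}})$, Bonferroni-adjusted over the four
  classes. The test named in the protocol specifies no statistic; global
  map dissimilarity is the standard choice.
* **Mixed ANOVA.** Duration, coverage and occurrence are each analyzed with
  group (between) × class (within) expected-mean-squares F tests via
  `aov(value ~ group*class + Error(subject/class))`. No sphericity
  correction is applied by default (none is part of the modelled protocol);
  a Greenhouse–Geisser option exists.
* **Pairwise comparisons** gate on Shapiro–Wilk normality (paired t /
  Wilcoxon signed-rank; Welch t / Mann–Whitney), with Bonferroni adjustment
  and the family size always reported. A literal rank-based Dunn backend is
  available: "Dunn's test" after a mixed ANOVA is nonstandard, so the
  gated parametric/rank tests are the default.
* **Transitions** get one paired test per ordered off-diagonal pair,
  Bonferroni family fixed at 12.

## The prediction stage

Responders are patients whose PSQI fell by at least 50% of baseline; the
boundary comparator is configurable (`>=` by default, strict `>` available)
because clinical usage varies. Class imbalance is addressed by bootstrap
oversampling of the minority class to the majority count.

**Feature selection** runs in configurable ordered stages, by default:
per-method top-15 ranking (random-forest Gini importance, recursive feature
elimination on standardized logistic coefficients, gradient-boosted-tree
gain), each wrapped in 100-resample bootstrap stability selection retaining
features chosen in more than 75% of resamples; consensus across at least 2
of the 3 methods; then collinearity pruning (drop the largest VIF while any
exceeds 10, then break $|r| > 0.8$ pairs by the larger mean absolute
correlation). An alternative stage order (consensus of plain top-k first,
stability after) is available, since narrative descriptions of such
pipelines often leave the exact order ambiguous.

**Models.** Seven of the eight configured algorithms have backends here
(logistic regression, RBF SVM with calibrated probabilities, random forest
and XGBoost with 100 trees, 5-NN, Gaussian naive Bayes, and an in-package
discrete-SAMME AdaBoost over depth-1 stumps); CatBoost has no R
implementation in this stack and is skipped with a logged warning — the
model list is config-driven, so adding a backend is a one-entry change. All
stochastic learners are seeded (seed 42 by default).

**Evaluation** uses 100 stratified 75/25 shuffle-splits, reporting mean ± SD
of AUC, accuracy, precision, recall, F1 and PR-AUC, pooled-score DeLong
comparisons between models, and percentile ROC bands. Oversampling placement
matters: balancing **before** splitting lets duplicated subjects straddle
the train/test boundary and inflates scores. The default therefore
oversamples inside the training fold only; `paper_mode` reproduces the
balance-then-split order and its reports are explicitly labelled
optimistic.

**DeLong test.** AUCs are normalized Mann–Whitney statistics; the variance
of an AUC difference comes from the structural components (placement values
of each positive among the negatives and vice versa), $z = \Delta
\mathrm{AUC}/\sqrt{\widehat{\mathrm{var}}}$ with a two-sided normal p-value;
identical score orderings are reported as degenerate with $p = 1$.

**Attribution.** With at most ~14 surviving features, Shapley values are
computed *exactly* by enumerating all $2^p$ coalitions against a background
sample (interventional expectation). Additivity — attributions summing to
the prediction minus the base value — holds exactly by construction, which
is the property the test suite asserts.

## Numerical choices and degenerate inputs

* Spatial correlation of a zero-variance map is undefined; such peaks are
  dropped with a message.
* A single-label peak sequence yields an all-zero transition matrix with
  `n_transitions = 0`, flagged but not an error.
* Zero-variance metric data short-circuits the mixed ANOVA to a "no
  effect" result instead of a division by zero.
* Perfectly collinear features are pruned with VIF reported as `Inf`.
* Canonical-label ties within $10^{-9}$ break by lexicographic permutation
  order, deterministically.
* All stochastic functions take explicit seeds; derived child seeds are
  kept below $2^{31}$.

## Problem sizes used by the test suite

The validation suite exercises the closure property at the study's stated
recording conditions — 20 subjects, 26 channels, 256 Hz, 150 s, snr 2,
mean dwell 70 ms, 100 restarts — and verifies template recovery at
$|r| \ge 0.95$, durations and occurrences within ±10%, coverages within ±5
points and transition percentages within ±3 points of the true-sequence
metrics. Selection-pipeline recovery uses 6 planted features (standardized
effect 1.5) among 28 with 27+27 subjects over 20 seeded repeats. Null
calibration of the evaluation stage is measured across several independent
null tables, because repeated shuffle-splits of a single finite table share
that table's accidental signal: per-table mean AUC scatters around chance
far more than the split-to-split standard error suggests, and averaging
over tables is what estimates the intended null level. Permutation and
DeLong calibration use 100–200 nested repeats.

## Known limitations

* The generator's single-carrier, spatially white noise model is a
  deliberately simple contrast; real EEG has 1/f spectra, spatially
  correlated noise and artifacts.
* Episode detection from peak labels slightly underestimates durations and
  overestimates occurrences (boundary quantization and occasional peakless
  segments); the bias stays within the stated tolerances at the default
  conditions but grows as dwell times approach the peak spacing.
* The mixed ANOVA assumes complete per-subject class measurements; with
  $k = 2$ within-levels sphericity is moot, at $k = 4$ the optional
  Greenhouse–Geisser correction may be warranted.
* Only four-class models are supported by design; five-to-seven class
  microstate inventories are out of scope.
* The prediction stage performs no hyperparameter tuning, nested
  cross-validation or external validation; with ~50 subjects its outputs
  are exploratory by nature, and the fold-internal oversampling default is
  the package's guard against the most common source of optimism.

## A minimal worked example

```{r example, eval = FALSE}
cl_truth <- ground_truth(snr = 2, mean_dwell_ms = 70, seed = 1)
seq1 <- simulate_state_sequence(cl_truth, duration_s = 150, rate = 256)
rec <- synthesize_recording(cl_truth, seq1, rate = 256)
bf <- backfit_peaks(rec, cl_truth$templates)
compute_metrics(bf)
```
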