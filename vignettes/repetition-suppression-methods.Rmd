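---
title: "Methods: normalized signal energy, spatial ROIs, mixed models and single-trial decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized signal energy, spatial ROIs, mixed models and single-trial decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repetition suppression (RS) — the attenuation of neural responses to a
repeated stimulus — is the electrophysiological counterpart of habituation
and is reliably altered in fragile X syndrome (FXS). `rseeg` implements a
complete analysis chain for a passive auditory habituation paradigm: 18
pseudoword trains of 10 identical presentations each, recorded on a
dense-array EEG net with 99 retained scalp channels, segmented into 800-ms
epochs at 250 Hz. The chain quantifies how response magnitude changes over
presentations, whether those changes differ between neurotypical controls
and FXS participants, how they co-vary with non-verbal IQ (NVIQ) within FXS,
and whether single trials carry enough signal to classify FXS participants
into NVIQ median-split subgroups (≤ 42 vs > 42).

No public data set accompanies this paradigm, so the package includes a
synthetic cohort generator as a first-class, tested module. Every
calibration claim in the test suite is made against that generator's known
ground truth.

## Signal energy and its normalization

Response magnitude is measured component-free as signal energy

$$E = \sum_t |amp_t|^2,$$

the sum of squared voltages over the 0–800 ms window. Energy is robust to
latency and morphology differences across a wide age range, which matters in
a developmental clinical sample.

Two preprocessing decisions shape what E means here:

* **Non-phase-locked isolation.** The evoked (phase-locked) waveform is
  estimated per presentation index as the mean over the 18 pseudowords at
  that index (per participant and channel) and subtracted from each epoch.
  Activity that is phase-locked to stimulus onset cancels; induced
  oscillatory activity with trial-varying phase survives. The subtraction
  mode is configurable (`mode = "none"`) for sensitivity checks. Whether the
  original workflow subtracted before or after normalization is not
  documented; subtraction-first is the default here because it keeps the
  normalization pool consistent with the energies actually summed.
* **Repetition-series normalization.** For each participant, channel and
  pseudoword, the 10-presentation series is divided by its pooled sample
  standard deviation (denominator N − 1, pooled over all kept presentations
  × samples). Every pseudoword series then has SD 1, making energies
  unitless and comparable across channels, participants and amplifier
  scales. Two identities pin the implementation: scale invariance (E is
  unchanged when the raw series is multiplied by any c > 0) and
  $\sum_p E_p = 10T - 1$ for a mean-zero series, which places per-
  presentation energies near T = 200 — the scale regime in which group means
  around 185–225 are expected. Whether the original analysis pooled the SD
  per channel or across channels, and sample vs population SD, is not
  stated; per-channel sample SD is the default and the divisor is recorded
  per series.

Rejected epochs (any sample strictly exceeding ±100 μV; equality keeps the
epoch) are excluded from the SD pool, from the evoked estimate and from all
downstream tables, so one artifact cannot inflate a whole train's divisor.

Per-epoch bandpass filtering (1–50 Hz, zero-phase 4th-order Butterworth
applied forward–backward) deviates from a continuous-recording workflow,
which filters before segmentation. An 800-ms segment is shorter than the
1-Hz edge's impulse response, so each segment is extended by autoregressive
forecasting (Yule–Walker, order ≤ 20, two epoch lengths per side) before
filtering and trimmed afterwards; the unit tests verify the realized
passband against the filter's analytic transfer function on sinusoid
epochs.

## Spatial PCA and regions of interest

Scalp regions of interest are derived per diagnostic group from the
(participants × presentations) × channels matrix of stimulus-averaged
energies: correlation-matrix PCA (channels standardized — the convention of
the classic SPSS workflow), retention of the smallest leading set of
components reaching 60% cumulative variance, Varimax rotation with Kaiser
normalization. Rotation is orthogonal, so communalities and total retained
variance are preserved (asserted to 1e−8). Channels are assigned to the
factor with their maximal absolute rotated loading when it reaches 0.40
(the conventional salient-loading cutoff; configurable), factors left empty
are dropped, and ROIs are named by the spatial centroid of their channels
(anterior–posterior band × laterality). The two groups' ROI sets are pooled
— seven ROIs under the default synthetic cohort, two contributed by the FXS
model and five by the control model — and the pooled set is used for all
participants downstream, mirroring how the derived regions are used in the
modelling and decoding stages.

## The linear-mixed-model ladder

The modelling stage works on stimulus-averaged ROI energies (one row per
participant × presentation × ROI). The baseline model is

```
energy ~ repetition * ROI,  random = ~ 0 + repetition_num | participant
```

a per-participant random slope on the numeric repetition covariate and *no*
random intercept — the structure found to fit this paradigm best — estimated
by maximum likelihood. Repetition enters the fixed effects as a 10-level
factor so that per-presentation contrasts are available, while the random
slope and the serial-correlation ordering use its numeric coding. Factors
are sum-coded so the marginal (type-III-style) F tests remain interpretable
under interactions.

Predictors are added in the fixed order group → NVIQ → age, each judged by a
chi-square likelihood-ratio test at α = 0.05 against the last accepted
model; the group block adds 70 parameters and the NVIQ block 20, matching
the degrees of freedom of the published ladder. Age is expected to fail —
the generator gives it no role. The residual covariance across the ten
ordered presentations (identity, compound symmetry, AR(1); the candidate set
is restricted to these three because "all available structures" is a
package-specific notion of the original software) is then selected by AIC on
the accepted model. NVIQ enters uncentered; a configuration flag allows
centring for sensitivity checks. Degrees of freedom use the containment
approximation of the underlying `nlme` machinery — fractional
Satterthwaite-style df of the original software are not reproduced, and no
acceptance quantity depends on them.

Post hoc, all 45 presentation pairs are tested on the estimated marginal
means with Bonferroni correction (p × 45, capped at 1), and the contrasts
are refused — not silently computed — when the repetition main effect is not
significant.

Two calibration facts about this ladder drove design choices in the
generator:

* Residuals of normalized energies are genuinely correlated within
  participant: the normalization constraint couples the ten presentations,
  and slow state fluctuations add serial correlation. Fitting the ladder
  with an identity covariance visibly inflates the LRT for a pure-noise
  covariate such as age; the AR(1) default removes most of that inflation.
* The normalization constraint is in fact *singular*: each cell's ten
  energies have an (almost) fixed total, so their covariance has one
  direction with essentially zero variance. Any full-rank fit counts that
  empty direction in its residual degrees of freedom, biasing the residual
  variance downward and inflating every F statistic by roughly 10% — enough
  to push the repetition test's type-I rate to ~0.10–0.12 regardless of
  which parametric structure (identity, CS, AR(1), or even a moment-
  estimated unstructured correlation) is fitted in the full space. The
  package therefore provides a calibration-grade fit
  (`fit_mixed(covariance = "unstructured")`): each cell is projected onto
  the orthocomplement of the constant-in-presentation direction — the
  subspace normalization leaves identifiable, where every repetition
  contrast lives — then whitened by the moment-estimated projected
  correlation and tested by Wald F with the correct (projected) degrees of
  freedom. Under null cohorts this fit holds the repetition test's level
  (~0.08 over 100 cohorts); the calibration suite uses it, while the ladder
  itself keeps the conventional mixed-model fits whose *decisions* are
  driven by effects far larger than the residual miscalibration.
* A covariate that is *modelled* linearly (NVIQ) but *simulated* as a hard
  step leaves lack-of-fit that any chance-correlated participant covariate
  can absorb. The generator therefore interpolates individual FXS
  habituation trajectories continuously along NVIQ (logistic weight centred
  at the median split, scale 6 NVIQ points) — consistent with reading the
  median split as a statistical tool over an underlying continuum rather
  than a biological boundary.

## Single-trial decoding and chance calibration

For the 14 FXS participants, each of the 252 trials (14 × 18) yields 17
features per ROI: E(P1) − E(Pj) for j = 2..10 and E(P2) − E(Pj) for
j = 3..10 — 119 features over the seven ROIs. Classification of
fxs_low vs fxs_high is evaluated with leave-two-subject-out cross-validation
under bootstrap class balancing: all C(8,6) = 28 subsets of the larger class
give balanced 6-vs-6 designs of 216 trials; within each subset every
cross-class participant pair (36 folds; exhaustive pairing removes the
arbitrariness of choosing one pairing) serves once as the test set (their 36
trials) while an RBF-kernel SVM (C = 1, γ = 1 on the per-fold z-scored
feature; libsvm) is trained on the remaining ten participants' 180 trials.
Standardization is fit on training data only. Per-feature decoding accuracy
(DA) is averaged within subset and then over the 28 subsets; the dispersion
across subsets gives the s.e.m. Trials with an artifact-rejected constituent
presentation are dropped from both sides for that feature. A cheaper
rotational pairing (`pairing = "disjoint"`, 6 folds per subset, every trial
still evaluated once per subset) is available and is what the Monte-Carlo
calibration studies use; it leaves the expected DA unchanged and only
enlarges the subset-level dispersion.

Chance is calibrated exactly: the significance threshold is 100·k*/216
where k* is the smallest count whose exact binomial upper tail (summed in
log space; no normal approximation) does not exceed the corrected α. The
published recipe — binomial cumulative distribution with Bonferroni
correction across 119 features — under-determines the printed pair
62.96/64.35%: it does not fix sidedness or the exact multiplicity divisor.
`calibrate_convention()` therefore searches
{one-sided, two-sided} × multiplier {1, 2, 4} and adopts the first
convention reproducing both printed values at 2-decimal precision; the
winner is an effective per-feature α of α/476 (equivalently: a two-sided
tail with the Bonferroni family doubled), and it is recorded in the output
metadata of every run rather than silently assumed. Flags use strict
exceedance: DA exactly at a threshold is not significant.

## What the generator emulates — and what it does not

Each synthetic epoch is the sum of:

* a fixed damped-sine evoked template (5 Hz, 150-ms decay, peak 2 μV),
  identical across epochs and participants — the analyses here concern
  energy, not ERP morphology;
* induced 10-Hz oscillations on planted unit-norm, mutually orthogonal
  scalp topographies, with per-epoch uniform random phase (so they cancel
  in the across-stimulus average) and per-epoch random power
  (u² ~ Gamma(8, 8), a moderate trial-to-trial variability);
* white sensor noise (SD 1 μV);
* rare square-pulse artifacts (2% of epochs, ±150 μV) for the rejection
  stage to find.

The per-presentation gain of each source follows the subgroup's habituation
profile: controls (1.3, 1, …, 1); fxs_high (1.4, 1.4, 1.4, 1, …, 1);
fxs_low flat at 1.4. The control gain is sized so normalized energies drop
by roughly 20 units after P1 and the FXS gain so the delayed drop is
roughly 30 units — the magnitudes of the reported group tables — and
individual FXS trajectories blend the two anchors along NVIQ as described
above. Each participant × source trajectory is additionally jittered by a
slow AR(1) state fluctuation (SD 0.12, lag-1 correlation 0.4 across
presentations), which is what makes a random repetition slope and an AR(1)
residual structure the *right* model family for these data.

The default spatial model has five compact block sources over classic
auditory-attention regions (16 channels each) and two broad sign-balanced
sources (42 and 40 channels) whose signed loadings are orthogonal to every
compact block yet whose energy footprint spans much of the scalp. Controls
weight the compact sources (gain 1 vs 0.35), FXS participants the broad
ones — emulating the finding that FXS activity concentrates in two spatially
extended fronto-central/temporal factors while control activity splits into
five regional ones. Under the default cohort the control-group PCA retains
five factors and the FXS-group PCA two at the 60% target, pooling to seven
ROIs. Because energies are quadratic in the loadings, an energy-domain
factor recovers the *squared* topography profile; for sign-balanced broad
sources the recovered channel set is therefore the support, not the signed
map — ROI derivation needs exactly that, but congruence-based recovery
tests use all-positive block topographies where the two notions coincide.

Not emulated: continuous raw EEG (epochs are generated directly, so no
segmentation stage), ocular/muscle artifact structure beyond amplitude
excursions (no ICA), volume-conduction head models, age effects of any
kind, and medication or comorbidity structure. Passing calibration tests on
this generator therefore shows the *statistical machinery* behaves as
specified under the planted mechanisms — not that real FXS EEG satisfies
those mechanisms.

## Problem sizes used in the calibration suites

The test suite runs its Monte-Carlo calibrations at reduced montages, which
leave the quantities under study untouched (energies, profiles and ladder
structure do not depend on channel count):

* ladder recovery and post hoc power: 50 cohorts of 26/8/6 participants,
  seven disjoint two-channel sources (overlap-free ROIs keep the LRT
  calibrated), AR(1) ladder without the covariance sweep;
* decodability: 20 cohorts with one broad 40-channel source and hard
  median-split profiles, best of the fourteen planted-step features
  (j ≥ 4), rotational fold pairing;
* null calibration: 50 flat-profile cohorts (singleton sources) for the
  repetition type-I rate; two flat-profile cohorts with the full 7 × 17
  feature set for the family-wise check;
* spatial recovery: synthetic observation matrices for congruence, plus a
  26-participant five-source cohort (14-channel blocks on the 99-channel
  montage) for the retention count.

The full-montage showcase lives in `analysis/01_simulate.R` …
`06_significance.R`, which reproduce the whole chain at the study's
original dimensions.

## Known limitations

* Degrees of freedom and exact F/t values of the original mixed-model
  software are not reproducible (different df approximations; no real
  data); only structural decisions (which predictors survive, which
  covariance wins, which contrasts are significant) are calibrated.
* Seven-ROI pooling across groups can assign one channel to two ROIs (one
  per group); the mixed model treats ROI as a factor and tolerates this,
  but cross-ROI residual correlation is then possible. The calibration
  suites use overlap-free sources for exactly this reason.
* The binomial chance calibration assumes independent trials; trials nested
  in participants violate this, which is why the published thresholds are
  conservative multiplicity-corrected ones rather than nominal binomial
  quantiles.
* Per-epoch filtering, even with AR-extension padding, is not identical to
  filtering the continuous record; the energy statistics are dominated by
  mid-band content where the difference is negligible.
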