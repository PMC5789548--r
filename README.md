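# rseeg — repetition-suppression analysis and single-trial decoding for auditory EEG

Repetition suppression (RS) — the drop in neural response when a stimulus is
repeated — is the electrophysiological face of habituation and is altered in
fragile X syndrome (FXS). `rseeg` implements, as a reusable and fully tested
R pipeline, the analysis chain for a passive auditory habituation paradigm:
18 pseudoword trains × 10 presentations, 99 scalp channels, 800-ms epochs at
250 Hz, in a cohort of neurotypical controls and FXS participants split at
non-verbal IQ (NVIQ) 42.

The chain is:

1. **Cleaning** — zero-phase 1–50 Hz Butterworth bandpass (AR-extension
   padding per epoch), average reference, ±100 μV artifact rejection.
2. **Signal energy** — the component-free response measure
   *E* = Σ|amp|², computed on non-phase-locked activity (evoked waveform
   subtracted per presentation index) after each pseudoword's
   10-presentation series is normalized by its pooled standard deviation.
3. **Spatial ROIs** — per-group spatial PCA (correlation matrix, Varimax)
   on the participants×presentations by channels energy matrix; factors up
   to 60% cumulative variance; channels assigned by maximal rotated loading
   ≥ 0.40; the groups' ROI sets pooled.
4. **Mixed models** — energy ~ repetition × ROI with a per-participant
   random repetition slope (no intercept), ML; predictors group → NVIQ →
   age added by χ² likelihood-ratio tests; residual covariance (identity /
   compound symmetry / AR1) selected by AIC; Bonferroni post hoc
   presentation contrasts.
5. **Single-trial decoding** — per trial and ROI, features E(P1)−E(Pj) and
   E(P2)−E(Pj) (17 per ROI); RBF-SVM under leave-two-subject-out
   cross-validation over all C(8,6)=28 balanced 6-vs-6 bootstrap subsets
   (216 trials each, 36 test trials per fold).
6. **Chance calibration** — exact binomial thresholds: the minimum decoding
   accuracy significant at Bonferroni-corrected *p* < 0.05 / *p* < 0.01 over
   119 features at n = 216 is 100·k*/216 where k* is the smallest count with
   P(X ≥ k*) below the corrected α (k* = 136 → 62.96%, k* = 139 → 64.35%).

Because no EEG from this paradigm is publicly deposited, the package ships a
synthetic cohort generator (`sim_config()`, `generate_cohort()`) that plants
the three canonical habituation profiles — controls suppress after P1, the
milder FXS phenotype (NVIQ > 42) after P3, the lower-functioning subgroup
not at all — on orthogonal scalp topographies, with per-epoch random-phase
induced oscillations, slow AR(1) trajectory drift, sensor noise, and
injectable artifacts. Every statistical stage is calibrated against this
generator's ground truth; see `vignettes/repetition-suppression-methods.Rmd`
for the model, parameter choices, and what passing these calibrations does
and does not show about real data.

## Worked example — the full study at original scale

The numbered scripts under `analysis/` run the whole chain on the default
synthetic cohort (26 controls, 8 FXS ≤ 42, 6 FXS > 42) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # cohort + metadata
Rscript analysis/02_preprocess_energy.R  # cleaning + energies (slowest step)
Rscript analysis/03_rois.R               # spatial PCA ROIs
Rscript analysis/04_lmm.R                # LMM ladder + post hocs
Rscript analysis/05_decoding.R           # 28x36-fold SVM decoding
Rscript analysis/06_significance.R       # binomial thresholds + flags
```

Output highlights from this run (seed 1):

```
Epochs kept for analysis: 7067 of 7200 (98.2%)
Mean normalized energy 199.9 (unit-variance scale, T = 200)

fxs group: 2 factors retained (74.4% cumulative variance)
control group: 4 factors retained (64.4% cumulative variance)

 predictor     chi2 df            p accepted
     group 283.4810 50 2.322051e-34     TRUE
      nviq 377.0758 20 1.145460e-67     TRUE
       age  31.8519 10 4.238361e-04     TRUE

Controls: repetition F-test p = 0; 9 of 45 contrasts significant
   pair estimate        t   df  p_bonferroni
  1 - 2 41.96693 28.94355 1225 3.923438e-139

Chance thresholds: 62.50% (p < 0.05), 63.89% (p < 0.01)
50 of 85 features significant after Bonferroni correction
               feature mean_da    sem significance
 central-midline.2 2-7   74.81 0.1794          p01
```

Reading this: 98.2% of epochs survive rejection (the clinical regime is
~97–99%); normalized energies sit at the T = 200 scale with the planted
~20-unit first-presentation elevation; the FXS spatial model concentrates in
two broad factors while the control model splits into regional ones (here
four — five is the modal count across seeds, so this cohort pools 6 ROIs and
85 features, and the thresholds are recomputed at that family size under the
calibrated convention; the canonical 7-ROI/119-feature design gives the
62.96/64.35% pair). The ladder accepts group and NVIQ with huge margins;
controls show the classic P1→P2 suppression in every leading contrast. Age
is spuriously accepted in this particular cohort — a known consequence of
pooling channel-overlapping ROIs from the two group models (cross-ROI
residual correlation the mixed model cannot carry); the calibration suite,
which uses overlap-free sources, rejects age in 90% of cohorts. Decoding
recovers the planted subgroup difference well above the chance bar,
concentrated — as designed — on early-presentation difference features over
the FXS-weighted regions.

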