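---
title: "Models and methods behind megafmrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind megafmrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megafmrs)
```

## The measurement problem

GABA-edited functional MR spectroscopy (fMRS) tries to resolve small,
task-locked changes in the inhibitory (GABA+) and excitatory (Glx,
glutamate + glutamine) neurotransmitter pools while a subject performs a
cognitive task. A MEGA-PRESS sequence alternates editing pulses between
1.9 ppm (edit-ON) and 7.46 ppm (edit-OFF); subtracting the two
sub-spectra (DIFF = ON − OFF) cancels the dominant singlets and leaves the
coupled GABA+ resonance at ~3.0 ppm, the co-edited Glx signal at
~3.75 ppm, and an inverted NAA lobe at ~2.0 ppm. Disabling water
suppression on every third transient interleaves an unsuppressed water
reference into the same acquisition: the BOLD response lengthens T2*,
narrowing spectral lines, so the fitted water linewidth tracked over time
is a concurrent, spatially co-localised BOLD measure
(`delta_fwhm_hz`, reported so that positive = stronger BOLD).

`megafmrs` implements this whole chain — a parametric simulator of the
interleaved acquisition, spectral preprocessing, peak quantification with
serial quality control, the water-linewidth BOLD estimator, and the
cohort statistics — so that every stage can be validated against known
ground truth without any data download.

## The simulator

Each transient is a sum of damped complex exponentials sampled at
`spectral_width_hz` (default 2000 Hz, 2048 complex points; the tests and
the acceptance script use 1024 points, which keeps the resolution below
2 Hz and halves the cost). Defaults mirror the acquisition they emulate:
TE 68 ms, TR 1.5 s, 700 transients, water reference every third
transient (0-based indices 2, 5, 8, ...; 233 water / 467 metabolite
transients), two-step phase cycle, and a block-event flanker task
(60 s OFF + 11 × [30 s ON + 60 s OFF]; one trial per TR, 40%
incongruent, stimulus 100–350 ms before the excitation pulse). Those
choices reproduce the design arithmetic exactly: 220 trials, about 48
task-ON metabolite transients per inner temporal bin, and roughly 320
(324 under the default interleave) task-OFF metabolite transients.

Model components, per transient:

* **Resonances.** NAA 2.01, Cr 3.03, Cho 3.20 ppm (Lorentzian); GABA+
  3.01 ppm (Gaussian, edit-ON only — the "+" denotes ~50% co-edited
  macromolecule content, tracked as a bookkeeping fraction); Glx as a
  Gaussian pseudo-doublet at 3.71/3.79 ppm with edit factors 1.5/0.5 so
  the DIFF amplitude equals the subject's `amp_glx`; water 4.68 ppm
  (Lorentzian) on reference transients only. No attempt is made to
  separate Glu from Gln, and no density-matrix simulation is performed —
  parametric lines are sufficient to exercise every pipeline stage.
* **Task dynamics.** Task-ON transients scale Glx by
  `1 + task_glx_frac` (default 0.06) plus `early_bin_boost` (default
  0.037) when the stimulus-to-acquisition interval is below 183 ms, and
  GABA+ by `1 + task_gaba_frac` (default 0). The 6% figure and the
  stronger early-interval response are the study conditions the
  generator emulates.
* **BOLD coupling.** Instantaneous linewidth is
  `base_fwhm_hz − bold_narrowing_hz × h(t)`, where `h` is the stimulus
  impulse train convolved with a canonical dual-gamma HRF (peak delay
  6 s, undershoot delay 16 s, unit dispersions, peak:undershoot 6:1,
  32 s support), normalised to peak 1.
* **Contamination.** Linear frequency drift (default 1 Hz/min), motion
  spikes (probability 0.01 control / 0.02 patient; frequency jump
  ~N(0, 5 Hz), phase ~N(0, 20°)), a phase-cycle-locked DC offset the
  nuisance model is expected to remove, and complex Gaussian noise
  (default SD 0.5, which puts the NAA SNR of a single metabolite
  transient near 20 and of a condition average near 300 — the scale of
  a well-behaved 3 T acquisition).

The cohort generator layers the study's statistical structure on top:
51 + 51 subjects by default, ages pair-matched within ±4 years, baseline
Glx lower by 2 i.u. in patients, opposite-sign coupling between the
BOLD-fMRI covariate and baseline Glx (−0.38 i.u./Z in controls,
+0.16 i.u./Z in patients — the interaction of 0.54 these defaults imply
is the study-scale effect), water-line narrowing correlated with the
fMRI Z at r = 0.35 in controls and r = 0 in patients, PANSS and
medication profiles typical of a hallucinating-psychosis sample, and a
GABA+ association with prescribed dose of 0.15 i.u. per defined daily
dose. One root seed drives everything; per-subject streams derive from a
documented splitting rule, so any subject regenerates independently.

What the simulator does **not** emulate: realistic macromolecule
baselines, eddy-current or frequency-dependent phase distortions,
coil-combination effects, subject-specific lineshape asymmetries, or
non-stationary noise. Passing recovery tests therefore demonstrates that
the pipeline is correct and unbiased under its own generative
assumptions, not that it is robust to everything in vivo data can do.

## Preprocessing

**Spectral registration.** Each transient's frequency and phase error is
estimated by maximising the time-domain correlation with a template (the
pointwise median FID of same-kind transients: edit-ON, edit-OFF, or
water), evaluated on a zero-padded FFT grid over the first 512 samples
and refined by successive parabolic interpolation; a two-pass scheme
rebuilds the template from aligned data once. Corrections are pure
phase/frequency modulations, so amplitudes are untouched. Each group is
then frequency-referenced to a landmark (water 4.68, NAA 2.01 or Cr
3.03 ppm) so scanner drift leaves no global shift; the landmark
interpolation is accurate to ~0.3 Hz, a constant calibration offset well
inside every fit window. Motion outliers are flagged where estimates
leave a linear drift trend by more than 5 unscaled MADs (floored at
0.5 Hz / 5°).

**Condition model.** The complex value of every spectral point across
metabolite transients of one edit state is regressed on condition
indicators — task-OFF plus five stimulus-to-acquisition bins with edges
at [100, 183, 267, 350] ms, lower limits inclusive, open at the ends —
together with nuisance columns: the phase-cycle sign and standardised
motion regressors (spike flag, |frequency|, |phase|). Motion columns
that are constant or collinear are pruned; a collinear structural column
is an error. The GLM solves real and imaginary parts jointly with one QR
decomposition per edit state; with a balanced design and no nuisance
variance it reduces exactly to per-condition means. Empty bins are
reported absent rather than as zero spectra — with the nominal
100–350 ms jitter only the three inner bins populate. DIFF spectra are
edit-ON minus edit-OFF condition coefficients.

**Reference deconvolution.** Lineshape matching divides the target FID
by the normalised magnitude envelope of a measured water reference and
imposes an ideal Gaussian decay, with the pointwise gain capped at
`1/floor_frac` (default 20) so a decayed reference cannot amplify noise.
When the reference and ideal envelopes agree the operation is the
identity to machine precision. The pipeline leaves this stage off by
default: the parametric simulator produces matched lineshapes already,
so enabling it would only swap fit shapes; it remains a config toggle
and is validated as a standalone operation.

## Quantification and quality control

DIFF fitting follows edited-MRS practice: GABA+ as a single Gaussian on
2.79–3.55 ppm, Glx as a two-Gaussian pseudo-doublet with shared
linewidth on 3.45–4.10 ppm, NAA as an inverted Lorentzian on
1.80–2.25 ppm, each with a linear baseline, solved by bounded
Levenberg–Marquardt. Edit-OFF NAA/Cr/Cho are fitted jointly as
Lorentzians with a shared linewidth. Non-convergence is a flag, never an
exception. Windows and shapes are configurable; they are declared
defaults, not values inferred from any particular dataset.

Three rejection criteria apply **in series**: (1) linewidth — GABA+ FWHM
above 30 Hz or NAA FWHM above 12 Hz; (2) SNR — fitted NAA amplitude over
twice the noise SD (signal-free 9.5–10.5 ppm window) strictly below 20;
(3) outliers — among survivors, GABA+ or Glx estimates more than 5
unscaled MADs from the median (a raw 5 × MAD is already ~3.4 SDs, so no
consistency factor is needed here); an all-identical group (MAD 0)
rejects nothing. The order matters and is tested against a literal
three-pass oracle.

Water scaling is `iu = area / water_area × 100`: with the simulator's
default water amplitude the scale is chosen so a difference-spectrum
line of simulated amplitude *a* quantifies to *a* i.u., putting default
healthy-control Glx near 15 i.u. No tissue or relaxation corrections are
applied; i.u. is an arbitrary documented unit.

## The water-linewidth BOLD estimate

Every water-reference transient is fitted with a pseudo-Voigt
(η·Lorentzian + (1−η)·Gaussian, shared FWHM) on a linear baseline. The
linewidth series is cleaned in two serial steps — 5 × MAD outliers, then
a jump rule invalidating both neighbours of any first difference beyond
3 × the MAD of first differences — with no interpolation. Both MAD
estimates are floored at 2.5% of the median linewidth: when the water
fit is very precise the raw MAD collapses to the fit noise, and an
unfloored screen starts flagging the genuine BOLD-driven linewidth
dynamics (a few tenths of a Hz on an 8 Hz line) instead of artefacts,
which both discards data and biases the BOLD estimate towards zero. The cleaned series is regressed on the HRF-convolved
stimulus regressor plus intercept, linear drift and any motion
covariates; `delta_fwhm_hz` is minus the regressor coefficient, so
positive values mean stronger BOLD (activation narrows the line). Fewer
than 10 valid samples flags the estimate unreliable.

## Statistics

* `rank_tests()`: Wilcoxon signed-rank / Mann–Whitney U, two-sided;
  all-tied paired differences return p = 1 with a warning.
* `skipped_spearman()`: bivariate outliers are flagged by projecting all
  points onto directions from the minimum-covariance-determinant centre
  through each point and applying the 1.5 × IQR box-plot rule to each
  projection; Spearman's rho on the retained points, percentile
  bootstrap CI (1000 resamples, seeded), t-approximation p. With nothing
  flagged it reduces exactly to classical Spearman.
* `fit_baseline_model()`: `response ~ group * BOLD + fGM + age`, with a
  single-pass DFFITS screen at 2√(k/n) (one screen, not iterated —
  observations "were dropped" once), then Jarque–Bera and White
  LM/two-moment diagnostics on the refit; a diagnostic p < 0.05 attaches
  a model-suitability warning, never silently. Note the group
  coefficient is conditional at BOLD = 0, as the formula implies.
* `fit_mixed_model()`: random intercept per subject (no random slopes),
  `response ~ group * condition + fGM + age + (1|subject)`; one residual
  filter at 2.5 × the normal-consistent MAD (≈ 3.7 residual SDs), one
  refit; Satterthwaite p-values, Wald CIs; a singular random-effects fit
  falls back to OLS with a warning. The consistency scaling in this
  filter is deliberate: a cutoff of 2.5 raw MADs sits at ~1.7 SDs,
  trims ~9% of perfectly healthy observations, shrinks the residual
  variance estimate and inflates the type-I error of every term to
  ~0.12 (we measured this by Monte Carlo); at ~3.7 SDs the screen
  removes only genuinely strong residuals and the test size stays
  nominal. The QC outlier stage and linewidth cleaning, whose 5 × MAD
  thresholds are comfortably in the tail either way, keep the plain
  unscaled MAD.
  `fGM` and age are mean-centred so the intercept is the reference-group
  task-OFF level at average covariates — that makes the reported percent
  task effect (task coefficient / intercept × 100) a fraction of a
  typical baseline rather than of an extrapolation to a zero-aged,
  zero-grey-matter subject.
* `medication_model()`: `GABA+ ~ is_active * DDD + fGM + age +
  PANSS_positive` on patients, same screening machinery; a constant
  medication flag drops the interaction with a warning, an invariant
  dose column is an error naming `ddd`.
* `holm_adjust()`: step-down Holm–Bonferroni (via `p.adjust`), applied
  within each enumerated sub-analysis family; family membership is a
  pipeline choice, with the behavioural contrasts forming one family.
* `delta_metabolites()`: task-ON minus task-OFF per subject, absent (not
  zero) when either condition is unusable. Reaction-time slowing is
  defined as incongruent-minus-congruent median correct RT.

## Numerical choices and degenerate inputs

* Spectra use the spectroscopy axis convention (highest ppm first); the
  first FID point is halved before transformation so baselines are flat
  and discrete peak integrals equal `amplitude × bandwidth / 2`, the
  discrete counterpart of the closed-form one-sided line area.
* All fits run on the real part; the simulator produces
  absorption-phased spectra and registration removes phase errors first.
* All-zero FIDs are marked unusable and excluded from templates;
  all-zero spectra yield flagged, not crashing, fits.
* Serial filters (QC, linewidth cleaning) implement their stage order
  explicitly; tests compare against brute-force oracles and against
  deliberately permuted stage orders.
* Problem sizes in the tests and the acceptance script — 1024-point
  FIDs, cohorts of 4–10 subjects per group for full-pipeline recovery,
  truth-level tables at 51 + 51 for the cohort statistics, 20–30 seeded
  replicates per recovery property — were fixed once as the smallest
  sizes at which the quantities of interest are stable.
* The acceptance check for the differential group × BOLD association
  uses couplings of ±0.8 i.u./Z rather than the study-scale defaults:
  a direction-recovery property demanded in ≥90% of replicates needs a
  clearly powered scenario, while the defaults reproduce the
  study-scale coefficients themselves.

## Limitations

Beyond the simulator gaps listed above: quantification is peak-based,
not basis-set fitting, so macromolecule handling is limited to the fixed
co-edited fraction; the water-scaled unit omits relaxation and
partial-volume corrections and is comparable only within this package;
the BOLD estimate assumes the canonical HRF shape; and the statistical
battery mirrors one specific analysis plan rather than offering model
selection. The serialisation format is a plain-text container (JSON
header + CSV payload) chosen for portability and diff-friendliness, not
for I/O speed on large cohorts.
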