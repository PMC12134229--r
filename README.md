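# megafmrs

Simulation and quantification of GABA-edited functional MR spectroscopy
(fMRS) with concurrent BOLD estimation from the water linewidth.

## The problem

MEGA-PRESS spectral editing alternates an editing pulse between 1.9 ppm
(edit-ON) and 7.46 ppm (edit-OFF); the difference spectrum
(DIFF = ON − OFF) isolates GABA+ at ~3.0 ppm and co-edited Glx
(glutamate + glutamine) at ~3.75 ppm, with an inverted NAA lobe at
~2.0 ppm. Acquiring ~700 such transients while a subject performs a
block-event flanker task, and disabling water suppression on every third
transient, yields three measurements from one scan:

* **task-resolved metabolite levels** — DIFF spectra per task condition
  and per stimulus-to-acquisition interval bin, quantified against the
  water reference;
* **a concurrent BOLD estimate** — activation lengthens T2\* and narrows
  the water line, so regressing the fitted water linewidth on an
  HRF-convolved task regressor gives ΔFWHM<sub>water</sub>, the
  "BOLD-fMRS" measure (reported so that positive = stronger BOLD);
* **behaviour** — accuracy, reaction times and reaction-time slowing
  from the flanker trials.

The package is aimed at spectroscopists and methodologists who want a
fully testable implementation of this analysis chain: a parametric
simulator with known ground truth stands in for the scanner, so every
stage — spectral registration, the nuisance linear model, reference
deconvolution, peak fitting, serial quality control, the linewidth BOLD
model, and the cohort statistics (influence-screened OLS with
Jarque-Bera/White diagnostics, MAD-filtered linear mixed models, skipped
Spearman correlations, Holm-Bonferroni adjustment) — can be validated
end to end.

## Worked example

Simulate one subject with a 6% task-ON Glx increase and a 0.5 Hz BOLD
water-line narrowing, run the full per-subject pipeline, and look at the
estimates:

```r
library(megafmrs)

cfg <- run_config(seed = 3, params = acq_params(n_points = 1024L))
res <- run_subject(cfg, subject_truth(), "S001", 1L)

res$estimates[1:2, c("condition", "glx_iu", "gaba_iu", "naa_snr",
                     "reject_stage")]
#>   condition   glx_iu  gaba_iu  naa_snr reject_stage
#> 1  task_off 15.02420 2.509291 305.5733         none
#> 2   task_on 15.93607 2.532856 224.0635         none

res$bold
#> <bold_estimate> dFWHM_water = 0.499 Hz (SE 0.003, t = 153.28, n = 233)
```

The task-OFF Glx estimate recovers the simulated baseline of 15 i.u.;
the task-ON estimate is ~6% higher, matching the injected
`task_glx_frac = 0.06` (plus the early-interval boost); the water
linewidth regression recovers the injected 0.5 Hz narrowing; and the
spectrum passes all three serial rejection criteria (linewidths below
30/12 Hz, NAA SNR above 20, no MAD outlier).

Cohort-level analysis with the statistical battery:

```r
cfg <- run_config(seed = 1,
                  cohort = cohort_config(n_control = 10L, n_patient = 10L),
                  params = acq_params(n_points = 1024L))
man <- run_cohort(cfg)
man$models$mixed_glx_task$percent_task_effect   # ~6-7% task-ON Glx increase
man$models$baseline_glx_fmri$terms              # group, BOLD, interaction
```

A thin command-line front end is installed under
`inst/scripts/fmrs-pipeline.R`
(`Rscript fmrs-pipeline.R --verb run-all --seed 1 --out demo`).

## Layout

* `R/` — simulator (`acq_params`, `build_schedule`,
  `simulate_transients`, `simulate_cohort`), preprocessing
  (`register_spectra`, `fit_condition_glm`, `reference_deconvolve`),
  quantification (`fit_diff`, `fit_editoff`, `compute_qc`,
  `reject_outliers`, `scale_to_iu`), BOLD (`fit_wref`, `clean_series`,
  `build_bold_regressor`, `estimate_bold`), statistics (`rank_tests`,
  `skipped_spearman`, `fit_baseline_model`, `fit_mixed_model`,
  `medication_model`, `holm_adjust`, `delta_metabolites`,
  `behavioural_metrics`), and the pipeline (`run_config`, `run_subject`,
  `run_cohort`).
* `vignettes/megafmrs-methods.Rmd` — the models, assumptions, parameter
  defaults and numerical choices, in detail.
* `tests/testthat/` — unit, property and acceptance suites.
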