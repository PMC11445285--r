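# petHetero

Lesion-level response-heterogeneity analysis for longitudinal FDG PET/CT,
with a bootstrapped Cox model-comparison harness for testing whether
quantifying the response of *all* lesions prognosticates overall survival
better than the lesion subsets and single summaries used by standard
criteria.

## Who this is for

Quantitative-imaging and biostatistics researchers studying treatment
response in multi-lesion cancers (lymphoma, metastatic lung cancer, ...).
Standard response assessments compress a patient's disease into a few
target lesions: RECIST 1.1 sums the diameters of at most five lesions,
PERCIST follows the SUVpeak of the single hottest lesion, and the Deauville
score grades the hottest residual uptake against aorta and liver
references. When lesions within one patient respond discordantly — some
decreasing or disappearing while others grow or appear — those summaries
discard exactly the information that may carry the prognosis. `petHetero`
implements the full analysis chain needed to measure that loss.

## What it computes

**Per lesion-ROI** (labelled voxel set on the PET grid): SUVmax, SUVmean,
SUVhetero (the SD of voxel SUVs), volume (ml), SUVtotal = SUVmean x volume
(SUV·ml), SUVpeak (mean over a 1 cm^3 sphere centered on the hottest
voxel), and the RECIST long-axis diameter maximized over axial slices.

**Per lesion track**: baseline and follow-up lesions are matched one-to-one
(voxel overlap, then centroid distance, 15 mm gate) and categorized by
percent change in SUVtotal,

    new | increasing (> +30%) | stable (within +/-30%) | decreasing (< -30%) | disappeared

the +/-30% band approximating the test-retest repeatability of serial FDG
PET. A patient is *heterogeneous* with at least one new/increasing and one
decreasing/disappeared track.

**Per patient**: whole-patient features at each timepoint, their percent
changes, and 60 heterogeneity features ({count, fraction} per category plus
{max, sum} of each base feature per category); automated RECIST / PERCIST /
Deauville assessments on a common 1-5 ordinal scale.

**Per model**: the harness fits Cox proportional-hazards models through
univariable screening (p < 0.2), bootstrapped stepwise backward selection
under BIC = -2 logPL + k ln(events) (features ranking in the top 40th
percentile of selection frequency are kept), and evaluates each model by
refitting on bootstrap resamples and taking the median Harrell C-index;
models sharing a resample matrix are compared with paired t-tests under
Bonferroni correction, with scaled Schoenfeld diagnostics for the
proportional-hazards assumption.

A synthetic two-timepoint PET/CT cohort generator (DLBCL-like and
NSCLC-like profiles: median 9 and 3 lesions per patient, 40.1% and 88.6%
heterogeneous patients, survival drawn from a known Cox model over the
engineered features) provides ground truth for validating every stage.

## Worked example

```r
library(petHetero)

co <- generate_cohort(profile_dlbcl(n_patients = 100), master_seed = 2024)
co
#> <pet_cohort> DLBCL-like: 100 patients (master seed 2024)
#>   baseline lesions/patient: median 9 [0-30]
#>   heterogeneous response:   40/100 (40.0%)
#>   deaths observed:          66/100 (34.0% censored)

X <- assemble_design_matrix(co, "all", c("BL", "FU", "Response", "Heterogeneity"))
m <- response_model(X, co$survival, B_select = 100, B_eval = 200,
                    rng_seed = 1, label = "all features, all lesions")
m
#> <response_model> all features, all lesions
#>   51 screened -> 13 selected feature(s); median C-index 0.756 (B = 200)
#>   overall score test p = 9.78e-08; PH global p = 0.183
```

Reading this: of 82 engineered features, 51 passed the univariable screen,
13 survived bootstrap-BIC selection (their selection frequencies and hazard
ratios per SD are shown by `summary(m)`), and the model orders patient risk
correctly for 75.6% of comparable patient pairs (median over 200 bootstrap
refits). The Schoenfeld global p = 0.18 gives no evidence against
proportional hazards — as expected, since the generator's hazards are
proportional by construction.

`run_experiment()` runs the full comparison — all lesions vs the 5 biggest
vs the 1 hottest, full features vs BL/FU/Response subsets, vs the
RECIST/PERCIST/Deauville ordinals as univariable comparators — on one
shared bootstrap-resample matrix and reports median C-indices and paired
Bonferroni-adjusted p-values. On seeded synthetic cohorts whose hazard
loads on heterogeneity features, the all-feature/all-lesion model
dominates: e.g. median C-index 0.777 against 0.738 (5 biggest), 0.541
(baseline-only) and 0.628/0.646/0.585 (RECIST/PERCIST/Deauville ordinals),
every deficit with adjusted p < 0.05.

## Layout

- `R/` — profiles and the synthetic generator, per-lesion quantification,
  lesion tracking, feature engineering, response criteria, the survival
  harness (`response_model()` and friends), experiment orchestration, IO.
- `tests/testthat/` — unit and property tests with independent brute-force
  oracles; `test-acceptance.R` holds the end-to-end validation suite.
- `vignettes/lesion-response-heterogeneity.Rmd` — the methods vignette:
  model, assumptions, parameter choices, numerical conventions, and what
  the synthetic experiments do and do not establish.
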