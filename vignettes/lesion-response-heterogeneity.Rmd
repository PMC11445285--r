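---
title: "Quantifying lesion-level response heterogeneity on longitudinal PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion-level response heterogeneity on longitudinal PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petHetero)
```

## The problem

Standard treatment-response criteria for metastatic cancer — RECIST 1.1,
PERCIST, the Deauville score — summarize a patient's disease from a handful
of target lesions (at most five diameters, one SUVpeak, one five-point
score). When different lesions in the same patient respond differently to
therapy ("heterogeneous response": some lesions shrinking or resolving while
others grow or appear), those summaries can miss prognostically decisive
information. `petHetero` implements the full analysis chain needed to test
that claim quantitatively: per-lesion PET quantification at two timepoints,
longitudinal lesion tracking with a five-way change categorization,
patient-level heterogeneity feature engineering, automated implementations
of the three standard criteria, and a bootstrapped Cox
proportional-hazards model-comparison harness scored by Harrell's
concordance index.

Because real trial images are access-restricted, the package also ships a
synthetic two-timepoint PET/CT cohort generator with complete ground truth
(lesion placement, per-lesion change categories, and survival drawn from a
known Cox model). Every downstream stage can therefore be validated against
what the generator actually did, and the package's central experiment — do
all-lesion heterogeneity features prognosticate survival better than lesion
subsets, whole-patient summaries, or the standard criteria? — can be
reproduced in silico.

## Per-lesion quantification

For each lesion-ROI (a labelled voxel set on the PET grid) the package
computes seven quantities:

* **SUVmax** — the hottest voxel;
* **SUVmean** — the arithmetic mean over mask voxels;
* **SUVhetero** — the standard deviation of mask voxel SUVs, population
  convention (divisor N), so a single-voxel lesion has SUVhetero 0;
* **volume** — voxel count times voxel volume, in ml;
* **SUVtotal** — SUVmean x volume (SUV·ml). This is the
  total-lesion-glycolysis convention: it is voxel-size independent, and the
  +/-30% change band used for categorization (below) then matches the
  test–retest repeatability framing that motivates it. A plain voxel sum
  would differ only by the constant voxel volume; the choice is isolated in
  `quantify_lesion()`;
* **SUVpeak** — the mean over all image voxels whose centers lie within a
  1 cm^3 sphere (radius 6.2035 mm) centered on the lesion's hottest voxel.
  Following standard PERCIST practice the sphere is *not* clipped to the
  lesion mask; membership is voxel-center-in-sphere with no partial-volume
  weighting, and ties for the hottest voxel break to the lowest (z, y, x)
  index. Because the sphere can include hotter neighbouring tissue,
  `suv_peak <= suv_max` is guaranteed only when the lesion is hotter than
  its surroundings — true of the generator's images and of typical FDG-avid
  disease, not of arbitrary arrays;
* **LAD** — the RECIST long-axis diameter: the maximum in-plane distance
  between voxel centers, computed per axial slice and maximized over
  slices. Measuring between centers means a single-voxel lesion has LAD
  0 mm; no pixel-edge padding is added, so the brute-force oracle used in
  the tests is exact.

A lesion's organ is the modal organ label over its voxels (ties to the
lowest code).

## Tracking and the five-way categorization

Baseline and follow-up lesions are matched greedily one-to-one: candidate
pairs are ranked by voxel overlap (descending), then centroid distance
(ascending); zero-overlap pairs are admitted only within a 15 mm centroid
gate. Unmatched baseline lesions are *disappeared*, unmatched follow-up
lesions *new*. Matched pairs are categorized by percent change in SUVtotal
with the baseline as denominator: beyond +30% *increasing*, beyond -30%
*decreasing*, inside the band (boundary inclusive) *stable*. The band
approximates the test–retest repeatability of serial FDG PET, so only
changes beyond it count as real; exactly +/-30% is therefore read as
*stable*. A patient's response is *heterogeneous* when at least one track is
new-or-increasing and at least one is decreasing-or-disappeared.

The matcher replaces a proprietary registration-based algorithm whose
internals are not public; on the simulator's co-registered grids
registration is unnecessary, and the matcher sits behind a single interface
(`match_lesions()`) so a registration-based variant could be substituted.
Only one-to-one matches are supported — no split/merge topology.

## Feature engineering

Four feature groups are built per patient:

* **BL** and **FU** — whole-patient single-timepoint features per scan:
  maxima of SUVmax/SUVpeak, sums of volume and SUVtotal, the
  volume-weighted global SUVmean, a pooled global SUVhetero (reconstructed
  exactly from per-lesion mean/SD/volume moments), and the lesion count
  (7 features each).
* **Response** — percent change of each of those from baseline (missing
  when the baseline value is 0 or missing — never infinite), plus the
  absolute change in lesion count (8 features).
* **Heterogeneity** — per change category: lesion count and fraction of
  tracks, plus the max and the sum of each of the five base features
  (SUVmax, SUVmean, SUVhetero, SUVtotal, volume) over that category's
  lesions (60 features). Aggregates are evaluated on follow-up values for
  categories that exist at follow-up and on baseline values for
  disappeared lesions — the only timepoint at which those exist. Empty
  categories yield count 0, fraction 0, and missing aggregates.

The exact published feature inventory is not public; the implemented set is
the closed family generated by {count, fraction} x category and
{max, sum} x base-feature x category plus the BL/FU/Response globals — every
named example of such a feature ("count of new lesions", "highest SUV of
increasing lesions", "SUVtotal of decreasing lesions") is a member. The
fraction denominator is the total track count (matched + new + disappeared),
counting each physical lesion once.

`assemble_design_matrix()` applies an optional lesion subset *before* all
feature computation — `five_biggest` (largest volumes, at most two per
organ, the RECIST target rule) or `one_hottest` (highest SUVpeak, the
PERCIST rule) — re-runs tracking on the subset by masking non-selected
labels out of the label volumes, then drops constant columns and imputes
remaining missing values by the cohort median.

## Automated response criteria

* **RECIST 1.1**: targets are the five largest baseline lesions by volume,
  at most two per organ. Any new lesion is PD. Otherwise the sum of target
  LADs is compared: CR when the follow-up sum is zero and no lesions remain
  anywhere, PR at -30% or better, PD at +20% *and* +5 mm or worse, SD
  otherwise. With only two timepoints the baseline is the nadir. LAD is
  measured on the PET-mask footprint. The -30% / +20%+5 mm thresholds come
  from the RECIST 1.1 guideline itself.
* **PERCIST**: the target at each timepoint is the lesion with the highest
  SUVmax in that scan (the two targets may differ); response is the percent
  change of their SUVpeak at +/-30%, with CMR when no lesion remains at
  follow-up and PMD for any new lesion. Declaring CMR on mask resolution is
  the mask-based analogue of resolution to background.
* **Deauville**: the hottest residual lesion's SUVpeak against the
  follow-up scan's aorta and liver SUVmean, both read from the organ-label
  map rather than passed as constants: 1 no residual lesion, 2 at or below
  aorta, 3 above aorta but at or below liver, 4 above liver up to 3x liver,
  5 above 3x liver. All lower boundaries are inclusive ("<=").

Each criterion maps to a common ordinal scale (CR/CMR 1, PR/PMR 2, SD/SMD
3, PD/PMD 4; Deauville score k -> k) so it can enter a univariable Cox model
as a single numeric covariate. Patients with no baseline lesions are not
evaluable; standalone they yield `NA`, and inside `run_experiment()` their
ordinal is median-imputed (with the count logged in the bundle) so that all
models share the same patients and bootstrap resamples.

## The survival harness

`response_model()` is the package's modelling interface:

1. **Univariable screen** — one single-covariate Cox fit per feature; keep
   Wald p < 0.2 (a deliberately permissive, conventional pre-filter).
2. **Bootstrapped backward BIC selection** — on each of `B_select`
   resamples (with replacement, full cohort size), stepwise backward
   elimination removes the feature whose removal most decreases
   BIC = -2 logPL + k ln(d), stopping when no removal decreases it; d is
   the number of events, the effective sample size of a Cox partial
   likelihood. A feature's selection frequency is the fraction of resamples
   retaining it; the final set is the features at or above the 60th
   percentile of the frequency distribution — i.e. ranking within the top
   40% ("top 40th percentile" read as a rank rule; a fixed absolute
   frequency cutoff would be the alternative reading and can be imposed by
   filtering `selection$frequencies` directly). As a computational
   strategy, each elimination step shortlists the five covariates with the
   smallest Wald statistics of the current fit and refits exactly only
   those; accepted steps always strictly decrease the BIC, and `width =
   Inf` recovers the exhaustive scan. Exactly collinear covariates are
   aliased by the fit and dropped before the pass, so duplicated columns
   can never survive together. The final set is additionally capped at 13
   features (the documented practical ceiling) and at d - 5.
3. **Final fit** — multivariable Cox with z-scored covariates (hazard
   ratios per SD), Breslow tie handling, partial likelihood maximized to
   relative tolerance 1e-9; Wald CIs and the overall score (logrank) test.
   Simulated times are continuous, so ties have measure zero and Breslow is
   exact for practical purposes.
4. **Bootstrap evaluation** — for each of `B_eval` resamples, refit on the
   resample and compute Harrell's C-index of that fit *on the same
   resample*; the headline C-index is the median. In-sample scoring follows
   the described procedure literally; whether the original analysis scored
   in-sample or out-of-bag is not stated, so `out_of_bag = TRUE` is
   provided as a sensitivity analysis rather than guessed as the default.
   Models to be compared must share one resample-index matrix
   (`bootstrap_indices()`): `compare_models()` then runs a paired t-test on
   the per-resample C-index differences (df = B - 1) with Bonferroni
   adjustment over the family of comparisons drawn together.
5. **Diagnostics** — scaled Schoenfeld residuals against the Kaplan–Meier
   time transform, per covariate and globally.

The C-index counts pairs where the shorter observed time is an event;
risk ties score 1/2; tied times are not comparable. It is implemented
in-package and cross-checked against both an explicit pair-enumeration
oracle and `survival::concordance` in the tests.

## The synthetic cohort generator

`generate_cohort()` draws, per patient: a baseline lesion count, a
heterogeneity flag, lesion placements, per-lesion change categories, a
follow-up scan realising them, and finally survival from a Cox model over
the engineered features. Design choices, and what they do and do not
emulate:

* **Geometry** — axis-aligned ellipsoidal lesions (radii 4–12 mm) with
  Gaussian intra-lesion noise (SD 0.6 SUV), placed without overlap inside a
  fixed box-organ atlas; the aorta (SUV 1.9) and liver (SUV 2.6) are
  constant-uptake reference regions read back from the image so the
  Deauville path is exercised end to end. Volumes are 48x48x44 voxels at
  4 mm isotropic — a PET-like grid large enough for ~30 non-overlapping
  lesions. There is no scanner PSF, reconstruction artifact, respiratory
  motion, or multi-scanner variation: passing tests demonstrate the
  *analysis chain* is correct, not that it is robust to acquisition
  physics.
* **Cohort profiles** — `profile_dlbcl()`: lesion counts negative binomial
  (mu 10.3, size 2.5, capped at 30), population median 9; ~40.1% of
  patients heterogeneous; baseline hazard ln(2)/1845 per day; 30% censoring
  target. `profile_nsclc()`: counts nbinom(mu 3.5, size 3, cap 15), median
  3; 88.6% heterogeneous; hazard ln(2)/753; 20% censoring. Medians, the
  heterogeneous fractions and the median survival times are calibration
  targets taken from published trial cohorts; the full count distributions
  are unpublished, so the negative binomial (overdispersed, right-skewed)
  is a modelling choice calibrated once to the medians.
* **Categories** — each baseline lesion draws a category from the
  profile's mixture; new-lesion counts are Poisson. The heterogeneity flag
  is assigned by quota over patient indices, so the configured
  heterogeneous fraction is realised exactly rather than with binomial
  noise (patients are exchangeable, so which indices carry the flag is
  immaterial; an iid draw would wander several points at trial-sized
  cohorts). Heterogeneous patients are guaranteed one lesion on each side
  (forcing a lesion when the draw misses); non-heterogeneous patients draw
  from one side only. Follow-up SUVmean scalings (increasing x1.7–2.3,
  stable x0.97–1.03, decreasing x0.25–0.42) leave margins well clear of the
  +/-30% band even after the <=1-voxel rasterization wobble caused by the
  3 mm spatial jitter, which is itself far below the matcher's 15 mm gate —
  hence >=99% ground-truth category recovery.
* **Survival** — features named in the profile's `true_beta` are z-scored
  across the cohort, so coefficients are scale-free; event times are
  exponential with rate h0 exp(beta . x) (proportional hazards exact by
  construction, so the Schoenfeld check passes under the null), and
  censoring is uniform over an administrative window solved numerically to
  hit the target censoring fraction. The default `true_beta` loads mainly
  on heterogeneity features (fractions of new/increasing/decreasing
  tracks, count of disappeared lesions) plus a baseline tumour-burden term,
  so the data-generating truth rewards exactly the information that lesion
  subsets and single-timepoint summaries discard. Setting `tv_flip_time`
  flips the sign of the linear predictor at that time, injecting a
  proportional-hazards violation for testing the diagnostic's power.
* **Seeding** — one master seed; per-patient seeds derive deterministically
  from it, so cohorts are byte-reproducible and scans can be regenerated on
  demand (`patient_scans()`) instead of being held in memory.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(profile_dlbcl(n_patients = 100), master_seed = 2024)
co
cohort_summary(co)$heterogeneous_fraction
category_recovery(co)$accuracy

X <- assemble_design_matrix(co, "all",
                            c("BL", "FU", "Response", "Heterogeneity"))
m <- response_model(X, co$survival, B_select = 100, B_eval = 200,
                    rng_seed = 1, label = "all features, all lesions")
summary(m)
```

For the full comparison (lesion subsets, feature subsets, criteria
comparators, paired tests) use `run_experiment()`; see the README for the
numbers a complete seeded run prints.

## Numerical choices and problem sizes

* All tie-breaks are deterministic (lowest index / lowest id / lowest
  organ code), so every pipeline stage is exactly reproducible.
* Matched tracks with baseline SUVtotal 0 cannot be categorized and raise
  an error; the generator never produces them (uptake is bounded away
  from 0).
* Degenerate inputs are defined, not fatal: empty scans quantify to empty
  tables, empty cohorts run end to end, patients without baseline disease
  are not evaluable for RECIST/PERCIST, and fewer than 3 events yields a
  missing Schoenfeld result.
* The shipped validation suite runs at deliberately modest sizes — e.g. a
  300-patient cohort with 100 selection and 200 evaluation bootstraps for
  the model-comparison experiment, and n = 2000 for parameter-recovery
  checks — chosen so the full suite completes in minutes while keeping
  every conclusion stable across seeds at the stated tolerances.

## Known limitations

* The lesion matcher is overlap/centroid-based and one-to-one; it assumes
  co-registered grids and will not model split/merge lesion topology or
  large deformations.
* The generator's organ atlas is schematic (boxes), lesions are ellipsoids,
  and uptake is piecewise constant plus noise; radiomic texture beyond
  SUVhetero is out of scope.
* Conclusions from the synthetic experiment concern the method's internal
  validity (the pipeline detects heterogeneity signal that is truly
  there); they do not by themselves establish prognostic value on real
  trial images.
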