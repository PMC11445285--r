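Package: petHetero
Title: Lesion-Level Response Heterogeneity Analysis for Longitudinal FDG PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Quantifies intra-patient heterogeneity of lesion response between
    baseline and follow-up FDG PET/CT scans and measures its prognostic value
    for overall survival. Provides per-lesion standardized-uptake-value (SUV)
    quantification (SUVmax, SUVmean, SUVtotal, SUVhetero, SUVpeak, volume and
    RECIST long-axis diameter), longitudinal lesion matching with five-way
    change categorization (new, increasing, stable, decreasing, disappeared)
    on a +/- 30 percent SUVtotal band, patient-level heterogeneity feature
    engineering, automated RECIST 1.1, PERCIST and Deauville scoring, and a
    bootstrapped Cox proportional-hazards model-comparison harness
    (univariable screening, stepwise backward BIC selection over bootstrap
    resamples, Harrell concordance index, paired bootstrap t-tests, and
    Schoenfeld proportional-hazards diagnostics). A synthetic two-timepoint
    PET/CT cohort generator with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
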