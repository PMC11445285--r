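# End-to-end experiment orchestration: simulate -> quantify -> track ->
# engineer -> criteria -> model -> compare, as one reproducible, configured
# run.

#' Experiment configuration
#'
#' @param profile A [cohort_profile()].
#' @param master_seed Integer master seed for the whole run.
#' @param B_select Bootstrap resamples for BIC feature selection.
#' @param B_eval Bootstrap resamples for C-index evaluation (shared across
#'   all models — the paired design).
#' @param lesion_modes Lesion subsets to evaluate with the full feature set.
#' @param feature_sets Named list of feature-group subsets to evaluate on
#'   all lesions.
#' @param comparators Comparator models: any of `"RECIST"`, `"PERCIST"`,
#'   `"Deauville"` (criterion ordinals as a single covariate) and bare
#'   feature names from the engineered feature table (e.g.
#'   `"fu_global_suv_peak"`, `"bl_global_volume"`,
#'   `"response_global_suv_max"`).
#' @param outdir Optional output directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(profile,
                       master_seed = 1L,
                       B_select = 100L,
                       B_eval = 200L,
                       lesion_modes = c("all", "five_biggest", "one_hottest"),
                       feature_sets = list(
                         "BL + FU + Response" = c("BL", "FU", "Response"),
                         "FU" = "FU",
                         "BL" = "BL"),
                       comparators = c("RECIST", "PERCIST", "Deauville",
                                       "fu_global_suv_peak", "bl_global_volume",
                                       "response_global_suv_max"),
                       outdir = NULL) {
  structure(list(profile = profile, master_seed = as.integer(master_seed),
                 B_select = B_select, B_eval = B_eval,
                 lesion_modes = lesion_modes, feature_sets = feature_sets,
                 comparators = comparators, outdir = outdir),
            class = "run_config")
}

#' Run the full model-comparison experiment
#'
#' Generates the synthetic cohort, fits the reference model (all features,
#' all lesions), the lesion-subgroup models, the feature-subgroup models and
#' the univariable comparators — all evaluated on one shared bootstrap
#' resample matrix — and compares every model against the reference with
#' paired t-tests under Bonferroni correction. Not-evaluable criterion
#' ordinals are median-imputed for the comparator fits (count reported in
#' the bundle).
#'
#' @param config A [run_config()].
#' @return A report bundle: `config`, `cohort_summary`,
#'   `category_recovery`, `models` (named `response_model` list), a
#'   `results` table (label, kind, median C-index, overall score-test p),
#'   `comparisons` (vs the reference model), and `n_not_evaluable` per
#'   criterion.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$master_seed
  cohort <- generate_cohort(config$profile, seed)
  if (cohort$n == 0L) {
    return(structure(list(config = config, cohort_summary = cohort_summary(cohort),
                          category_recovery = NULL, models = list(),
                          results = data.frame(), comparisons = data.frame(),
                          n_not_evaluable = integer(0),
                          skipped_models = character(0), reference = NULL),
                     class = "experiment_bundle"))
  }
  y <- cohort$survival
  indices <- bootstrap_indices(cohort$n, config$B_eval, derive_seed(seed, 900L))
  models <- list()
  kinds <- character(0)
  skipped <- character(0)

  fit_one <- function(X, label, select = TRUE) {
    response_model(X, y, B_select = config$B_select, indices = indices,
                   rng_seed = derive_seed(seed, 901L + length(models)),
                   select = select, label = label)
  }
  try_model <- function(X, label, kind, select = TRUE) {
    m <- tryCatch(fit_one(X, label, select = select), error = function(e) e)
    if (inherits(m, "error")) {
      skipped[label] <<- conditionMessage(m)
      warning("model '", label, "' skipped: ", conditionMessage(m))
    } else {
      models[[label]] <<- m
      kinds[label] <<- kind
    }
  }

  ref_label <- "All features, all lesion-ROI"
  for (mode in config$lesion_modes) {
    label <- if (mode == "all") ref_label else
      c(five_biggest = "5 biggest lesion-ROI",
        one_hottest = "1 hottest lesion-ROI")[[mode]]
    X <- assemble_design_matrix(cohort, mode, FEATURE_GROUPS)
    try_model(X, label, if (mode == "all") "reference" else "lesion subgroup")
  }
  for (fs_label in names(config$feature_sets)) {
    X <- assemble_design_matrix(cohort, "all", config$feature_sets[[fs_label]])
    try_model(X, fs_label, "feature subgroup")
  }
  if (!ref_label %in% names(models)) {
    stop("reference model (all features, all lesion-ROI) could not be fitted: ",
         skipped[ref_label])
  }

  n_ne <- integer(0)
  criterion_cols <- c(RECIST = "recist", PERCIST = "percist", Deauville = "deauville")
  for (cmp in config$comparators) {
    x <- if (cmp %in% names(criterion_cols)) {
      v <- cohort$assessments[[criterion_cols[[cmp]]]]
      n_ne[cmp] <- sum(is.na(v))
      v
    } else {
      if (!cmp %in% colnames(cohort$features)) {
        stop("unknown comparator feature: ", cmp)
      }
      cohort$features[[cmp]]
    }
    X1 <- impute_median(matrix(as.numeric(x), ncol = 1,
                               dimnames = list(NULL, cmp)))
    try_model(X1, cmp, "comparator", select = FALSE)
  }

  others <- setdiff(names(models), ref_label)
  comparisons <- do.call(rbind, lapply(others, function(lbl) {
    cm <- compare_models(models[[ref_label]]$evaluation,
                         models[[lbl]]$evaluation,
                         n_comparisons = length(others))
    data.frame(model = lbl, kind = kinds[[lbl]],
               mean_diff = cm$mean_diff, se_diff = cm$se_diff,
               t = cm$t, p_value = cm$p_value, p_adjusted = cm$p_adjusted)
  }))
  results <- do.call(rbind, lapply(names(models), function(lbl) {
    m <- models[[lbl]]
    data.frame(model = lbl, kind = kinds[[lbl]],
               n_features = length(m$features),
               median_cindex = m$evaluation$median_cindex,
               sd_cindex = stats::sd(m$evaluation$cindex, na.rm = TRUE),
               score_test_p = m$fit$score_test_p)
  }))
  bundle <- structure(list(config = config,
                           cohort_summary = cohort_summary(cohort),
                           category_recovery = category_recovery(cohort),
                           models = models, results = results,
                           comparisons = comparisons,
                           n_not_evaluable = n_ne,
                           skipped_models = skipped,
                           reference = ref_label),
                      class = "experiment_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$results, file.path(outdir, "model_results.csv"),
                   row.names = FALSE)
  if (nrow(bundle$comparisons %||% data.frame())) {
    utils::write.csv(bundle$comparisons, file.path(outdir, "model_comparisons.csv"),
                     row.names = FALSE)
  }
  writeLines(render_report(bundle), file.path(outdir, "report.md"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- bundle$config
    jsonlite::write_json(
      list(profile = cfg$profile$name, master_seed = cfg$master_seed,
           B_select = cfg$B_select, B_eval = cfg$B_eval,
           lesion_modes = cfg$lesion_modes,
           feature_sets = cfg$feature_sets, comparators = cfg$comparators),
      file.path(outdir, "run_config.json"), auto_unbox = TRUE)
  }
  invisible(outdir)
}

#' Render a human-readable experiment report
#'
#' @param bundle An `experiment_bundle` from [run_experiment()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  s <- bundle$cohort_summary
  lines <- c("# Lesion response heterogeneity experiment", "",
             sprintf("Profile: %s; master seed %d; B_select = %d, B_eval = %d",
                     bundle$config$profile$name, bundle$config$master_seed,
                     bundle$config$B_select, bundle$config$B_eval), "",
             "## Cohort descriptives", "")
  if ((s$n %||% 0) == 0) {
    lines <- c(lines, "Empty cohort (0 patients).", "")
  } else {
    lines <- c(lines,
               sprintf("- Patients: %d", s$n),
               sprintf("- Baseline lesion-ROI per patient: median %.0f [%d-%d]",
                       s$median_lesion_count, s$min_lesion_count, s$max_lesion_count),
               sprintf("- Patients with heterogeneous change: %d/%d (%.1f%%)",
                       s$n_heterogeneous, s$n, 100 * s$heterogeneous_fraction),
               sprintf("- Censored: %.1f%%; median observed time %.0f days",
                       100 * s$censored_fraction, s$median_time_days),
               if (!is.null(bundle$category_recovery)) {
                 sprintf("- Tracking recovered %d/%d assigned categories (%.1f%%)",
                         bundle$category_recovery$n_correct,
                         bundle$category_recovery$n_lesions,
                         100 * bundle$category_recovery$accuracy)
               }, "")
  }
  if (nrow(bundle$results %||% data.frame())) {
    lines <- c(lines, "## Model performance", "",
               "| Model | Kind | Features | Median C-index | SD | Score-test p |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %.3f | %.3f | %.3g |",
                       bundle$results$model, bundle$results$kind,
                       bundle$results$n_features, bundle$results$median_cindex,
                       bundle$results$sd_cindex, bundle$results$score_test_p), "")
  }
  if (nrow(bundle$comparisons %||% data.frame())) {
    lines <- c(lines,
               sprintf("## Paired comparisons vs %s", bundle$reference), "",
               "| Model | Mean C-index deficit | t | Adjusted p |",
               "|---|---|---|---|",
               sprintf("| %s | %+.4f | %.3g | %.3g |",
                       bundle$comparisons$model, bundle$comparisons$mean_diff,
                       bundle$comparisons$t, bundle$comparisons$p_adjusted), "")
  }
  ref <- if (!is.null(bundle$reference)) bundle$models[[bundle$reference]]
  if (!is.null(ref) && !is.null(ref$selection)) {
    fr <- ref$selection$frequencies[ref$features]
    hr <- ref$fit$hr
    lines <- c(lines, "## Reference model selected features", "",
               "| Feature | Selection frequency | HR (95% CI) | p |",
               "|---|---|---|---|",
               sprintf("| %s | %.2f | %.2f (%.2f-%.2f) | %.3g |",
                       ref$features, fr, hr, ref$fit$ci_lower,
                       ref$fit$ci_upper, ref$fit$p), "")
  }
  if (length(bundle$n_not_evaluable)) {
    lines <- c(lines,
               sprintf("Not-evaluable assessments imputed for comparators: %s",
                       paste(sprintf("%s=%d", names(bundle$n_not_evaluable),
                                     bundle$n_not_evaluable), collapse = ", ")),
               "")
  }
  lines
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
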