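#' Cohort simulation profile
#'
#' A `cohort_profile` bundles every parameter of the synthetic two-timepoint
#' PET/CT cohort generator: lesion-count distribution, the mixture of
#' per-lesion change categories, uptake parameters, image geometry, and the
#' Cox model (coefficients per standard deviation of each named feature)
#' that drives simulated overall survival.
#'
#' @param name Profile label.
#' @param n_patients Number of patients to simulate.
#' @param lesion_count Either a fixed non-negative integer, or a list
#'   `list(type = "nbinom", mu =, size =, max =)` describing a negative
#'   binomial lesion-count distribution truncated at `max`.
#' @param category_mixture Named probabilities over the four categories a
#'   baseline lesion can realise at follow-up
#'   (`increasing`, `stable`, `decreasing`, `disappeared`); must sum to 1.
#' @param new_rate Expected number of new lesions per patient (Poisson mean).
#' @param heterogeneous_fraction Target fraction of patients with a
#'   heterogeneous response (at least one new/increasing and at least one
#'   decreasing/disappeared lesion).
#' @param uptake_range Range (SUV) from which each lesion's mean uptake is
#'   drawn uniformly.
#' @param uptake_noise_sd Standard deviation (SUV) of zero-mean Gaussian
#'   intra-lesion voxel noise.
#' @param lesion_radius_range Range (mm) of per-axis ellipsoid radii.
#' @param voxel_spacing Voxel spacing in mm per axis (x, y, z).
#' @param volume_shape Volume dimensions in voxels (x, y, z).
#' @param jitter_mm Maximum spatial perturbation (mm, per axis) applied to
#'   persisting lesions at follow-up; must stay below the lesion matcher's
#'   15 mm centroid gate for guaranteed ground-truth recovery.
#' @param censoring_fraction Target proportion of censored survival times.
#' @param true_beta Named numeric vector mapping engineered feature names to
#'   log-hazard coefficients (applied to cohort z-scores of those features).
#' @param baseline_hazard_rate Baseline hazard (events per day) of the
#'   exponential survival model.
#' @param tv_flip_time Optional time (days) at which the sign of the linear
#'   predictor flips, injecting a time-varying effect that violates
#'   proportional hazards; `NULL` (default) keeps hazards proportional.
#' @return An object of class `cohort_profile`.
#' @seealso [profile_dlbcl()], [profile_nsclc()], [generate_cohort()]
#' @export
cohort_profile <- function(name = "custom",
                           n_patients = 100L,
                           lesion_count = list(type = "nbinom", mu = 10.3, size = 2.5, max = 30L),
                           category_mixture = c(increasing = 0.10, stable = 0.20,
                                                decreasing = 0.45, disappeared = 0.25),
                           new_rate = 0.5,
                           heterogeneous_fraction = 0.4,
                           uptake_range = c(3, 10),
                           uptake_noise_sd = 0.6,
                           lesion_radius_range = c(4, 12),
                           voxel_spacing = c(4, 4, 4),
                           volume_shape = c(48L, 48L, 44L),
                           jitter_mm = 3,
                           censoring_fraction = 0.25,
                           true_beta = c(fraction_new = 0.5,
                                         fraction_increasing = 0.45,
                                         fraction_decreasing = -0.45,
                                         count_disappeared = -0.30,
                                         bl_global_suv_total = 0.25),
                           baseline_hazard_rate = log(2) / 1000,
                           tv_flip_time = NULL) {
  cats <- c("increasing", "stable", "decreasing", "disappeared")
  if (!setequal(names(category_mixture), cats)) {
    stop("category_mixture must be named over: ", paste(cats, collapse = ", "))
  }
  category_mixture <- category_mixture[cats]
  if (abs(sum(category_mixture) - 1) > 1e-8) {
    stop("category_mixture probabilities must sum to 1")
  }
  if (any(category_mixture < 0)) stop("category_mixture probabilities must be non-negative")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stop("voxel_spacing must be three strictly positive values (mm)")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 8)) {
    stop("volume_shape must be three voxel counts of at least 8")
  }
  if (is.numeric(lesion_count) && length(lesion_count) == 1L) {
    if (lesion_count < 0) stop("fixed lesion_count must be >= 0")
    lesion_count <- list(type = "fixed", value = as.integer(lesion_count))
  }
  if (heterogeneous_fraction < 0 || heterogeneous_fraction > 1) {
    stop("heterogeneous_fraction must lie in [0, 1]")
  }
  if (censoring_fraction < 0 || censoring_fraction >= 1) {
    stop("censoring_fraction must lie in [0, 1)")
  }
  if (jitter_mm >= 15) {
    warning("jitter_mm >= 15 mm exceeds the lesion matcher's centroid gate; ",
            "ground-truth category recovery is no longer guaranteed")
  }
  structure(list(
    name = name,
    n_patients = as.integer(n_patients),
    lesion_count = lesion_count,
    organ_set = setdiff(names(organ_atlas(volume_shape, voxel_spacing)$codes),
                        c("background", "aorta")),
    category_mixture = category_mixture,
    new_rate = new_rate,
    heterogeneous_fraction = heterogeneous_fraction,
    uptake_range = uptake_range,
    uptake_noise_sd = uptake_noise_sd,
    lesion_radius_range = lesion_radius_range,
    voxel_spacing = as.numeric(voxel_spacing),
    volume_shape = as.integer(volume_shape),
    jitter_mm = jitter_mm,
    censoring_fraction = censoring_fraction,
    true_beta = true_beta,
    baseline_hazard_rate = baseline_hazard_rate,
    tv_flip_time = tv_flip_time
  ), class = "cohort_profile")
}

#' Preset profile emulating a DLBCL-like trial cohort
#'
#' Median 9 baseline lesions per patient, ~40% of patients with heterogeneous
#' change, long median survival: the structure of a diffuse large B-cell
#' lymphoma chemotherapy trial with baseline and interim PET/CT.
#'
#' @param n_patients Number of patients (default 127).
#' @param ... Overrides passed to [cohort_profile()].
#' @return A `cohort_profile`.
#' @export
profile_dlbcl <- function(n_patients = 127L, ...) {
  args <- list(
    name = "DLBCL-like",
    n_patients = n_patients,
    lesion_count = list(type = "nbinom", mu = 10.3, size = 2.5, max = 30L),
    category_mixture = c(increasing = 0.10, stable = 0.20,
                         decreasing = 0.45, disappeared = 0.25),
    new_rate = 0.5,
    heterogeneous_fraction = 0.401,
    censoring_fraction = 0.30,
    baseline_hazard_rate = log(2) / 1845
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_profile, args)
}

#' Preset profile emulating an NSCLC-like trial cohort
#'
#' Median 3 baseline lesions per patient, ~89% heterogeneous change, shorter
#' median survival: the structure of a non-small cell lung cancer
#' chemoradiotherapy trial with baseline and post-treatment PET/CT.
#'
#' @param n_patients Number of patients (default 114).
#' @param ... Overrides passed to [cohort_profile()].
#' @return A `cohort_profile`.
#' @export
profile_nsclc <- function(n_patients = 114L, ...) {
  args <- list(
    name = "NSCLC-like",
    n_patients = n_patients,
    lesion_count = list(type = "nbinom", mu = 3.5, size = 3, max = 15L),
    category_mixture = c(increasing = 0.30, stable = 0.15,
                         decreasing = 0.35, disappeared = 0.20),
    new_rate = 0.8,
    heterogeneous_fraction = 0.886,
    censoring_fraction = 0.20,
    baseline_hazard_rate = log(2) / 753
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_profile, args)
}

#' Draw per-patient baseline lesion counts from a profile
#'
#' @param profile A [cohort_profile()].
#' @param n Number of draws.
#' @param rng_seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_lesion_counts <- function(profile, n, rng_seed) {
  with_seed(rng_seed, draw_lesion_counts(profile, n))
}

draw_lesion_counts <- function(profile, n) {
  lc <- profile$lesion_count
  if (identical(lc$type, "fixed")) return(rep(lc$value, n))
  k <- stats::rnbinom(n, size = lc$size, mu = lc$mu)
  pmin(k, lc$max %||% Inf)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> ", x$name, "\n", sep = "")
  cat("  patients:            ", x$n_patients, "\n")
  if (identical(x$lesion_count$type, "fixed")) {
    cat("  lesion count:         fixed at", x$lesion_count$value, "\n")
  } else {
    cat(sprintf("  lesion count:         nbinom(mu=%.3g, size=%.3g), capped at %d\n",
                x$lesion_count$mu, x$lesion_count$size, x$lesion_count$max))
  }
  cat("  category mixture:    ",
      paste(sprintf("%s=%.2f", names(x$category_mixture), x$category_mixture),
            collapse = " "), "\n")
  cat(sprintf("  new-lesion rate:      %.2f / patient\n", x$new_rate))
  cat(sprintf("  heterogeneous frac:   %.3f\n", x$heterogeneous_fraction))
  cat(sprintf("  volume: %s voxels at %s mm\n",
              paste(x$volume_shape, collapse = "x"),
              paste(x$voxel_spacing, collapse = "x")))
  cat(sprintf("  survival: h0=%.3g/day, censoring target %.2f\n",
              x$baseline_hazard_rate, x$censoring_fraction))
  cat("  true beta:           ",
      paste(sprintf("%s=%.2f", names(x$true_beta), x$true_beta), collapse = " "), "\n")
  invisible(x)
}

#' Read or write a cohort profile as YAML or JSON
#'
#' @param profile A `cohort_profile`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns a
#'   `cohort_profile`.
#' @export
write_profile <- function(profile, path) {
  lst <- unclass(profile)
  lst$true_beta <- as.list(lst$true_beta)
  lst$category_mixture <- as.list(lst$category_mixture)
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite required for JSON profiles")
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml required for YAML profiles")
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_profile
#' @param path File path to read.
#' @export
read_profile <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite required for JSON profiles")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml required for YAML profiles")
    yaml::read_yaml(path)
  }
  args <- lst[setdiff(names(lst), "organ_set")]
  args$true_beta <- unlist(lst$true_beta)
  args$category_mixture <- unlist(lst$category_mixture)
  if (!is.null(args$lesion_count$value)) args$lesion_count <- args$lesion_count$value
  do.call(cohort_profile, args)
}
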