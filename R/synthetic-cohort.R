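# Two-timepoint synthetic cohort generation with ground truth: lesion
# change categories are assigned up front, scans realise them, and survival
# is drawn from a known Cox model over the engineered features.

# Deterministic per-patient generation unit: everything that depends on the
# patient's own RNG stream. Re-running it with the same master seed and index
# reproduces the scans byte for byte.
generate_patient <- function(profile, master_seed, index) {
  with_seed(derive_seed(master_seed, index), {
    k <- draw_lesion_counts(profile, 1L)
    # quota assignment over patient indices: the configured heterogeneous
    # fraction is realised exactly (patients are exchangeable, so which
    # indices carry the flag is immaterial)
    h <- profile$heterogeneous_fraction
    heterogeneous <- floor(index * h) - floor((index - 1) * h) >= 1
    if (heterogeneous && k == 0L) k <- 1L  # a heterogeneous response needs a lesion
    baseline <- gen_baseline(profile, k)
    truth <- assign_categories(profile, k, heterogeneous)
    truth$heterogeneous <- heterogeneous
    truth$n_baseline <- k
    truth$categories_df <- data.frame(
      lesion_id = c(seq_len(k), if (truth$n_new) max(0L, k) + seq_len(truth$n_new)),
      category = c(truth$categories, rep("new", truth$n_new)),
      stringsAsFactors = FALSE)
    followup <- gen_followup(baseline, truth, profile)
    list(baseline = baseline, followup = followup, truth = truth)
  })
}

#' Draw survival records from the profile's Cox model
#'
#' Features named in `profile$true_beta` are z-scored across the cohort, the
#' linear predictor \eqn{\beta \cdot x} is formed, and event times are drawn
#' from an exponential distribution with rate `baseline_hazard_rate *
#' exp(lp)`. Censoring times are drawn independently, uniform over an
#' administrative window solved numerically so the expected censoring
#' proportion matches `profile$censoring_fraction`; the observed time is the
#' minimum and the event flag indicates death observed. When
#' `profile$tv_flip_time` is set, the sign of the linear predictor flips at
#' that time, injecting a proportional-hazards violation.
#'
#' @param features Data frame or matrix (patients x features) containing
#'   every column named in `profile$true_beta`.
#' @param profile A [cohort_profile()].
#' @param rng_seed Integer seed.
#' @return Data frame with `time_days`, `event` (1 = death observed,
#'   0 = censored) and `lp` (the true linear predictor).
#' @export
generate_survival <- function(features, profile, rng_seed) {
  beta <- profile$true_beta
  features <- as.data.frame(features)
  missing_f <- setdiff(names(beta), colnames(features))
  if (length(missing_f)) {
    stop("features named in true_beta are absent: ", paste(missing_f, collapse = ", "))
  }
  x <- as.matrix(features[, names(beta), drop = FALSE])
  if (anyNA(x)) stop("true_beta features contain missing values")
  n <- nrow(x)
  lp <- if (n > 1L) {
    as.vector(standardize_columns(x)$x %*% beta)
  } else {
    rep(0, n)  # a single patient has no cohort scale; lp defined as 0
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  h0 <- profile$baseline_hazard_rate
  with_seed(rng_seed, {
    t_event <- if (is.null(profile$tv_flip_time)) {
      stats::rexp(n, rate = h0 * exp(lp))
    } else {
      draw_flip_times(lp, h0, profile$tv_flip_time)
    }
    cf <- profile$censoring_fraction
    if (cf > 0 && n > 0) {
      cmax <- solve_censor_window(h0 * exp(lp), cf)
      t_cens <- stats::runif(n, 0, cmax)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(time_days = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               lp = lp)
  })
}

# With C ~ U(0, cmax) and T ~ exp(rate_i), P(censored_i) =
# (1 - exp(-rate_i * cmax)) / (rate_i * cmax); solve mean_i = target.
solve_censor_window <- function(rates, target) {
  f <- function(cmax) mean((1 - exp(-rates * cmax)) / (rates * cmax)) - target
  lo <- 1e-6 / mean(rates); hi <- 1e6 / mean(rates)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# Event times under a sign flip of the linear predictor at `flip`:
# hazard h0*exp(lp) before, h0*exp(-lp) after (inverse-CDF draw).
draw_flip_times <- function(lp, h0, flip) {
  n <- length(lp)
  r1 <- h0 * exp(lp); r2 <- h0 * exp(-lp)
  e <- stats::rexp(n)
  h_at_flip <- r1 * flip
  ifelse(e <= h_at_flip, e / r1, flip + (e - h_at_flip) / r2)
}

#' Generate a complete synthetic two-timepoint cohort
#'
#' For each patient: draws a lesion count and a heterogeneity flag, renders
#' the baseline scan, assigns per-lesion change categories honouring the
#' flag, renders the follow-up scan, quantifies both scans, tracks lesions,
#' and engineers the full feature vector. Survival is then drawn at cohort
#' level from the profile's Cox model over the engineered features. Per-
#' patient seeds derive deterministically from `master_seed`, so identical
#' inputs reproduce identical cohorts and scans are regenerable on demand
#' (see [patient_scans()]).
#'
#' @param profile A [cohort_profile()].
#' @param master_seed Integer master seed.
#' @param keep_scans Keep the rendered volumes in the returned object
#'   (`FALSE` by default; scans are regenerated on demand).
#' @return An object of class `pet_cohort`: a list with `profile`,
#'   `master_seed`, `n`, `patients` (each holding lesion tables `lesions_bl`
#'   and `lesions_fu`, categorized `tracks`, ground `truth`, references, and
#'   optionally the scans), `features` (all-lesion design rows, unimputed),
#'   `survival`, and `assessments` (RECIST/PERCIST/Deauville ordinals).
#' @export
generate_cohort <- function(profile, master_seed, keep_scans = FALSE) {
  n <- profile$n_patients
  patients <- vector("list", n)
  feat_rows <- vector("list", n)
  assess <- matrix(NA_integer_, n, 3,
                   dimnames = list(NULL, c("recist", "percist", "deauville")))
  for (i in seq_len(n)) {
    g <- generate_patient(profile, master_seed, i)
    lesions_bl <- quantify_scan(g$baseline)
    lesions_fu <- quantify_scan(g$followup)
    tracks <- categorize_change(match_lesions(g$baseline, g$followup),
                                lesions_bl, lesions_fu)
    refs <- reference_suv_means(g$followup)
    feat_rows[[i]] <- patient_feature_row(lesions_bl, lesions_fu, tracks)
    assess[i, ] <- assess_patient(lesions_bl, lesions_fu, tracks, refs)
    patients[[i]] <- list(
      lesions_bl = lesions_bl, lesions_fu = lesions_fu, tracks = tracks,
      truth = g$truth, references = refs,
      baseline = if (keep_scans) g$baseline,
      followup = if (keep_scans) g$followup)
  }
  features <- if (n) {
    as.data.frame(do.call(rbind, lapply(feat_rows, as.numeric)),
                  col.names = names(feat_rows[[1]]))
  } else {
    data.frame()
  }
  if (n) colnames(features) <- names(feat_rows[[1]])
  survival <- if (n) {
    cbind(patient = seq_len(n),
          generate_survival(features, profile, derive_seed(master_seed, 0L)))
  } else {
    data.frame(patient = integer(0), time_days = numeric(0),
               event = integer(0), lp = numeric(0))
  }
  structure(list(profile = profile, master_seed = master_seed, n = n,
                 keep_scans = keep_scans, patients = patients,
                 features = features, survival = survival,
                 assessments = as.data.frame(assess)),
            class = "pet_cohort")
}

#' Regenerate (or fetch) one patient's scans
#'
#' @param cohort A `pet_cohort`.
#' @param i Patient index.
#' @return List with `baseline` and `followup` `patient_scan` objects,
#'   byte-identical to the scans used when the cohort was generated.
#' @export
patient_scans <- function(cohort, i) {
  p <- cohort$patients[[i]]
  if (!is.null(p$baseline)) return(list(baseline = p$baseline, followup = p$followup))
  g <- generate_patient(cohort$profile, cohort$master_seed, i)
  list(baseline = g$baseline, followup = g$followup)
}

#' @export
print.pet_cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat("<pet_cohort> ", x$profile$name, ": ", x$n, " patients (master seed ",
      x$master_seed, ")\n", sep = "")
  if (x$n) {
    cat(sprintf("  baseline lesions/patient: median %.0f [%d-%d]\n",
                s$median_lesion_count, s$min_lesion_count, s$max_lesion_count))
    cat(sprintf("  heterogeneous response:   %d/%d (%.1f%%)\n",
                s$n_heterogeneous, x$n, 100 * s$heterogeneous_fraction))
    cat(sprintf("  deaths observed:          %d/%d (%.1f%% censored)\n",
                sum(x$survival$event), x$n,
                100 * mean(1 - x$survival$event)))
  }
  invisible(x)
}

#' Cohort descriptive summary
#'
#' @param cohort A `pet_cohort`.
#' @return List of descriptives: lesion-count median/range, observed
#'   heterogeneous fraction (from the categorized tracks), censoring
#'   fraction, and median observed survival time.
#' @export
cohort_summary <- function(cohort) {
  if (cohort$n == 0L) {
    return(list(n = 0L, median_lesion_count = NA_real_,
                min_lesion_count = NA_integer_, max_lesion_count = NA_integer_,
                n_heterogeneous = 0L, heterogeneous_fraction = NA_real_,
                censored_fraction = NA_real_, median_time_days = NA_real_))
  }
  counts <- vapply(cohort$patients, function(p) nrow(p$lesions_bl), integer(1))
  het <- vapply(cohort$patients, function(p) is_heterogeneous(p$tracks), logical(1))
  list(n = cohort$n,
       median_lesion_count = stats::median(counts),
       min_lesion_count = min(counts), max_lesion_count = max(counts),
       n_heterogeneous = sum(het),
       heterogeneous_fraction = mean(het),
       censored_fraction = mean(1 - cohort$survival$event),
       median_time_days = stats::median(cohort$survival$time_days))
}

#' Ground-truth category recovery of the tracking stage
#'
#' Compares the categorized tracks against the generator's assigned
#' categories, lesion by lesion (baseline lesions by their baseline label,
#' new lesions by their follow-up label).
#'
#' @param cohort A `pet_cohort`.
#' @return List with `n_lesions`, `n_correct` and `accuracy`.
#' @export
category_recovery <- function(cohort) {
  n_total <- 0L; n_correct <- 0L
  for (p in cohort$patients) {
    truth <- p$truth$categories_df
    tr <- p$tracks
    for (r in seq_len(nrow(truth))) {
      n_total <- n_total + 1L
      want <- truth$category[r]
      got <- if (want == "new") {
        tr$category[match(truth$lesion_id[r], tr$followup_id)]
      } else {
        tr$category[match(truth$lesion_id[r], tr$baseline_id)]
      }
      if (!is.na(got) && got == want) n_correct <- n_correct + 1L
    }
  }
  list(n_lesions = n_total, n_correct = n_correct,
       accuracy = if (n_total) n_correct / n_total else NA_real_)
}
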