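# Patient-level feature engineering: whole-patient single-timepoint
# features, patient-level response features, and intra-patient response
# heterogeneity features; lesion-subset selection and design-matrix assembly.

BASE_FEATURES <- c("suv_max", "suv_mean", "suv_hetero", "suv_total", "volume_ml")

#' Whole-patient single-timepoint features
#'
#' Aggregates one scan's lesion table into patient-level features: maxima of
#' SUVmax/SUVpeak, sums of volume and SUVtotal, the volume-weighted global
#' SUVmean (= total SUVtotal / total volume), a pooled global SUVhetero
#' (pooled SD reconstructed from per-lesion mean/SD/volume moments), and the
#' lesion count. An empty table yields count 0, sums 0, and missing
#' maxima/means.
#'
#' @param lesions Lesion feature table from [quantify_scan()].
#' @return Named numeric vector of 7 features.
#' @export
patient_single_timepoint_features <- function(lesions) {
  n <- nrow(lesions)
  if (n == 0L) {
    return(c(global_suv_max = NA_real_, global_suv_peak = NA_real_,
             global_volume = 0, global_suv_total = 0,
             global_suv_mean = NA_real_, global_suv_hetero = NA_real_,
             lesion_count = 0))
  }
  gvol <- sum(lesions$volume_ml)
  gtot <- sum(lesions$suv_total)
  gmean <- gtot / gvol
  # pooled SD over all lesion voxels from per-lesion moments; per-lesion voxel
  # counts are proportional to volume on a common grid
  w <- lesions$volume_ml
  pooled_var <- sum(w * (lesions$suv_hetero^2 + lesions$suv_mean^2)) / sum(w) - gmean^2
  c(global_suv_max = max(lesions$suv_max),
    global_suv_peak = max(lesions$suv_peak),
    global_volume = gvol,
    global_suv_total = gtot,
    global_suv_mean = gmean,
    global_suv_hetero = sqrt(max(0, pooled_var)),
    lesion_count = n)
}

#' Patient-level response features
#'
#' Percent change from baseline for each whole-patient feature
#' (`100 * (fu - bl) / bl`; missing when the baseline value is 0 or missing),
#' plus the absolute change in lesion count.
#'
#' @param bl,fu Named vectors from [patient_single_timepoint_features()].
#' @return Named numeric vector (`response_*` entries and
#'   `delta_lesion_count`).
#' @export
patient_response_features <- function(bl, fu) {
  if (!identical(names(bl), names(fu))) stop("bl and fu feature names must match")
  pct <- 100 * (fu - bl) / bl
  pct[is.na(bl) | bl == 0] <- NA_real_
  names(pct) <- paste0("response_", names(bl))
  c(pct, delta_lesion_count = unname(fu["lesion_count"] - bl["lesion_count"]))
}

#' Intra-patient response heterogeneity features
#'
#' For each of the five change categories: the lesion count, the fraction of
#' tracks (0 when there are no tracks), and the max and sum of each base
#' feature (SUVmax, SUVmean, SUVhetero, SUVtotal, volume) over the lesions in
#' that category. Per-category aggregates are evaluated on follow-up features
#' for categories that exist at follow-up (new, increasing, stable,
#' decreasing) and on baseline features for disappeared lesions — the only
#' timepoint at which those exist. Empty categories yield count 0, fraction 0
#' and missing aggregates.
#'
#' @param tracks Categorized track table from [categorize_change()].
#' @param bl_lesions,fu_lesions Lesion feature tables for the two timepoints.
#' @return Named numeric vector (60 features).
#' @export
heterogeneity_features <- function(tracks, bl_lesions, fu_lesions) {
  total <- nrow(tracks)
  out <- numeric(0)
  for (cat in CHANGE_CATEGORIES) {
    in_cat <- if (total) tracks$category == cat else logical(0)
    cnt <- sum(in_cat)
    out[paste0("count_", cat)] <- cnt
    out[paste0("fraction_", cat)] <- if (total) cnt / total else 0
    if (cat == "disappeared") {
      ids <- tracks$baseline_id[in_cat]
      tab <- bl_lesions
    } else {
      ids <- tracks$followup_id[in_cat]
      tab <- fu_lesions
    }
    rows <- tab[match(ids, tab$lesion_id), , drop = FALSE]
    for (f in BASE_FEATURES) {
      v <- rows[[f]]
      out[paste0("max_", f, "_", cat)] <- if (cnt) max(v) else NA_real_
      out[paste0("sum_", f, "_", cat)] <- if (cnt) sum(v) else NA_real_
    }
  }
  out
}

#' Select a lesion subset
#'
#' `all` keeps every lesion; `five_biggest` greedily takes lesions by
#' descending volume, skipping lesions whose organ already holds two selected
#' ones, stopping at five (the RECIST target-selection rule); `one_hottest`
#' keeps the single lesion with the highest SUVpeak (the PERCIST rule). Ties
#' are broken by ascending lesion id.
#'
#' @param lesions Lesion feature table.
#' @param mode One of `"all"`, `"five_biggest"`, `"one_hottest"`.
#' @return The subsetted lesion table.
#' @export
select_lesion_subset <- function(lesions, mode = c("all", "five_biggest", "one_hottest")) {
  mode <- match.arg(mode)
  if (mode == "all" || nrow(lesions) == 0L) return(lesions)
  if (mode == "one_hottest") {
    ord <- order(-lesions$suv_peak, lesions$lesion_id)
    return(lesions[ord[1], , drop = FALSE])
  }
  ord <- order(-lesions$volume_ml, lesions$lesion_id)
  picked <- integer(0)
  organ_n <- integer(0)
  for (r in ord) {
    org <- lesions$organ[r]
    cnt <- if (org %in% names(organ_n)) organ_n[[org]] else 0L
    if (cnt >= 2L) next
    organ_n[org] <- cnt + 1L
    picked <- c(picked, r)
    if (length(picked) == 5L) break
  }
  lesions[sort(picked), , drop = FALSE]
}

# Full named feature vector for one patient (all four groups), with group
# tags as an attribute.
patient_feature_row <- function(bl_lesions, fu_lesions, tracks) {
  bl <- patient_single_timepoint_features(bl_lesions)
  fu <- patient_single_timepoint_features(fu_lesions)
  resp <- patient_response_features(bl, fu)
  het <- heterogeneity_features(tracks, bl_lesions, fu_lesions)
  out <- c(stats::setNames(bl, paste0("bl_", names(bl))),
           stats::setNames(fu, paste0("fu_", names(fu))),
           resp, het)
  attr(out, "groups") <- c(rep("BL", length(bl)), rep("FU", length(fu)),
                           rep("Response", length(resp)),
                           rep("Heterogeneity", length(het)))
  out
}

FEATURE_GROUPS <- c("BL", "FU", "Response", "Heterogeneity")

#' Assemble a patients-by-features design matrix
#'
#' Applies the lesion subset per scan before any feature computation, re-runs
#' lesion tracking on the subset (non-selected labels are masked out of the
#' label volumes), computes the requested feature groups for every patient,
#' drops constant columns, and imputes remaining missing values by the cohort
#' median.
#'
#' @param cohort A `pet_cohort` from [generate_cohort()].
#' @param lesion_mode Lesion subset, as in [select_lesion_subset()].
#' @param feature_groups Subset of `c("BL", "FU", "Response",
#'   "Heterogeneity")`.
#' @return Data frame (patients x features), rows aligned with
#'   `cohort$survival`; attributes `groups` (feature group per retained
#'   column), `n_imputed` and `dropped_constant`.
#' @export
assemble_design_matrix <- function(cohort,
                                   lesion_mode = c("all", "five_biggest", "one_hottest"),
                                   feature_groups = FEATURE_GROUPS) {
  lesion_mode <- match.arg(lesion_mode)
  bad <- setdiff(feature_groups, FEATURE_GROUPS)
  if (length(bad)) {
    stop("unavailable feature group(s): ", paste(bad, collapse = ", "))
  }
  if (!length(feature_groups)) stop("at least one feature group is required")
  rows <- vector("list", cohort$n)
  groups <- NULL
  for (i in seq_len(cohort$n)) {
    p <- cohort$patients[[i]]
    if (lesion_mode == "all") {
      bl_tab <- p$lesions_bl; fu_tab <- p$lesions_fu; tracks <- p$tracks
    } else {
      bl_tab <- select_lesion_subset(p$lesions_bl, lesion_mode)
      fu_tab <- select_lesion_subset(p$lesions_fu, lesion_mode)
      scans <- patient_scans(cohort, i)
      bl_scan <- mask_labels(scans$baseline, bl_tab$lesion_id)
      fu_scan <- mask_labels(scans$followup, fu_tab$lesion_id)
      tracks <- categorize_change(match_lesions(bl_scan, fu_scan), bl_tab, fu_tab)
    }
    v <- patient_feature_row(bl_tab, fu_tab, tracks)
    groups <- attr(v, "groups")
    rows[[i]] <- as.numeric(v)
  }
  if (cohort$n == 0L) {
    template <- patient_feature_row(quantify_lesion_empty(), quantify_lesion_empty(),
                                    categorize_change(
                                      data.frame(baseline_id = integer(0),
                                                 followup_id = integer(0)),
                                      quantify_lesion_empty(), quantify_lesion_empty()))
    x <- matrix(numeric(0), nrow = 0, ncol = length(template),
                dimnames = list(NULL, names(template)))
    groups <- attr(template, "groups")
  } else {
    x <- do.call(rbind, rows)
    colnames(x) <- names(patient_feature_row(
      cohort$patients[[1]]$lesions_bl, cohort$patients[[1]]$lesions_fu,
      cohort$patients[[1]]$tracks))
  }
  keep <- groups %in% feature_groups
  x <- x[, keep, drop = FALSE]
  groups <- groups[keep]
  # drop constant (or all-missing) columns
  if (nrow(x)) {
    is_const <- apply(x, 2, function(col) {
      col <- col[!is.na(col)]
      length(col) == 0L || max(col) - min(col) == 0
    })
  } else {
    is_const <- rep(FALSE, ncol(x))
  }
  dropped <- colnames(x)[is_const]
  x <- x[, !is_const, drop = FALSE]
  groups <- groups[!is_const]
  x <- impute_median(x)
  out <- as.data.frame(x)
  attr(out, "groups") <- stats::setNames(groups, colnames(x))
  attr(out, "n_imputed") <- attr(x, "n_imputed")
  attr(out, "dropped_constant") <- dropped
  out
}

# Zero out all lesion labels not in `keep_ids`.
mask_labels <- function(scan, keep_ids) {
  ll <- scan$lesion_labels
  ll[!(ll %in% keep_ids)] <- 0L
  scan$lesion_labels <- ll
  scan
}
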