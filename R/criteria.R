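# Automated RECIST 1.1, PERCIST and Deauville scoring from lesion features
# and categorized tracks, plus the common 1-5 ordinal scale.

response_assessment <- function(criterion, category, ordinal, target_ids = integer(0)) {
  structure(list(criterion = criterion, category = category,
                 ordinal = ordinal, target_ids = target_ids),
            class = "response_assessment")
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("<%s assessment> %s (ordinal %s)", x$criterion,
              x$category, ifelse(is.na(x$ordinal), "NA", x$ordinal)))
  if (length(x$target_ids)) {
    cat("; targets:", paste(x$target_ids, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Select RECIST target lesions at baseline
#'
#' The five largest lesions by volume, with no more than two per organ
#' (greedy by descending volume, ties by ascending lesion id).
#'
#' @param bl_lesions Baseline lesion feature table.
#' @return Integer vector of at most 5 lesion ids.
#' @export
select_recist_targets <- function(bl_lesions) {
  select_lesion_subset(bl_lesions, "five_biggest")$lesion_id
}

#' Automated RECIST 1.1 category
#'
#' Target sums of long-axis diameters are compared between timepoints over
#' the baseline target lesions (a disappeared target contributes 0 mm at
#' follow-up; with only two timepoints the baseline is the nadir). Any new
#' lesion track means progressive disease. Complete response requires the
#' follow-up target sum to be 0 with no residual lesions anywhere; a drop of
#' at least 30\% is a partial response; an increase of at least 20\% that is
#' also at least 5 mm absolute is progressive disease; anything else is
#' stable disease.
#'
#' @param bl_lesions Baseline lesion feature table.
#' @param tracks Categorized track table.
#' @param fu_lesions Follow-up lesion feature table.
#' @return A `response_assessment` (category `NA` / not evaluable when there
#'   are no baseline lesions).
#' @export
recist_category <- function(bl_lesions, tracks, fu_lesions) {
  targets <- select_recist_targets(bl_lesions)
  if (!length(targets)) {
    return(response_assessment("RECIST", NA_character_, NA_integer_))
  }
  if (any(tracks$category == "new")) {
    return(response_assessment("RECIST", "PD", 4L, targets))
  }
  bl_sum <- sum(bl_lesions$lad_mm[match(targets, bl_lesions$lesion_id)])
  fu_ids <- tracks$followup_id[match(targets, tracks$baseline_id)]
  fu_sum <- sum(fu_lesions$lad_mm[match(fu_ids[!is.na(fu_ids)], fu_lesions$lesion_id)])
  if (fu_sum == 0 && nrow(fu_lesions) == 0L) {
    return(response_assessment("RECIST", "CR", 1L, targets))
  }
  if (bl_sum == 0) {
    # degenerate: all targets single-voxel; no percent change defined
    return(response_assessment("RECIST", "SD", 3L, targets))
  }
  pct <- 100 * (fu_sum - bl_sum) / bl_sum
  cat <- if (pct <= -30) "PR"
  else if (pct >= 20 && (fu_sum - bl_sum) >= 5) "PD"
  else "SD"
  response_assessment("RECIST", cat, to_ordinal_code(cat), targets)
}

#' Automated PERCIST category
#'
#' The target at each timepoint is the lesion with the highest SUVmax in that
#' scan (the two targets may differ); the response measure is the percent
#' change of the targets' SUVpeak. No residual lesions at follow-up is a
#' complete metabolic response; any new lesion is progressive metabolic
#' disease; a drop of at least 30\% is a partial metabolic response; a rise
#' of at least 30\% is progressive metabolic disease; otherwise stable.
#'
#' @inheritParams recist_category
#' @return A `response_assessment` (not evaluable without baseline lesions).
#' @export
percist_category <- function(bl_lesions, fu_lesions, tracks) {
  if (nrow(bl_lesions) == 0L) {
    return(response_assessment("PERCIST", NA_character_, NA_integer_))
  }
  bl_target <- bl_lesions$lesion_id[order(-bl_lesions$suv_max, bl_lesions$lesion_id)][1]
  if (nrow(fu_lesions) == 0L) {
    return(response_assessment("PERCIST", "CMR", 1L, bl_target))
  }
  if (any(tracks$category == "new")) {
    return(response_assessment("PERCIST", "PMD", 4L, bl_target))
  }
  fu_target <- fu_lesions$lesion_id[order(-fu_lesions$suv_max, fu_lesions$lesion_id)][1]
  blp <- bl_lesions$suv_peak[match(bl_target, bl_lesions$lesion_id)]
  fup <- fu_lesions$suv_peak[match(fu_target, fu_lesions$lesion_id)]
  pct <- 100 * (fup - blp) / blp
  cat <- if (pct <= -30) "PMR" else if (pct >= 30) "PMD" else "SMD"
  response_assessment("PERCIST", cat, to_ordinal_code(cat),
                      c(bl_target, fu_target))
}

#' Reference-region SUVmean values of a scan
#'
#' @param scan A `patient_scan` whose organ-label volume includes aorta and
#'   liver regions.
#' @return Named vector `c(aorta =, liver =)` of SUVmean over each region.
#' @export
reference_suv_means <- function(scan) {
  out <- c(aorta = NA_real_, liver = NA_real_)
  for (organ in names(out)) {
    code <- scan$organ_codes[[organ]]
    if (is.null(code)) stop("organ-label map defines no '", organ, "' region")
    idx <- scan$organ_labels == code
    if (!any(idx)) stop("organ-label map defines no '", organ, "' region")
    out[[organ]] <- mean(scan$pet[idx])
  }
  out
}

#' Automated Deauville score
#'
#' Five-point scale on the hottest residual lesion's SUVpeak against the
#' follow-up scan's aorta and liver SUVmean: 1 — no residual lesion (no
#' uptake); 2 — SUVpeak at or below aorta; 3 — above aorta but at or below
#' liver; 4 — above liver but at most 3x liver; 5 — above 3x liver.
#'
#' @param fu_lesions Follow-up lesion feature table.
#' @param aorta_suv_mean,liver_suv_mean Reference SUVmean values, e.g. from
#'   [reference_suv_means()].
#' @return A `response_assessment` with ordinal equal to the score.
#' @export
deauville_score <- function(fu_lesions, aorta_suv_mean, liver_suv_mean) {
  if (is.na(aorta_suv_mean)) stop("missing reference region: aorta")
  if (is.na(liver_suv_mean)) stop("missing reference region: liver")
  if (nrow(fu_lesions) == 0L) {
    return(response_assessment("Deauville", "score1", 1L))
  }
  ord <- order(-fu_lesions$suv_peak, fu_lesions$lesion_id)
  hottest <- fu_lesions[ord[1], ]
  sp <- hottest$suv_peak
  score <- if (sp <= aorta_suv_mean) 2L
  else if (sp <= liver_suv_mean) 3L
  else if (sp <= 3 * liver_suv_mean) 4L
  else 5L
  response_assessment("Deauville", paste0("score", score), score, hottest$lesion_id)
}

to_ordinal_code <- function(category) {
  map <- c(CR = 1L, PR = 2L, SD = 3L, PD = 4L,
           CMR = 1L, PMR = 2L, SMD = 3L, PMD = 4L)
  unname(map[category])
}

#' Map an assessment to the common 1-5 ordinal scale
#'
#' CR/CMR map to 1, PR/PMR to 2, SD/SMD to 3, PD/PMD to 4; a Deauville score
#' k maps to k. Not-evaluable assessments yield `NA` and are excluded from
#' univariable comparator models (their count is logged by the caller).
#'
#' @param assessment A `response_assessment`.
#' @return Integer ordinal, or `NA` for not-evaluable.
#' @export
to_ordinal <- function(assessment) {
  if (is.na(assessment$category)) return(NA_integer_)
  if (assessment$criterion == "Deauville") return(assessment$ordinal)
  to_ordinal_code(assessment$category)
}

#' Assess one patient with all three criteria
#'
#' @param bl_lesions,fu_lesions Lesion feature tables for both timepoints.
#' @param tracks Categorized track table.
#' @param references Named vector `c(aorta =, liver =)` of follow-up
#'   reference SUVmeans.
#' @return Named integer vector of ordinals `c(recist =, percist =,
#'   deauville =)` (`NA` where not evaluable).
#' @export
assess_patient <- function(bl_lesions, fu_lesions, tracks, references) {
  c(recist = to_ordinal(recist_category(bl_lesions, tracks, fu_lesions)),
    percist = to_ordinal(percist_category(bl_lesions, fu_lesions, tracks)),
    deauville = to_ordinal(deauville_score(fu_lesions, references[["aorta"]],
                                           references[["liver"]])))
}
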