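# Longitudinal lesion matching and five-way change categorization.

MATCH_GATE_MM <- 15  # centroid-distance gate for zero-overlap matches

CHANGE_CATEGORIES <- c("new", "increasing", "stable", "decreasing", "disappeared")

lesion_centroids <- function(scan) {
  idx <- which(scan$lesion_labels > 0L)
  if (!length(idx)) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  co <- arrayInd(idx, dim(scan$pet))
  lab <- scan$lesion_labels[idx]
  mm <- sweep(co - 1, 2, scan$spacing, "*")
  out <- rowsum(mm, lab) / as.vector(table(lab))
  colnames(out) <- c("x", "y", "z")
  out  # rownames are label values, sorted ascending
}

#' Match lesions between two co-registered scans
#'
#' Greedy one-to-one matching of baseline against follow-up lesions.
#' Candidate pairs are ranked by voxel-overlap count (descending), then by
#' centroid distance (ascending); pairs with zero overlap are admitted only
#' when their centroids lie within 15 mm. Unmatched baseline lesions become
#' disappeared-candidates, unmatched follow-up lesions new-candidates.
#'
#' @param baseline,followup `patient_scan` objects on the same voxel grid.
#' @return Data frame of tracks with columns `baseline_id` and `followup_id`
#'   (`NA` marks the absent side); categories unset.
#' @export
match_lesions <- function(baseline, followup) {
  if (!identical(dim(baseline$pet), dim(followup$pet)) ||
      !isTRUE(all.equal(baseline$spacing, followup$spacing))) {
    stop("baseline and follow-up scans are not on the same voxel grid")
  }
  bl_ids <- lesion_ids(baseline)
  fu_ids <- lesion_ids(followup)
  cand <- NULL
  if (length(bl_ids) && length(fu_ids)) {
    both <- baseline$lesion_labels > 0L & followup$lesion_labels > 0L
    ov <- if (any(both)) {
      as.data.frame(table(bl = baseline$lesion_labels[both],
                          fu = followup$lesion_labels[both]),
                    stringsAsFactors = FALSE)
    } else {
      data.frame(bl = character(0), fu = character(0), Freq = integer(0))
    }
    ov <- ov[ov$Freq > 0, , drop = FALSE]
    cb <- lesion_centroids(baseline)
    cf <- lesion_centroids(followup)
    g <- expand.grid(bl = bl_ids, fu = fu_ids)
    d <- sqrt(rowSums((cb[as.character(g$bl), , drop = FALSE] -
                         cf[as.character(g$fu), , drop = FALSE])^2))
    key <- paste(g$bl, g$fu)
    overlap <- integer(nrow(g))
    if (nrow(ov)) {
      m <- match(paste(as.integer(ov$bl), as.integer(ov$fu)), key)
      overlap[m] <- ov$Freq
    }
    cand <- data.frame(bl = g$bl, fu = g$fu, overlap = overlap, dist = d)
    cand <- cand[cand$overlap > 0 | cand$dist <= MATCH_GATE_MM, , drop = FALSE]
    cand <- cand[order(-cand$overlap, cand$dist, cand$bl, cand$fu), , drop = FALSE]
  }
  pairs <- data.frame(baseline_id = integer(0), followup_id = integer(0))
  used_bl <- integer(0); used_fu <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      b <- cand$bl[r]; f <- cand$fu[r]
      if (b %in% used_bl || f %in% used_fu) next
      pairs <- rbind(pairs, data.frame(baseline_id = b, followup_id = f))
      used_bl <- c(used_bl, b); used_fu <- c(used_fu, f)
    }
  }
  unb <- setdiff(bl_ids, used_bl)
  unf <- setdiff(fu_ids, used_fu)
  tracks <- rbind(
    pairs,
    data.frame(baseline_id = unb, followup_id = rep(NA_integer_, length(unb))),
    data.frame(baseline_id = rep(NA_integer_, length(unf)), followup_id = unf)
  )
  rownames(tracks) <- NULL
  tracks
}

#' Assign change categories to lesion tracks
#'
#' Applies the five-way rule on percent change in SUVtotal with the
#' baseline value as denominator: unmatched-at-baseline tracks are `new`,
#' unmatched-at-follow-up `disappeared`; matched tracks with change beyond
#' +30\% are `increasing`, beyond -30\% `decreasing`, and within the band
#' (boundary inclusive) `stable`. The +/-30\% band approximates the
#' test-retest repeatability of SUVtotal, so only changes beyond it count as
#' real.
#'
#' @param tracks Track table from [match_lesions()].
#' @param bl_features,fu_features Lesion feature tables from
#'   [quantify_scan()] for the two timepoints.
#' @return `tracks` with `category` and `pct_change_suv_total` columns
#'   (`NA` percent change for new/disappeared tracks).
#' @export
categorize_change <- function(tracks, bl_features, fu_features) {
  n <- nrow(tracks)
  category <- character(n)
  pct <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    b <- tracks$baseline_id[r]; f <- tracks$followup_id[r]
    if (is.na(b)) {
      category[r] <- "new"
    } else if (is.na(f)) {
      category[r] <- "disappeared"
    } else {
      bv <- bl_features$suv_total[match(b, bl_features$lesion_id)]
      fv <- fu_features$suv_total[match(f, fu_features$lesion_id)]
      if (is.na(bv) || is.na(fv)) {
        stop("matched track (", b, ", ", f, ") lacks a feature row")
      }
      if (bv == 0) stop("baseline SUVtotal is 0 for lesion ", b,
                        ": percent change undefined")
      pct[r] <- 100 * (fv - bv) / bv
      category[r] <- if (pct[r] > 30) "increasing"
      else if (pct[r] < -30) "decreasing"
      else "stable"
    }
  }
  tracks$category <- category
  tracks$pct_change_suv_total <- pct
  tracks
}

#' Match and categorize in one step
#'
#' @inheritParams match_lesions
#' @param bl_features,fu_features Optional precomputed [quantify_scan()]
#'   tables; computed from the scans when omitted.
#' @return Categorized track table.
#' @export
track_lesions <- function(baseline, followup,
                          bl_features = quantify_scan(baseline),
                          fu_features = quantify_scan(followup)) {
  categorize_change(match_lesions(baseline, followup), bl_features, fu_features)
}

#' Is a patient's response heterogeneous?
#'
#' TRUE iff the track set holds at least one new-or-increasing and at least
#' one decreasing-or-disappeared lesion.
#'
#' @param tracks Categorized track table.
#' @return Logical scalar; `FALSE` for an empty track list.
#' @export
is_heterogeneous <- function(tracks) {
  if (!nrow(tracks)) return(FALSE)
  any(tracks$category %in% c("new", "increasing")) &&
    any(tracks$category %in% c("decreasing", "disappeared"))
}
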