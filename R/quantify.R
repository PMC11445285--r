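# Per-lesion PET quantification: the six single-timepoint SUV/volume
# features plus the RECIST long-axis diameter.

# Radius (mm) of the 1 cm^3 SUVpeak sphere: (3 * 1000 / (4*pi))^(1/3).
SUVPEAK_RADIUS_MM <- (3 * 1000 / (4 * pi))^(1 / 3)

# Integer voxel offsets whose centers fall within the SUVpeak sphere for a
# given spacing. The inclusion test is voxel-center-in-sphere; no
# partial-volume weighting.
sphere_offsets <- function(spacing, radius = SUVPEAK_RADIUS_MM) {
  m <- floor(radius / spacing)
  g <- expand.grid(dx = -m[1]:m[1], dy = -m[2]:m[2], dz = -m[3]:m[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

#' SUVpeak of a lesion
#'
#' Mean SUV over all voxels of the whole image (not restricted to the lesion
#' mask) whose centers lie within a 1 cm^3 sphere centered on the lesion's
#' hottest voxel. Ties for the hottest voxel are broken by the lowest
#' linear-array index, i.e. lowest (z, y, x) order. The sphere is truncated
#' at the image boundary.
#'
#' @param scan A [patient_scan()].
#' @param lesion_id Positive integer lesion label.
#' @return SUVpeak (SUV).
#' @export
compute_suv_peak <- function(scan, lesion_id) {
  idx <- which(scan$lesion_labels == lesion_id)
  if (!length(idx)) stop("lesion_id ", lesion_id, " not present in lesion_labels")
  center <- idx[which.max(scan$pet[idx])]
  shape <- dim(scan$pet)
  cvox <- as.integer(arrayInd(center, shape))
  off <- sphere_offsets(scan$spacing)
  vx <- sweep(off, 2, cvox, "+")
  keep <- vx[, 1] >= 1 & vx[, 1] <= shape[1] &
    vx[, 2] >= 1 & vx[, 2] <= shape[2] &
    vx[, 3] >= 1 & vx[, 3] <= shape[3]
  vx <- vx[keep, , drop = FALSE]
  lin <- (vx[, 3] - 1L) * shape[1] * shape[2] + (vx[, 2] - 1L) * shape[1] + vx[, 1]
  mean(scan$pet[lin])
}

#' Long-axis diameter of a lesion
#'
#' For each axial slice intersected by the lesion mask, the maximum pairwise
#' in-plane Euclidean distance (mm) between voxel centers of the slice's mask
#' voxels; the returned LAD is the maximum over slices. A slice holding a
#' single voxel contributes 0 mm.
#'
#' @inheritParams compute_suv_peak
#' @return LAD in mm.
#' @export
compute_lad <- function(scan, lesion_id) {
  idx <- which(scan$lesion_labels == lesion_id)
  if (!length(idx)) stop("lesion_id ", lesion_id, " not present in lesion_labels")
  co <- arrayInd(idx, dim(scan$pet))
  best <- 0
  for (z in unique(co[, 3])) {
    pts <- co[co[, 3] == z, 1:2, drop = FALSE]
    if (nrow(pts) < 2L) next
    xy <- cbind((pts[, 1] - 1) * scan$spacing[1], (pts[, 2] - 1) * scan$spacing[2])
    best <- max(best, max(stats::dist(xy)))
  }
  best
}

#' Quantify one lesion
#'
#' Computes the six single-timepoint features plus LAD for one lesion-ROI:
#' SUVmax (hottest voxel), SUVmean (arithmetic mean), SUVhetero (population
#' standard deviation of mask voxel SUVs), volume (ml), SUVtotal
#' (SUVmean x volume, SUV*ml — the total-lesion-glycolysis convention),
#' SUVpeak and LAD. The lesion's organ is the modal organ label over its
#' voxels (ties to the lowest code).
#'
#' @inheritParams compute_suv_peak
#' @return One-row data frame with columns `lesion_id`, `organ`, `suv_max`,
#'   `suv_mean`, `suv_total`, `suv_hetero`, `suv_peak`, `volume_ml`, `lad_mm`.
#' @export
quantify_lesion <- function(scan, lesion_id) {
  idx <- which(scan$lesion_labels == lesion_id)
  if (!length(idx)) stop("lesion_id ", lesion_id, " not present in lesion_labels")
  v <- scan$pet[idx]
  vol_ml <- length(idx) * prod(scan$spacing) / 1000
  orgs <- scan$organ_labels[idx]
  tab <- table(orgs)
  organ_code <- as.integer(names(tab)[which.max(tab)])  # ties: lowest code
  organ_name <- names(scan$organ_codes)[match(organ_code, scan$organ_codes)]
  m <- mean(v)
  data.frame(
    lesion_id = as.integer(lesion_id),
    organ = organ_name %||% as.character(organ_code),
    suv_max = max(v),
    suv_mean = m,
    suv_total = m * vol_ml,
    suv_hetero = sd_pop(v),
    suv_peak = compute_suv_peak(scan, lesion_id),
    volume_ml = vol_ml,
    lad_mm = compute_lad(scan, lesion_id),
    stringsAsFactors = FALSE
  )
}

#' Quantify every lesion in a scan
#'
#' @param scan A [patient_scan()].
#' @return Data frame with one row per distinct positive lesion label, sorted
#'   by `lesion_id`; attribute `lesion_count` holds the row count. An empty
#'   label volume yields a zero-row table.
#' @export
quantify_scan <- function(scan) {
  ids <- lesion_ids(scan)
  out <- if (length(ids)) {
    do.call(rbind, lapply(ids, function(id) quantify_lesion(scan, id)))
  } else {
    quantify_lesion_empty()
  }
  attr(out, "lesion_count") <- nrow(out)
  out
}

quantify_lesion_empty <- function() {
  data.frame(lesion_id = integer(0), organ = character(0),
             suv_max = numeric(0), suv_mean = numeric(0),
             suv_total = numeric(0), suv_hetero = numeric(0),
             suv_peak = numeric(0), volume_ml = numeric(0),
             lad_mm = numeric(0), stringsAsFactors = FALSE)
}
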