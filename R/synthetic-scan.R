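# Synthetic PET/CT scan generation: axis-aligned ellipsoidal lesions with
# Gaussian intra-lesion noise, placed inside a fixed box-organ atlas that
# includes constant-uptake aorta and liver reference regions.

# Voxel center convention used throughout the package: the center of voxel
# (i, j, k) (1-based) lies at ((i-1)*sx, (j-1)*sy, (k-1)*sz) mm. The third
# array axis is axial (z).

ORGAN_UPTAKE <- c(background = 0.4, aorta = 1.9, liver = 2.6,
                  lung_left = 1.0, lung_right = 1.0, mediastinum = 1.0,
                  abdomen = 1.0, pelvis = 1.0, skeleton = 1.0)

# Disjoint fractional boxes (x1,x2, y1,y2, z1,z2 in [0,1]) defining the organ
# label map. The aorta is a thin central column, the liver a larger block;
# the remaining six boxes are generic lesion-bearing regions.
organ_atlas <- function(volume_shape, spacing) {
  frac <- list(
    aorta       = c(0.47, 0.53, 0.47, 0.53, 0.25, 0.75),
    liver       = c(0.12, 0.45, 0.12, 0.45, 0.10, 0.42),
    lung_left   = c(0.05, 0.40, 0.55, 0.95, 0.55, 0.95),
    lung_right  = c(0.60, 0.95, 0.55, 0.95, 0.55, 0.95),
    mediastinum = c(0.55, 0.95, 0.05, 0.45, 0.55, 0.95),
    abdomen     = c(0.55, 0.95, 0.55, 0.95, 0.05, 0.45),
    pelvis      = c(0.05, 0.45, 0.55, 0.95, 0.05, 0.45),
    skeleton    = c(0.05, 0.45, 0.05, 0.45, 0.55, 0.95)
  )
  codes <- c(background = 0L, aorta = 1L, liver = 2L, lung_left = 3L,
             lung_right = 4L, mediastinum = 5L, abdomen = 6L, pelvis = 7L,
             skeleton = 8L)
  boxes <- lapply(frac, function(f) {
    # voxel index ranges, 1-based inclusive
    lo <- pmax(1L, as.integer(ceiling(f[c(1, 3, 5)] * volume_shape)))
    hi <- pmin(volume_shape, as.integer(floor(f[c(2, 4, 6)] * volume_shape)))
    list(lo = lo, hi = hi)
  })
  list(codes = codes, boxes = boxes)
}

#' Construct a single-timepoint patient scan
#'
#' Container for one timepoint's co-registered volumes: PET in SUV units, an
#' integer lesion-label volume (0 = background) and an integer organ-label
#' volume, all on the same voxel grid.
#'
#' @param pet 3D numeric array of SUV values.
#' @param lesion_labels 3D integer array, same shape; positive integers label
#'   lesions, 0 is background.
#' @param organ_labels 3D integer array, same shape, of organ codes.
#' @param spacing Voxel spacing in mm per axis (x, y, z); the third axis is
#'   axial.
#' @param organ_codes Named integer vector mapping organ names (including
#'   `aorta` and `liver`) to label codes.
#' @return An object of class `patient_scan`.
#' @export
patient_scan <- function(pet, lesion_labels, organ_labels, spacing,
                         organ_codes = organ_atlas(dim(pet), spacing)$codes) {
  if (!identical(dim(pet), dim(lesion_labels)) ||
      !identical(dim(pet), dim(organ_labels))) {
    stop("pet, lesion_labels and organ_labels must share the same shape")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three strictly positive mm values")
  }
  structure(list(pet = pet,
                 lesion_labels = lesion_labels,
                 organ_labels = organ_labels,
                 spacing = as.numeric(spacing),
                 organ_codes = organ_codes),
            class = "patient_scan")
}

#' @export
print.patient_scan <- function(x, ...) {
  ids <- lesion_ids(x)
  cat("<patient_scan> ", paste(dim(x$pet), collapse = "x"), " voxels at ",
      paste(x$spacing, collapse = "x"), " mm; ",
      length(ids), " lesion(s)\n", sep = "")
  invisible(x)
}

#' Lesion label values present in a scan
#'
#' @param scan A `patient_scan`.
#' @return Sorted integer vector of positive lesion labels.
#' @export
lesion_ids <- function(scan) {
  sort(unique(scan$lesion_labels[scan$lesion_labels > 0L]))
}

# Linear voxel indices of an axis-aligned ellipsoid, rasterized by the
# voxel-center-inside test.
ellipsoid_voxels <- function(shape, spacing, center, radii) {
  lo <- pmax(1L, as.integer(floor((center - radii) / spacing)) + 1L)
  hi <- pmin(shape, as.integer(ceiling((center + radii) / spacing)) + 1L)
  if (any(lo > hi)) return(integer(0))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  x <- (g$i - 1) * spacing[1]; y <- (g$j - 1) * spacing[2]; z <- (g$k - 1) * spacing[3]
  inside <- ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
    ((z - center[3]) / radii[3])^2 <= 1
  g <- g[inside, , drop = FALSE]
  (g$k - 1L) * shape[1] * shape[2] + (g$j - 1L) * shape[1] + g$i
}

# Axis-wise bounding-box separation test with a safety margin (mm): TRUE when
# the two ellipsoids' boxes are disjoint on at least one axis.
boxes_separated <- function(c1, r1, c2, r2, margin) {
  any(abs(c1 - c2) >= r1 + r2 + margin)
}

# Sample one lesion placement (center mm, radii mm, organ name) that fits in
# an organ box and does not collide with already-placed lesions. Returns NULL
# after `attempts` failures.
place_lesion <- function(profile, atlas, placed, attempts = 200L) {
  shape <- profile$volume_shape; spacing <- profile$voxel_spacing
  organs <- profile$organ_set
  vol <- vapply(atlas$boxes[organs], function(b) prod(pmax(b$hi - b$lo + 1L, 0L)),
                numeric(1))
  pr <- vol / sum(vol)
  rmax_hi <- profile$lesion_radius_range[2]
  for (a in seq_len(attempts)) {
    organ <- sample(organs, 1L, prob = pr)
    b <- atlas$boxes[[organ]]
    radii <- stats::runif(3, profile$lesion_radius_range[1], rmax_hi)
    lo_mm <- (b$lo - 1) * spacing; hi_mm <- (b$hi - 1) * spacing
    lo_c <- lo_mm + radii; hi_c <- hi_mm - radii
    if (any(lo_c > hi_c)) next
    center <- stats::runif(3, lo_c, hi_c)
    # snap to the nearest voxel center so the center voxel is always inside
    center <- round(center / spacing) * spacing
    ok <- TRUE
    for (p in placed) {
      if (!boxes_separated(center, radii, p$center, p$radii, margin = min(spacing))) {
        ok <- FALSE; break
      }
    }
    if (ok) return(list(center = center, radii = radii, organ = organ))
  }
  NULL
}

render_organ_volume <- function(shape, atlas) {
  org <- array(0L, dim = shape)
  for (nm in names(atlas$boxes)) {
    b <- atlas$boxes[[nm]]
    org[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- atlas$codes[[nm]]
  }
  org
}

render_scan <- function(profile, geometry) {
  shape <- profile$volume_shape; spacing <- profile$voxel_spacing
  atlas <- organ_atlas(shape, spacing)
  org <- render_organ_volume(shape, atlas)
  pet <- array(ORGAN_UPTAKE[["background"]], dim = shape)
  for (nm in names(atlas$boxes)) {
    b <- atlas$boxes[[nm]]
    pet[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- ORGAN_UPTAKE[[nm]]
  }
  lab <- array(0L, dim = shape)
  if (nrow(geometry)) {
    for (r in seq_len(nrow(geometry))) {
      idx <- ellipsoid_voxels(shape, spacing,
                              c(geometry$cx[r], geometry$cy[r], geometry$cz[r]),
                              c(geometry$rx[r], geometry$ry[r], geometry$rz[r]))
      lab[idx] <- geometry$id[r]
      pet[idx] <- pmax(0, geometry$mean_suv[r] +
                         stats::rnorm(length(idx), 0, profile$uptake_noise_sd))
    }
  }
  scan <- patient_scan(pet, lab, org, spacing, atlas$codes)
  attr(scan, "lesion_geometry") <- geometry
  scan
}

empty_geometry <- function() {
  data.frame(id = integer(0), organ = character(0),
             cx = numeric(0), cy = numeric(0), cz = numeric(0),
             rx = numeric(0), ry = numeric(0), rz = numeric(0),
             mean_suv = numeric(0))
}

#' Generate a synthetic baseline scan
#'
#' Places `n_lesions` non-overlapping axis-aligned ellipsoidal lesions inside
#' the organ-atlas regions (never the aorta), assigns each a mean uptake drawn
#' from the profile's range, and renders the PET volume as constant organ
#' uptake plus lesion mean uptake with zero-mean Gaussian voxel noise clipped
#' at 0.
#'
#' @param profile A [cohort_profile()].
#' @param rng_seed Integer seed.
#' @param n_lesions Optional lesion count override; by default drawn from the
#'   profile's lesion-count distribution.
#' @return A `patient_scan` with attribute `lesion_geometry` (the generator's
#'   ground-truth placement table).
#' @export
generate_baseline_scan <- function(profile, rng_seed, n_lesions = NULL) {
  with_seed(rng_seed, {
    if (is.null(n_lesions)) n_lesions <- draw_lesion_counts(profile, 1L)
    gen_baseline(profile, n_lesions)
  })
}

gen_baseline <- function(profile, n_lesions) {
  atlas <- organ_atlas(profile$volume_shape, profile$voxel_spacing)
  placed <- list()
  geom <- empty_geometry()
  if (n_lesions > 0) {
    # shrink radii for crowded scans so high counts remain placeable
    radius_hi <- if (n_lesions > 15) min(profile$lesion_radius_range[2], 9) else
      profile$lesion_radius_range[2]
    prof <- profile; prof$lesion_radius_range[2] <- radius_hi
    for (i in seq_len(n_lesions)) {
      p <- place_lesion(prof, atlas, placed)
      if (is.null(p)) {
        stop(sprintf(paste0("could not place lesion %d of %d without overlap in a ",
                            "%s-voxel volume: enlarge volume_shape or reduce the ",
                            "lesion count/radii"),
                     i, n_lesions, paste(profile$volume_shape, collapse = "x")))
      }
      placed[[i]] <- p
      geom <- rbind(geom, data.frame(
        id = i, organ = p$organ,
        cx = p$center[1], cy = p$center[2], cz = p$center[3],
        rx = p$radii[1], ry = p$radii[2], rz = p$radii[3],
        mean_suv = stats::runif(1, profile$uptake_range[1], profile$uptake_range[2])))
    }
  }
  render_scan(profile, geom)
}

# Assign follow-up change categories to k baseline lesions plus a new-lesion
# count, honouring the patient's heterogeneity flag. Heterogeneous patients
# are guaranteed at least one lesion on each side (positive: new/increasing;
# negative: decreasing/disappeared); non-heterogeneous patients draw from one
# side only.
assign_categories <- function(profile, k, heterogeneous) {
  mix <- profile$category_mixture
  cats <- character(k)
  if (heterogeneous) {
    if (k < 1L) stop("a heterogeneous patient needs at least one baseline lesion")
    cats <- sample(names(mix), k, replace = TRUE, prob = mix)
    n_new <- stats::rpois(1, profile$new_rate)
    neg <- cats %in% c("decreasing", "disappeared")
    pos <- cats == "increasing"
    if (!any(neg)) {
      cats[sample.int(k, 1)] <- sample(c("decreasing", "disappeared"), 1)
      neg <- cats %in% c("decreasing", "disappeared")
    }
    if (!any(cats == "increasing") && n_new == 0) {
      idx <- which(!(cats %in% c("decreasing", "disappeared")))
      if (length(idx) && sum(!neg) > 0) {
        cats[idx[sample.int(length(idx), 1)]] <- "increasing"
      } else {
        n_new <- 1L
      }
    }
  } else {
    p_neg <- sum(mix[c("decreasing", "disappeared")]) /
      sum(mix[c("decreasing", "disappeared", "increasing")])
    negative_side <- stats::runif(1) < p_neg
    if (negative_side || k == 0L) {
      sub <- mix[c("stable", "decreasing", "disappeared")]
      n_new <- 0L
    } else {
      sub <- mix[c("stable", "increasing")]
      n_new <- stats::rpois(1, profile$new_rate)
    }
    if (k > 0L) cats <- sample(names(sub), k, replace = TRUE, prob = sub / sum(sub))
    if (k == 0L) n_new <- 0L
  }
  list(categories = cats, n_new = as.integer(n_new))
}

# Follow-up SUVmean scaling factors by category. Margins are chosen so that,
# combined with rasterization-induced volume wobble after jitter, the
# measured SUVtotal change stays well clear of the +/-30% categorization
# band: increasing lands >= +50%, decreasing <= -50%, stable within ~+/-13%.
CATEGORY_SCALING <- list(
  increasing = c(1.7, 2.3),
  stable = c(0.97, 1.03),
  decreasing = c(0.25, 0.42)
)

#' Generate the follow-up scan realizing assigned change categories
#'
#' Persisting lesions keep their baseline geometry up to a small spatial
#' jitter; their mean uptake is rescaled per assigned category so the
#' downstream categorizer recovers the label with margin. Disappeared lesions
#' are removed; new lesions appear only at follow-up (labels continue after
#' the baseline maximum).
#'
#' @param baseline Baseline `patient_scan` produced by
#'   [generate_baseline_scan()] (its `lesion_geometry` attribute is required).
#' @param truth List with `categories` (character vector, one per baseline
#'   lesion, from \{increasing, stable, decreasing, disappeared\}) and `n_new`
#'   (count of new lesions).
#' @param rng_seed Integer seed.
#' @param profile The generating [cohort_profile()].
#' @return A `patient_scan` with attribute `lesion_geometry`.
#' @export
generate_followup_scan <- function(baseline, truth, rng_seed, profile) {
  with_seed(rng_seed, gen_followup(baseline, truth, profile))
}

gen_followup <- function(baseline, truth, profile) {
  geom <- attr(baseline, "lesion_geometry")
  if (is.null(geom)) stop("baseline scan carries no lesion_geometry attribute")
  if (nrow(geom) != length(truth$categories)) {
    stop("truth$categories must assign one category per baseline lesion")
  }
  if (profile$jitter_mm >= 15) {
    warning("follow-up jitter >= the matcher's 15 mm gate; ",
            "ground-truth recovery is not guaranteed")
  }
  spacing <- profile$voxel_spacing
  keep <- truth$categories != "disappeared"
  fu <- geom[keep, , drop = FALSE]
  cats_kept <- truth$categories[keep]
  if (nrow(fu)) {
    for (r in seq_len(nrow(fu))) {
      jit <- stats::runif(3, -profile$jitter_mm, profile$jitter_mm)
      ctr <- round((c(fu$cx[r], fu$cy[r], fu$cz[r]) + jit) / spacing) * spacing
      fu$cx[r] <- ctr[1]; fu$cy[r] <- ctr[2]; fu$cz[r] <- ctr[3]
      sc <- CATEGORY_SCALING[[cats_kept[r]]]
      fu$mean_suv[r] <- fu$mean_suv[r] * stats::runif(1, sc[1], sc[2])
    }
  }
  # new lesions: placed against the persisting lesions' follow-up positions
  n_new <- truth$n_new %||% 0L
  if (n_new > 0L) {
    atlas <- organ_atlas(profile$volume_shape, spacing)
    placed <- lapply(seq_len(nrow(fu)), function(r) {
      list(center = c(fu$cx[r], fu$cy[r], fu$cz[r]),
           radii = c(fu$rx[r], fu$ry[r], fu$rz[r]))
    })
    next_id <- if (nrow(geom)) max(geom$id) else 0L
    for (i in seq_len(n_new)) {
      p <- place_lesion(profile, atlas, placed)
      if (is.null(p)) {
        stop(sprintf("could not place new lesion %d of %d at follow-up: volume too crowded",
                     i, n_new))
      }
      placed[[length(placed) + 1L]] <- p
      fu <- rbind(fu, data.frame(
        id = next_id + i, organ = p$organ,
        cx = p$center[1], cy = p$center[2], cz = p$center[3],
        rx = p$radii[1], ry = p$radii[2], rz = p$radii[3],
        mean_suv = stats::runif(1, profile$uptake_range[1], profile$uptake_range[2])))
    }
  }
  render_scan(profile, fu)
}
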