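# Independent brute-force oracles and small scan builders used across the
# suite. Oracles deliberately use naive enumeration, not the package's code
# paths.

# Build a patient_scan from plain arrays; organs default to a single
# background-coded volume plus aorta/liver boxes when requested.
make_scan <- function(pet, labels = array(0L, dim = dim(pet)),
                      organs = array(0L, dim = dim(pet)),
                      spacing = c(2, 2, 2)) {
  patient_scan(pet, labels, organs, spacing,
               organ_codes = c(background = 0L, aorta = 1L, liver = 2L,
                               organA = 3L, organB = 4L, organC = 5L))
}

# Random labelled scan: k single-blob lesions as random boxes (possibly a
# single voxel), random uptake.
random_scan <- function(shape = c(12, 12, 10), k = 3, spacing = c(2, 2, 3),
                        organs_random = TRUE) {
  pet <- array(stats::runif(prod(shape), 0, 10), dim = shape)
  lab <- array(0L, dim = shape)
  for (id in seq_len(k)) {
    lo <- sapply(shape, function(s) sample.int(s - 3, 1))
    hi <- pmin(shape, lo + sample(0:3, 3, replace = TRUE))
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- id
  }
  org <- if (organs_random) {
    array(sample(0:5, prod(shape), replace = TRUE), dim = shape)
  } else {
    array(0L, dim = shape)
  }
  make_scan(pet, lab, org, spacing)
}

# --- SUVpeak oracle: test every voxel center of the image against the
# sphere around the lesion's first-maximum voxel.
oracle_suv_peak <- function(scan, lesion_id) {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  idx <- which(scan$lesion_labels == lesion_id)
  center_lin <- idx[which.max(scan$pet[idx])]
  cv <- as.integer(arrayInd(center_lin, dim(scan$pet)))
  cmm <- (cv - 1) * scan$spacing
  shape <- dim(scan$pet)
  vals <- c()
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    p <- (c(i, j, k) - 1) * scan$spacing
    if (sum((p - cmm)^2) <= r^2) vals <- c(vals, scan$pet[i, j, k])
  }
  mean(vals)
}

# --- LAD oracle: all-pairs in-plane distances per axial slice.
oracle_lad <- function(scan, lesion_id) {
  co <- which(scan$lesion_labels == lesion_id, arr.ind = TRUE)
  best <- 0
  for (z in unique(co[, 3])) {
    pts <- co[co[, 3] == z, , drop = FALSE]
    if (nrow(pts) < 2) next
    for (a in 1:(nrow(pts) - 1)) for (b in (a + 1):nrow(pts)) {
      d <- sqrt(((pts[a, 1] - pts[b, 1]) * scan$spacing[1])^2 +
                  ((pts[a, 2] - pts[b, 2]) * scan$spacing[2])^2)
      best <- max(best, d)
    }
  }
  best
}

# --- Harrell C-index oracle: explicit double loop over ordered pairs.
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] != 1 || time[i] >= time[j]) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# --- Constrained target-selection oracle: enumerate every subset of at most
# `size` lesions with at most 2 per organ; return the best total volume.
oracle_best_volume <- function(lesions, size = 5) {
  n <- nrow(lesions)
  best <- 0; best_size <- 0
  for (m in seq_len(min(size, n))) {
    combs <- utils::combn(n, m)
    for (cc in seq_len(ncol(combs))) {
      rows <- combs[, cc]
      if (any(table(lesions$organ[rows]) > 2)) next
      if (m > best_size) { best_size <- m; best <- 0 }
      if (m == best_size) best <- max(best, sum(lesions$volume_ml[rows]))
    }
  }
  list(size = best_size, volume = best)
}

# Random lesion feature table (no scan behind it) for subset/criteria tests.
random_lesion_table <- function(n, organs = c("organA", "organB", "organC")) {
  data.frame(
    lesion_id = seq_len(n),
    organ = sample(organs, n, replace = TRUE),
    suv_max = stats::runif(n, 2, 15),
    suv_mean = stats::runif(n, 1, 8),
    suv_total = stats::runif(n, 1, 300),
    suv_hetero = stats::runif(n, 0, 2),
    suv_peak = stats::runif(n, 1, 12),
    volume_ml = stats::runif(n, 0.1, 60),
    lad_mm = stats::runif(n, 2, 80),
    stringsAsFactors = FALSE)
}

# Minimal lesion table builder for hand-constructed criteria cases.
lesion_row <- function(id, organ = "organA", suv_max = 5, suv_peak = 4,
                       volume_ml = 10, lad_mm = 20, suv_mean = 3) {
  data.frame(lesion_id = as.integer(id), organ = organ, suv_max = suv_max,
             suv_mean = suv_mean, suv_total = suv_mean * volume_ml,
             suv_hetero = 0.5, suv_peak = suv_peak, volume_ml = volume_ml,
             lad_mm = lad_mm, stringsAsFactors = FALSE)
}

empty_lesion_table <- function() petHetero::quantify_scan(
  make_scan(array(1, dim = c(4, 4, 4))))

# Simple feature-level survival simulator for harness tests (independent of
# the image pipeline).
sim_survival <- function(n, beta, seed, h0 = 1e-3, cens_max = NULL) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lp <- drop(X %*% beta)
  tm <- stats::rexp(n, h0 * exp(lp))
  cs <- if (is.null(cens_max)) rep(Inf, n) else stats::runif(n, 0, cens_max)
  list(X = X,
       y = data.frame(time_days = pmin(tm, cs), event = as.integer(tm <= cs)),
       lp = lp)
}
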