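#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Per-patient seed derived from the master seed; kept below 2^31 - 1 so it is
# a valid R integer seed. Patient index 0 is reserved for cohort-level draws.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 65011 + 1) * 20011 + index * 7919) %% 2147483646L + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Population standard deviation (divisor N).
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Median-impute NA entries of each column; returns the matrix plus the count
# of imputed cells (attribute "n_imputed").
impute_median <- function(x) {
  n_imp <- 0L
  for (j in seq_len(ncol(x))) {
    bad <- is.na(x[, j])
    if (any(bad)) {
      med <- stats::median(x[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      x[bad, j] <- med
      n_imp <- n_imp + sum(bad)
    }
  }
  attr(x, "n_imputed") <- n_imp
  x
}

# Column z-scores; constant columns map to 0 rather than NaN.
standardize_columns <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  list(x = xs, center = ctr, scale = scl)
}
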