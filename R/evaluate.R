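# Bootstrap model evaluation (per-resample Cox refit + Harrell C-index),
# paired model comparison, and proportional-hazards diagnostics.

#' Shared bootstrap resample indices
#'
#' Generates the n x B index matrix used by [bootstrap_evaluate()]. Models
#' compared with [compare_models()] must be evaluated on the same matrix
#' (the paired design).
#'
#' @param n Cohort size.
#' @param B Number of resamples.
#' @param rng_seed Integer seed.
#' @return Integer matrix (n x B) of with-replacement indices.
#' @export
bootstrap_indices <- function(n, B, rng_seed) {
  with_seed(rng_seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B))
}

#' Bootstrap evaluation of a fixed feature set
#'
#' For each bootstrap resample, refits the Cox model on the resample and
#' computes the Harrell C-index of that fit on the same resample (the
#' in-sample convention; set `out_of_bag = TRUE` to score on the held-out
#' patients instead, as a sensitivity analysis). The model's headline
#' C-index is the median over resamples.
#'
#' @inheritParams fit_cox
#' @param B Number of resamples (ignored when `indices` is supplied).
#' @param rng_seed Seed used to draw indices when `indices` is missing.
#' @param indices Optional precomputed matrix from [bootstrap_indices()];
#'   required for paired comparisons across models.
#' @param out_of_bag Score each fit on its out-of-bag patients.
#' @param label Model label carried into reports.
#' @return An object of class `model_eval`: `label`, `cindex` (length B,
#'   `NA` for failed fits), `median_cindex`, `B`, `features`, `n_failed`,
#'   and the `indices` matrix.
#' @export
bootstrap_evaluate <- function(X, y, B = 1000L, rng_seed = 1L, indices = NULL,
                               out_of_bag = FALSE, label = "model") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 0L) stop("empty feature set")
  y <- as_surv(y)
  n <- nrow(X)
  if (is.null(indices)) indices <- bootstrap_indices(n, B, rng_seed)
  B <- ncol(indices)
  cidx <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- indices[, b]
    f <- quick_cox(X[idx, , drop = FALSE], y[idx, ])
    if (is.null(f)) next
    if (out_of_bag) {
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2L) next
      lp <- X[oob, , drop = FALSE] %*% f$coefficients
      cidx[b] <- harrell_c_index(as.vector(lp), y[oob, "time"], y[oob, "status"])
    } else {
      lp <- X[idx, , drop = FALSE] %*% f$coefficients
      cidx[b] <- harrell_c_index(as.vector(lp), y[idx, "time"], y[idx, "status"])
    }
  }
  n_failed <- sum(is.na(cidx))
  if (n_failed > 0.05 * B) {
    stop(sprintf("evaluation aborted: %d/%d bootstrap fits failed for model '%s'",
                 n_failed, B, label))
  }
  structure(list(label = label,
                 cindex = cidx,
                 median_cindex = stats::median(cidx, na.rm = TRUE),
                 B = B, features = colnames(X), n_failed = n_failed,
                 out_of_bag = out_of_bag,
                 indices = indices),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> %s: median C-index %.3f (SD %.3f) over %d bootstraps%s\n",
              x$label, x$median_cindex, stats::sd(x$cindex, na.rm = TRUE), x$B,
              if (x$n_failed) sprintf(" [%d failed]", x$n_failed) else ""))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Paired bootstrap comparison of two model evaluations
#'
#' Paired t-test on the per-resample C-index differences of two models
#' evaluated on the same bootstrap resamples, with Bonferroni adjustment
#' over the family of comparisons drawn together.
#'
#' @param eval_a,eval_b `model_eval` objects sharing the same resample
#'   indices.
#' @param n_comparisons Bonferroni family size.
#' @return An object of class `model_comparison`: mean paired difference,
#'   bootstrap SE of the differences, t statistic, degrees of freedom, raw
#'   and adjusted p-values.
#' @export
compare_models <- function(eval_a, eval_b, n_comparisons = 1L) {
  if (eval_a$B != eval_b$B) stop("models were evaluated with different B")
  if (!identical(eval_a$indices, eval_b$indices)) {
    stop("models were evaluated on different bootstrap resamples; ",
         "use a shared bootstrap_indices() matrix")
  }
  d <- eval_a$cindex - eval_b$cindex
  d <- d[!is.na(d)]
  B <- length(d)
  se <- stats::sd(d) / sqrt(B)
  mean_d <- mean(d)
  if (se == 0) {
    t_stat <- if (mean_d == 0) 0 else sign(mean_d) * Inf
    p <- if (mean_d == 0) 1 else .Machine$double.xmin
  } else {
    t_stat <- mean_d / se
    p <- 2 * stats::pt(-abs(t_stat), df = B - 1)
    if (p == 0) p <- .Machine$double.xmin
  }
  structure(list(labels = c(eval_a$label, eval_b$label),
                 mean_diff = mean_d, se_diff = se, t = t_stat, df = B - 1,
                 p_value = p,
                 p_adjusted = min(1, p * n_comparisons),
                 n_comparisons = n_comparisons),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  mean paired C-index difference %+.4f (SE %.2g), t = %.3g, adj. p = %.3g\n",
              x$mean_diff, x$se_diff, x$t, x$p_adjusted))
  invisible(x)
}

#' Schoenfeld proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residuals are regressed on the Kaplan-Meier time
#' transform; a score test per covariate plus a global test checks for time
#' trends that violate proportional hazards.
#'
#' @param fit A `cox_fit` from [fit_cox()].
#' @return List with `table` (feature, chisq, df, p — including a GLOBAL
#'   row), `global_p`, and `pass` (`TRUE` when the global p is at least
#'   0.05); all-`NA` result with fewer than 3 events.
#' @export
schoenfeld_ph_test <- function(fit) {
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  if (fit$n_events < 3) {
    return(list(table = NULL, global_p = NA_real_, pass = NA))
  }
  z <- tryCatch(survival::cox.zph(fit$fit, transform = "km", global = TRUE),
                error = function(e) NULL)
  if (is.null(z)) return(list(table = NULL, global_p = NA_real_, pass = NA))
  tab <- data.frame(feature = rownames(z$table),
                    chisq = z$table[, "chisq"],
                    df = z$table[, "df"],
                    p = z$table[, "p"], row.names = NULL)
  gp <- tab$p[tab$feature == "GLOBAL"]
  list(table = tab, global_p = gp, pass = gp >= 0.05)
}
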