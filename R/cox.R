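# Cox proportional-hazards fitting (standardized covariates, Breslow ties)
# and the fast refit path used inside bootstrap loops.

as_surv <- function(y) {
  if (survival::is.Surv(y)) return(y)
  if (is.data.frame(y)) {
    tm <- y$time_days %||% y$time
    ev <- y$event
    if (is.null(tm) || is.null(ev)) stop("y must carry time(_days) and event columns")
    return(survival::Surv(tm, ev))
  }
  stop("y must be a Surv object or a data frame with time and event columns")
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Covariates are z-scored internally, so coefficients are log hazard ratios
#' per standard deviation. The partial likelihood uses Breslow tie handling
#' and is maximized to relative tolerance 1e-9. Wald 95\% confidence
#' intervals and the overall score (logrank) test are reported.
#'
#' @param X Numeric matrix or data frame of covariates (no constant
#'   columns).
#' @param y Survival outcome: a `survival::Surv` object or a data frame with
#'   `time_days`/`time` and `event` columns.
#' @return An object of class `cox_fit` with elements `coefficients`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `score_test_p`, `loglik`,
#'   `converged`, `n`, `n_events`, `center`, `scale` and the underlying
#'   `coxph` fit (`fit`).
#' @export
fit_cox <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as_surv(y)
  if (nrow(X) != nrow(y)) stop("X and y disagree on the number of patients")
  rng <- apply(X, 2, function(v) max(v) - min(v))
  if (any(rng == 0)) {
    stop("constant column(s): ", paste(colnames(X)[rng == 0], collapse = ", "))
  }
  d <- sum(y[, "status"])
  if (d < ncol(X) + 5) {
    stop("too few events (", d, ") for ", ncol(X),
         " covariates; need at least p + 5")
  }
  std <- standardize_columns(X)
  df <- data.frame(std$x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(y ~ ., data = df, ties = "breslow", x = TRUE,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(fit$coefficients))) converged <- FALSE
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    coefficients = stats::setNames(co[, "coef"], colnames(X)),
    se = stats::setNames(co[, "se(coef)"], colnames(X)),
    hr = stats::setNames(exp(co[, "coef"]), colnames(X)),
    ci_lower = stats::setNames(s$conf.int[, "lower .95"], colnames(X)),
    ci_upper = stats::setNames(s$conf.int[, "upper .95"], colnames(X)),
    p = stats::setNames(co[, "Pr(>|z|)"], colnames(X)),
    score_test_p = unname(s$sctest["pvalue"]),
    loglik = fit$loglik,
    converged = converged,
    n = nrow(X), n_events = d,
    center = std$center, scale = std$scale,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d; score test p = %.3g%s\n",
              x$n, x$n_events, x$score_test_p,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    `lower95` = x$ci_lower, `upper95` = x$ci_upper, p = x$p)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
predict.cox_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  as.vector(xs %*% object$coefficients)
}

#' @export
summary.cox_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

# Minimal fast Cox fit for bootstrap loops; returns NULL on failure.
quick_cox <- function(x, y, init = NULL) {
  f <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x, y, strata = NULL, offset = NULL, init = init,
      control = survival::coxph.control(eps = 1e-7, iter.max = 30),
      weights = NULL, method = "breslow", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f$coefficients))) return(NULL)
  f
}

#' Univariable Cox screening
#'
#' Fits one single-covariate Cox model per feature and keeps features whose
#' Wald p-value falls below the threshold (default 0.2), the permissive
#' screen used before multivariable selection.
#'
#' @inheritParams fit_cox
#' @param threshold Wald p-value threshold.
#' @return Character vector of retained feature names, with attribute
#'   `p_values` (all univariable p-values).
#' @export
univariable_screen <- function(X, y, threshold = 0.2) {
  X <- as.matrix(X)
  y <- as_surv(y)
  if (sum(y[, "status"]) == 0) stop("no events: univariable screening impossible")
  pv <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j, drop = FALSE]
    if (max(xj) - min(xj) == 0) return(1)
    f <- quick_cox(xj, y)
    if (is.null(f)) return(1)
    z <- f$coefficients / sqrt(f$var[1, 1])
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  names(pv) <- colnames(X)
  keep <- names(pv)[pv < threshold]
  if (!length(keep)) {
    stop("every feature was screened out at p < ", threshold,
         "; review the data or raise the threshold")
  }
  attr(keep, "p_values") <- pv
  keep
}
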