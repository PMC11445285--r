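#' Fit a prognostic response-heterogeneity survival model
#'
#' The package's central modelling interface. Runs the full outcome-
#' prediction harness on a design matrix: (1) univariable Cox screening at
#' p < 0.2; (2) bootstrapped stepwise backward BIC selection, keeping
#' features whose selection frequency ranks within the top 40th percentile;
#' (3) a multivariable Cox fit (standardized covariates, Breslow ties) on
#' the final feature set; (4) bootstrap evaluation — a Cox refit and a
#' Harrell C-index per resample, summarized by the median; (5) Schoenfeld
#' proportional-hazards diagnostics on the final fit.
#'
#' @param X Patients-by-features design matrix or data frame (e.g. from
#'   [assemble_design_matrix()]).
#' @param y Survival outcome: `survival::Surv` or a data frame with
#'   `time_days` and `event` columns (e.g. `cohort$survival`).
#' @param screen_p Univariable screening threshold.
#' @param B_select Bootstrap resamples for BIC selection.
#' @param B_eval Bootstrap resamples for C-index evaluation.
#' @param top_frac Fraction of top-ranking features kept by selection.
#' @param rng_seed Integer seed.
#' @param indices Optional shared resample matrix from
#'   [bootstrap_indices()] for paired comparisons.
#' @param out_of_bag Score evaluation resamples out-of-bag instead of
#'   in-sample.
#' @param select Run the screen + BIC selection (`TRUE`); `FALSE` fits all
#'   columns of `X` directly (used for prespecified univariable
#'   comparators).
#' @param label Model label.
#' @return An object of class `response_model` with components `screened`,
#'   `selection`, `features`, `fit` (a `cox_fit`), `evaluation`
#'   (a `model_eval`), and `ph_test`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @examples
#' co <- generate_cohort(profile_nsclc(n_patients = 40), master_seed = 7)
#' X <- assemble_design_matrix(co, "all", c("BL", "Heterogeneity"))
#' m <- response_model(X, co$survival, B_select = 20, B_eval = 20,
#'                     rng_seed = 1, label = "demo")
#' print(m)
#' @export
response_model <- function(X, y, screen_p = 0.2, B_select = 1000L,
                           B_eval = 1000L, top_frac = 0.4, rng_seed = 1L,
                           indices = NULL, out_of_bag = FALSE,
                           select = TRUE, label = "response model") {
  X <- as.matrix(X)
  y_surv <- as_surv(y)
  if (select) {
    screened <- univariable_screen(X, y_surv, threshold = screen_p)
    sel <- bootstrap_bic_selection(X[, screened, drop = FALSE], y_surv,
                                   B = B_select,
                                   rng_seed = derive_seed(rng_seed, 1L),
                                   top_frac = top_frac)
    features <- sel$selected
    # practical ceiling: at most 13 features (the documented "fewer than 14")
    # and never more than events - 5, keeping the highest selection
    # frequencies
    cap <- max(1L, min(13L, sum(as_surv(y)[, "status"]) - 5L))
    if (length(features) > cap) {
      ord <- order(-sel$frequencies[features], features)
      features <- features[ord][seq_len(cap)]
      sel$capped <- TRUE
    }
  } else {
    screened <- colnames(X)
    sel <- NULL
    features <- colnames(X)
  }
  fit <- fit_cox(X[, features, drop = FALSE], y_surv)
  evaluation <- bootstrap_evaluate(X[, features, drop = FALSE], y_surv,
                                   B = B_eval,
                                   rng_seed = derive_seed(rng_seed, 2L),
                                   indices = indices,
                                   out_of_bag = out_of_bag, label = label)
  ph <- schoenfeld_ph_test(fit)
  structure(list(label = label, screened = screened, selection = sel,
                 features = features, fit = fit, evaluation = evaluation,
                 ph_test = ph, rng_seed = rng_seed),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("<response_model> ", x$label, "\n", sep = "")
  cat(sprintf("  %d screened -> %d selected feature(s); median C-index %.3f (B = %d)\n",
              length(x$screened), length(x$features),
              x$evaluation$median_cindex, x$evaluation$B))
  cat(sprintf("  overall score test p = %.3g; PH global p = %.3g\n",
              x$fit$score_test_p, x$ph_test$global_p))
  invisible(x)
}

#' @export
summary.response_model <- function(object, ...) {
  print(object)
  cat("\nFinal multivariable Cox fit (coefficients per SD):\n")
  print(object$fit)
  if (!is.null(object$selection)) {
    cat("\nTop selection frequencies:\n")
    print(round(utils::head(object$selection$frequencies, 10), 3))
  }
  invisible(object)
}

#' @export
coef.response_model <- function(object, ...) coef(object$fit)

#' @export
predict.response_model <- function(object, newdata, ...) {
  predict(object$fit, newdata)
}

#' @export
plot.response_model <- function(x, ...) {
  graphics::boxplot(x$evaluation$cindex, ylab = "Harrell C-index",
                    main = x$label, ...)
  invisible(x)
}

#' @export
residuals.response_model <- function(object, type = "martingale", ...) {
  stats::residuals(object$fit$fit, type = type, ...)
}
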