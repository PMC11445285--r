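# Survival harness: C-index, Cox fitting, screening, bootstrapped BIC
# selection, bootstrap evaluation, paired comparison, PH diagnostics.

test_that("C-index forced cases", {
  expect_equal(harrell_c_index(c(3, 2, 1), c(2, 4, 6), c(1, 1, 1)), 1.0)
  expect_equal(harrell_c_index(c(1, 1, 1), c(2, 4, 6), c(1, 1, 1)), 0.5)
  tm <- runif(30, 1, 100)
  expect_equal(harrell_c_index(-tm, tm, rep(1, 30)), 1.0)
  expect_equal(harrell_c_index(tm, tm, rep(1, 30)), 0.0)
  expect_true(is.na(harrell_c_index(c(1, 2), c(5, 5), c(1, 1))))  # no comparable pair
  expect_error(harrell_c_index(c(1, Inf), c(1, 2), c(1, 1)), "finite")
})

test_that("C-index equals the brute-force pair oracle and survival::concordance", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 50
    risk <- sample(c(rnorm(n - 5), rep(0.3, 5)))  # include risk ties
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
    got <- harrell_c_index(risk, tm, ev)
    expect_equal(got, oracle_cindex(risk, tm, ev))
    conc <- survival::concordance(survival::Surv(tm, ev) ~ risk, reverse = TRUE)
    expect_equal(got, unname(conc$concordance), tolerance = 1e-12)
  }
})

test_that("fit_cox matches a grid-search maximization of the Breslow partial likelihood", {
  x <- c(1, 1, 1, 0, 0, 0, 1, 0)
  tm <- c(2, 5, 7, 3, 8, 11, 13, 17)   # no ties
  ev <- c(1, 1, 0, 1, 1, 1, 1, 0)
  y <- data.frame(time_days = tm, event = ev)
  f <- fit_cox(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  # independent partial-likelihood evaluation on the same standardized scale
  z <- (x - mean(x)) / sd(x)
  logpl <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      rs <- which(tm >= tm[i])
      s <- s + b * z[i] - log(sum(exp(b * z[rs])))
    }
    s
  }
  grid <- seq(-3, 3, by = 1e-4)
  best <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(unname(f$coefficients), best, tolerance = 1e-3)
  expect_equal(unname(f$hr), exp(best), tolerance = 1e-3)
})

test_that("fit_cox null behaviour, HR/CI coherence, and input validation", {
  sim <- sim_survival(2000, c(0), seed = 4)
  f <- fit_cox(sim$X, sim$y)
  expect_lt(abs(unname(f$coefficients)), 0.05)
  expect_true(f$ci_lower <= f$hr && f$hr <= f$ci_upper)
  expect_equal(unname(f$hr), exp(unname(f$coefficients)))

  sim2 <- sim_survival(1000, c(0.7), seed = 12)
  f2 <- fit_cox(sim2$X, sim2$y)
  expect_lt(abs(unname(f2$coefficients) - 0.7), 0.1)

  expect_error(fit_cox(cbind(sim$X, const = 1), sim$y), "constant")
  tiny <- sim_survival(8, c(0.5, 0.5), seed = 1)
  tiny$y$event <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_error(fit_cox(tiny$X, tiny$y), "events")
})

test_that("univariable screening keeps signal, rejects on degenerate input", {
  sim <- sim_survival(500, c(0.8, 0, 0), seed = 3)
  keep <- univariable_screen(sim$X, sim$y)
  expect_true("f1" %in% keep)
  y0 <- sim$y; y0$event <- 0L
  expect_error(univariable_screen(sim$X, y0), "events")
  # a feature equal to the true linear predictor is always retained
  X2 <- cbind(sim$X, lp = sim$lp)
  expect_true("lp" %in% univariable_screen(X2, sim$y))
})

test_that("pure-noise features pass the 0.2 screen at roughly the nominal rate", {
  retained <- 0
  for (s in 1:200) {
    set.seed(s)
    n <- 300
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "noise"))
    y <- data.frame(time_days = rexp(n, 1e-3), event = rbinom(n, 1, 0.85))
    keep <- tryCatch(univariable_screen(x, y), error = function(e) character(0))
    retained <- retained + length(keep)
  }
  # binomial(200, 0.2): 40 +/- 3 sd ~ [23, 57]
  expect_gt(retained, 22)
  expect_lt(retained, 58)
})

test_that("backward BIC passes are monotone and respect the stopping rule", {
  sim <- sim_survival(300, c(0.8, -0.6, 0, 0, 0), seed = 21)
  y <- survival::Surv(sim$y$time_days, sim$y$event)
  kept <- petHetero:::bic_backward(sim$X, y)
  d <- sum(sim$y$event)
  bic_of <- function(cols) petHetero:::cox_bic(
    sim$X[, cols, drop = FALSE], y, d, ll0 = NULL)$bic
  expect_lte(bic_of(kept), bic_of(colnames(sim$X)))
  # stopping rule: no single removal improves the final BIC
  if (length(kept) > 1) {
    for (j in seq_along(kept)) {
      expect_gte(bic_of(kept[-j]), bic_of(kept) - 1e-8)
    }
  }
  expect_true(all(c("f1", "f2") %in% kept))
})

test_that("bootstrap BIC selection ranks the true predictor first", {
  sim <- sim_survival(500, c(0.8, rep(0, 9)), seed = 31, cens_max = 3000)
  sel <- bootstrap_bic_selection(sim$X, sim$y, B = 100, rng_seed = 7)
  expect_equal(names(sel$frequencies)[1], "f1")
  expect_true("f1" %in% sel$selected)
  expect_error(bootstrap_bic_selection(sim$X, sim$y, B = 5), "B < 10")
})

test_that("a single-feature selection is all-or-nothing per resample", {
  sim <- sim_survival(300, c(1.2), seed = 8)
  sel <- bootstrap_bic_selection(sim$X, sim$y, B = 20, rng_seed = 2)
  expect_equal(unname(sel$frequencies["f1"]), 1.0)
  simn <- sim_survival(300, c(0), seed = 9)
  seln <- bootstrap_bic_selection(simn$X, simn$y, B = 20, rng_seed = 2)
  expect_lt(unname(seln$frequencies["f1"]), 0.5)
})

test_that("duplicated identical columns are never both retained in one pass", {
  sim <- sim_survival(200, c(0.9), seed = 5)
  X <- cbind(sim$X, f1_copy = sim$X[, 1])
  y <- survival::Surv(sim$y$time_days, sim$y$event)
  for (s in 1:10) {
    set.seed(s)
    idx <- sample.int(200, 200, replace = TRUE)
    kept <- petHetero:::bic_backward(X[idx, ], y[idx, ])
    expect_false(all(c("f1", "f1_copy") %in% kept))
  }
})

test_that("bootstrap evaluation medians behave at the extremes", {
  sim <- sim_survival(400, c(1.5, -1.5), seed = 13, cens_max = 4000)
  ev <- bootstrap_evaluate(sim$X, sim$y, B = 40, rng_seed = 3, label = "signal")
  expect_gt(ev$median_cindex, 0.75)
  expect_true(all(ev$cindex >= 0 & ev$cindex <= 1, na.rm = TRUE))
  expect_equal(ev$median_cindex, median(ev$cindex, na.rm = TRUE))

  simn <- sim_survival(400, c(0, 0), seed = 14, cens_max = 4000)
  evn <- bootstrap_evaluate(simn$X, simn$y, B = 40, rng_seed = 3, label = "null")
  expect_gt(evn$median_cindex, 0.45)   # in-sample optimism bounds it above .5
  expect_lt(evn$median_cindex, 0.60)

  ev1 <- bootstrap_evaluate(sim$X, sim$y, B = 1, rng_seed = 5)
  expect_equal(ev1$median_cindex, ev1$cindex[1])
})

test_that("paired comparisons are symmetric and detect shared-index misuse", {
  sim <- sim_survival(300, c(1, 0), seed = 23, cens_max = 4000)
  idx <- bootstrap_indices(300, 50, rng_seed = 9)
  ea <- bootstrap_evaluate(sim$X[, 1, drop = FALSE], sim$y, indices = idx, label = "signal")
  eb <- bootstrap_evaluate(sim$X[, 2, drop = FALSE], sim$y, indices = idx, label = "noise")
  cm <- compare_models(ea, eb, n_comparisons = 3)
  cm_rev <- compare_models(eb, ea, n_comparisons = 3)
  expect_equal(cm$t, -cm_rev$t)
  expect_equal(cm$p_value, cm_rev$p_value)
  expect_equal(cm$p_adjusted, min(1, cm$p_value * 3))
  expect_gt(cm$mean_diff, 0)

  same <- compare_models(ea, ea)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)

  other <- bootstrap_evaluate(sim$X[, 2, drop = FALSE], sim$y,
                              indices = bootstrap_indices(300, 50, rng_seed = 10))
  expect_error(compare_models(ea, other), "resamples")
  short <- bootstrap_evaluate(sim$X[, 2, drop = FALSE], sim$y,
                              indices = bootstrap_indices(300, 20, rng_seed = 9))
  expect_error(compare_models(ea, short), "different B")
})

test_that("a constant nonzero paired difference reports a floor p-value", {
  ev_a <- structure(list(label = "a", cindex = rep(0.75, 20), median_cindex = 0.75,
                         B = 20L, features = "x", n_failed = 0L,
                         indices = matrix(1L, 2, 20)), class = "model_eval")
  ev_b <- ev_a; ev_b$cindex <- rep(0.70, 20); ev_b$label <- "b"
  cm <- compare_models(ev_a, ev_b)
  expect_equal(cm$mean_diff, 0.05)
  expect_lte(cm$p_value, .Machine$double.xmin)
})

test_that("Schoenfeld diagnostics pass under PH and degrade gracefully", {
  sim <- sim_survival(500, c(0.6, -0.6), seed = 41, cens_max = 4000)
  f <- fit_cox(sim$X, sim$y)
  ph <- schoenfeld_ph_test(f)
  expect_true(is.finite(ph$global_p))
  expect_equal(nrow(ph$table), 3)  # two features + GLOBAL

  # fewer than 3 events: missing result, no crash
  few <- list(n_events = 2)
  class(few) <- "cox_fit"
  out <- schoenfeld_ph_test(few)
  expect_true(is.na(out$global_p))
})

test_that("response_model wires the full harness and its methods cohere", {
  sim <- sim_survival(400, c(0.9, -0.7, rep(0, 6)), seed = 51, cens_max = 4000)
  m <- response_model(sim$X, sim$y, B_select = 30, B_eval = 30,
                      rng_seed = 2, label = "harness test")
  expect_true(all(c("f1", "f2") %in% m$features))
  expect_equal(coef(m), m$fit$coefficients)
  lp <- predict(m, sim$X)
  expect_equal(length(lp), 400)
  expect_gt(harrell_c_index(lp, sim$y$time_days, sim$y$event), 0.65)
  expect_output(print(m), "harness test")
  expect_output(summary(m), "selection frequencies")

  m0 <- response_model(sim$X[, 1, drop = FALSE], sim$y, select = FALSE,
                       B_eval = 10, rng_seed = 3, label = "prespecified")
  expect_equal(m0$features, "f1")
  expect_null(m0$selection)
})
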