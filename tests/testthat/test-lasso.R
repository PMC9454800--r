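test_that("fits satisfy the KKT certificate on random problems", {
  set.seed(11)
  for (rep in 1:25) {
    prob <- random_problem(sample(20:50, 1), sample(2:30, 1))
    amax <- alpha_max(prob$X, prob$y)
    alpha <- amax * 10^runif(1, -3, 0.2)
    fit <- fit_lasso(prob$X, prob$y, alpha)
    expect_lt(kkt_violation(prob$X, prob$y, fit), 1e-6)
  }
})

test_that("single-feature fits match the closed-form soft-threshold solution", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    y <- 0.8 * x + rnorm(n)
    alpha <- 10^runif(1, -4, 0.5)
    fit <- fit_lasso(matrix(x, ncol = 1), y, alpha)
    expect_equal(unname(fit$coefficients),
                 single_feature_lasso(x, y, alpha), tolerance = 1e-8)
  }
})

test_that("penalties at or above alpha_max give the exact null model", {
  set.seed(13)
  prob <- random_problem(30, 8)
  amax <- alpha_max(prob$X, prob$y)
  for (a in c(amax, amax * 1.0001, amax * 100)) {
    fit <- fit_lasso(prob$X, prob$y, a)
    expect_identical(unname(fit$coefficients), rep(0, 8))
    expect_equal(fit$intercept, mean(prob$y))
    expect_equal(fit$n_nonzero, 0)
  }
  # just below alpha_max at least one coefficient activates
  expect_gt(fit_lasso(prob$X, prob$y, amax * 0.99)$n_nonzero, 0)
})

test_that("the alpha -> 0 limit recovers OLS on a tall full-rank problem", {
  set.seed(14)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(200)
  fit <- fit_lasso(X, y, 1e-9)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-4)
})

test_that("coefficients agree with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  for (rep in 1:5) {
    prob <- random_problem(40, 12)
    alpha <- alpha_max(prob$X, prob$y) * 10^runif(1, -2, -0.3)
    ours <- fit_lasso(prob$X, prob$y, alpha)
    g <- glmnet::glmnet(prob$X, prob$y, lambda = alpha, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(ours$coefficients), unname(as.numeric(g$beta)),
                 tolerance = 1e-6)
    expect_equal(ours$intercept, unname(as.numeric(g$a0)), tolerance = 1e-6)
  }
})

test_that("the alpha grid has the right endpoints, spacing and errors", {
  g <- make_alpha_grid()
  expect_length(g, 201)
  expect_identical(g[1], 1e-5)
  expect_identical(g[201], 1e5)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 200), tolerance = 1e-12)
  expect_equal(make_alpha_grid(0.01, 1, 3), c(0.01, 0.1, 1), tolerance = 1e-12)
  expect_identical(make_alpha_grid(2, 8, 2), c(2, 8))
  expect_error(make_alpha_grid(1, 1), "low < high")
  expect_error(make_alpha_grid(1, 10, 1), "at least 2")
})

test_that("LOOCV is deterministic and collapses to fold means at big alpha", {
  out <- generate_cohort(cohort_config(n_patients = 12, n_analytes = 6,
                                       n_undetectable = 0, seed = 2))
  tab <- build_cohort_table(filter_low_detection(out$panel))
  cv1 <- loocv(tab, alpha = 0.05)
  cv2 <- loocv(tab, alpha = 0.05)
  expect_identical(cv1$predictions_days, cv2$predictions_days)
  expect_equal(cv1$rmse_days,
               sqrt(mean((cv1$observed_days - cv1$predictions_days)^2)),
               tolerance = 1e-10)
  expect_equal(cv1$observed_days, out$panel$pfi_days, tolerance = 1e-8)

  # alpha above every fold's alpha_max: prediction = inverted fold-train mean
  big <- loocv(tab, alpha = 1e4)
  expect_true(all(big$fold_coefficients == 0))
  n <- nrow(tab$X)
  expected <- vapply(seq_len(n), function(i)
    invert_transform(mean(tab$y[-i]), tab$pfi_transform), 0)
  expect_equal(big$predictions_days, expected, tolerance = 1e-10)
  expect_error(loocv(tab$X[1:2, ], tab$y[1:2], 0.1, tab$pfi_transform),
               "at least 3")
})

test_that("tuning finds signal supports and the null tail matches theory", {
  out <- make_signal_cohort(seed = 17)
  tab <- build_cohort_table(filter_low_detection(out$panel))
  tun <- tune_alpha(tab)
  # tail of the curve equals the LOOCV mean-predictor RMSE
  n <- nrow(tab$X)
  mean_pred <- vapply(seq_len(n), function(i)
    invert_transform(mean(tab$y[-i]), tab$pfi_transform), 0)
  obs <- invert_transform(tab$y, tab$pfi_transform)
  expect_equal(tun$loocv_rmse_days[length(tun$alphas)],
               sqrt(mean((obs - mean_pred)^2)), tolerance = 1e-8)
  # optimal model support contains the informative set on strong signal
  fit <- fit_lasso(tab$X, tab$y, tun$optimal_alpha)
  expect_true(all(fit$coefficients[out$truth$informative_set] != 0))
  # support shrinks from the small-alpha end to the large-alpha end
  expect_gte(tun$n_nonzero[1], tun$n_nonzero[length(tun$alphas)])
  expect_identical(tun$n_nonzero[length(tun$alphas)], 0)
})

test_that("pure-noise outcomes tune to sparse large-penalty models", {
  res <- vapply(1:20, function(s) {
    out <- generate_cohort(cohort_config(
      n_patients = 20, n_analytes = 10, n_undetectable = 0, n_informative = 0,
      noise_sd = 1, seed = 1000 + s))
    tab <- build_cohort_table(filter_low_detection(out$panel))
    tun <- tune_alpha(tab)
    fit <- fit_lasso(tab$X, tab$y, tun$optimal_alpha)
    c(upper = tun$optimal_alpha > sqrt(1e-5 * 1e5), nnz = fit$n_nonzero)
  }, numeric(2))
  # on noise the typical tuned model is the (near-)null one; the LOOCV curve
  # has shallow spurious minima in a minority of draws, so the robust
  # statements are about medians and a majority rate
  expect_lte(median(res["nnz", ]), 2)
  expect_true(median(res["upper", ]) == 1)
  expect_gte(mean(res["upper", ] & res["nnz", ] <= 2), 0.5)
})

test_that("relax_alpha picks the largest in-budget penalty with flags", {
  curve <- structure(list(alphas = c(0.01, 0.1, 1, 10),
                          loocv_rmse_days = c(10, 12, 18, 40),
                          n_nonzero = c(8L, 5L, 2L, 0L),
                          optimal_alpha = 0.01, optimal_rmse_days = 10, n = 20),
                     class = "alpha_tuning")
  r <- relax_alpha(curve, 20)
  expect_equal(r$alpha, 1)
  expect_true(r$feasible)
  expect_equal(r$rmse_days, 18)
  # budget at the minimum returns the largest alpha attaining it
  curve$loocv_rmse_days <- c(10, 10, 18, 40)
  expect_equal(relax_alpha(curve, 10)$alpha, 0.1)
  # infinite budget returns the top of the grid
  expect_equal(relax_alpha(curve, Inf)$alpha, 10)
  # infeasible budget falls back to the optimum and says so
  r2 <- relax_alpha(curve, 5)
  expect_false(r2$feasible)
  expect_equal(r2$alpha, curve$optimal_alpha)
})

test_that("nested LOOCV pools one error per patient and is not optimistic", {
  out <- generate_cohort(cohort_config(n_patients = 12, n_analytes = 8,
                                       n_undetectable = 0, seed = 19))
  tab <- build_cohort_table(filter_low_detection(out$panel))
  grid <- make_alpha_grid(1e-3, 10, 15)
  nest <- nested_loocv_rmse(tab, grid = grid)
  expect_length(nest$predictions_days, 12)
  expect_length(nest$chosen_alphas, 12)
  expect_gte(nest$rmse_days, 0)
  # tuned non-nested LOOCV is the optimistic one on most cohorts; check the
  # direction on a handful of seeds rather than a single draw
  cmp <- vapply(1:10, function(s) {
    o <- generate_cohort(cohort_config(n_patients = 12, n_analytes = 8,
                                       n_undetectable = 0, seed = 100 + s))
    tb <- build_cohort_table(filter_low_detection(o$panel))
    tn <- tune_alpha(tb, grid = grid)
    nn <- nested_loocv_rmse(tb, grid = grid)
    nn$rmse_days >= tn$optimal_rmse_days
  }, NA)
  expect_gte(mean(cmp), 0.8)
})

test_that("minimal nested LOOCV runs with four patients", {
  set.seed(20)
  X <- matrix(rnorm(4 * 3), 4, 3)
  y <- rnorm(4)
  t <- fit_yeo_johnson(c(100, 150, 220, 300))
  nest <- nested_loocv_rmse(X, y, make_alpha_grid(0.01, 1, 5), t)
  expect_length(nest$predictions_days, 4)
  expect_true(is.finite(nest$rmse_days))
})

test_that("cross-cohort prediction is self-consistent and flags missing analytes", {
  out <- make_signal_cohort(seed = 23)
  panel <- filter_low_detection(out$panel)
  tab <- build_cohort_table(panel)
  fit <- fit_lasso(tab$X, tab$y, 0.1)
  # target = source cohort reproduces the in-sample RMSE
  cp <- cross_predict(fit, tab, panel)
  insample <- invert_transform(fit$intercept + drop(tab$X %*% fit$coefficients),
                               tab$pfi_transform)
  expect_equal(cp$rmse_days, sqrt(mean((panel$pfi_days - insample)^2)),
               tolerance = 1e-8)
  expect_length(cp$missing_features, 0)

  # all-zero model predicts the inverted source mean everywhere
  null_fit <- fit_lasso(tab$X, tab$y, 1e4)
  cp0 <- cross_predict(null_fit, tab, panel)
  expect_equal(unique(round(cp0$predictions_days, 6)),
               round(invert_transform(mean(tab$y), tab$pfi_transform), 6))

  # dropping an analyte from the target holds it at the source mean
  drop1 <- panel_drop_analyte(panel, names(which(fit$coefficients != 0))[1])
  cp1 <- cross_predict(fit, tab, drop1)
  expect_equal(cp1$missing_features, names(which(fit$coefficients != 0))[1])
})

test_that("cross-cohort RMSE exceeds within-cohort LOOCV RMSE across true models", {
  worse <- vapply(1:20, function(s) {
    a <- generate_cohort(cohort_config(n_patients = 20, n_analytes = 15,
                                       n_undetectable = 0, seed = 3000 + s))
    b <- generate_cohort(cohort_config(n_patients = 20, n_analytes = 15,
                                       n_undetectable = 0, cohort_label = "PDS",
                                       seed = 4000 + s))
    ta <- build_cohort_table(filter_low_detection(a$panel))
    tun <- tune_alpha(ta, grid = make_alpha_grid(1e-3, 10, 25))
    fit <- fit_lasso(ta$X, ta$y, tun$optimal_alpha)
    cross <- cross_predict(fit, ta, filter_low_detection(b$panel))
    cross$rmse_days > tun$optimal_rmse_days
  }, NA)
  expect_gte(mean(worse), 0.9)
})
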