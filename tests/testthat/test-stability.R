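# build a stability report from hand-placed fold coefficients
report_from <- function(B, full_w, alpha = 0.1) {
  n <- nrow(B)
  colnames(B) <- names(full_w)
  t <- fit_yeo_johnson(seq(100, 100 + n) + 0)
  cv <- structure(list(fold_ids = as.character(seq_len(n)),
                       predictions_days = rep(100, n),
                       observed_days = rep(100, n), rmse_days = 0,
                       fold_coefficients = B, fold_intercepts = rep(0, n),
                       alpha = alpha, n = n), class = "pfi_cv")
  fit <- structure(list(alpha = alpha,
                        coefficients = full_w, intercept = 0,
                        feature_names = names(full_w),
                        n_nonzero = sum(full_w != 0)), class = "lasso_fit")
  stability_report(cv, fit)
}

test_that("fold statistics and %CV follow the definitions exactly", {
  B <- cbind(a = c(2, 2, 2), b = c(1, 0, 0), c = c(0, 0, 0))
  r <- report_from(B, c(a = 2, b = 0.5, c = 0))
  f <- r$features
  # constant coefficient: SD 0, %CV 0
  expect_equal(f$fold_sd[f$feature == "a"], 0)
  expect_equal(f$pct_cv[f$feature == "a"], 0)
  # intermittent feature: stats over ALL folds, zeros included
  expect_equal(f$fold_mean[f$feature == "b"], 1 / 3)
  expect_equal(f$fold_sd[f$feature == "b"], sd(c(1, 0, 0)))
  expect_equal(f$pct_cv[f$feature == "b"], sd(c(1, 0, 0)) / (1 / 3) * 100)
  expect_equal(f$inclusion_count, c(3L, 1L, 0L))
  # zero fold mean: %CV undefined
  expect_true(is.na(f$pct_cv[f$feature == "c"]))
  # aggregate averages defined %CVs of full-model nonzero features (a, b)
  expect_equal(r$aggregate_pct_cv,
               mean(c(0, sd(c(1, 0, 0)) / (1 / 3) * 100)))
  expect_equal(r$n_features_full_model, 2)
  expect_equal(r$n_features_all_folds, 1)  # only a is in every fold
})

test_that("four-fold single-inclusion example from first principles", {
  B <- cbind(f1 = c(1, 0, 0, 0))
  r <- report_from(B, c(f1 = 1))
  expect_equal(r$features$inclusion_count, 1L)
  expect_equal(r$features$fold_mean, 0.25)
  expect_equal(r$features$fold_sd, sd(c(1, 0, 0, 0)))
})

test_that("%CV is invariant to rescaling a feature's fold coefficients", {
  set.seed(41)
  B <- cbind(u = rnorm(6, 1, 0.2), v = rnorm(6, -2, 0.5))
  r1 <- report_from(B, c(u = 1, v = -2))
  B2 <- B
  B2[, "u"] <- B[, "u"] * -7.3
  r2 <- report_from(B2, c(u = -7.3, v = -2))
  expect_equal(r1$features$pct_cv, r2$features$pct_cv, tolerance = 1e-12)
})

test_that("aggregate %CV is NA for an empty model and mismatches raise", {
  B <- cbind(a = c(0, 0, 0), b = c(0, 0, 0))
  r <- report_from(B, c(a = 0, b = 0))
  expect_true(is.na(r$aggregate_pct_cv))
  expect_equal(r$n_features_full_model, 0)

  out <- generate_cohort(cohort_config(n_patients = 10, n_analytes = 4,
                                       n_informative = 2, n_undetectable = 0,
                                       seed = 1))
  tab <- build_cohort_table(filter_low_detection(out$panel))
  cv <- loocv(tab, alpha = 0.1)
  fit <- fit_lasso(tab$X[, 1:3], tab$y, 0.1)
  expect_error(stability_report(cv, fit), "do not match")
})

test_that("model comparison reports support overlap, signs and deltas", {
  B <- cbind(a = rep(0.5, 3), b = rep(-1, 3), c = rep(0.2, 3))
  r_opt <- report_from(B, c(a = 0.5, b = -1, c = 0.2))
  r_rel <- report_from(B * c(1, 1, 0), c(a = 0.4, b = -0.8, c = 0))

  cmp <- compare_models(r_opt, r_rel, rmse_opt = 5, rmse_relaxed = 18)
  expect_setequal(cmp$shared_features, c("a", "b"))
  expect_equal(cmp$dropped_features, "c")
  expect_length(cmp$added_features, 0)
  expect_equal(cmp$sign_agreement_fraction, 1)
  expect_equal(cmp$delta_rmse_days, 13)

  # identical reports: full agreement, nothing dropped or added
  same <- compare_models(r_opt, r_opt, 5, 5)
  expect_equal(same$sign_agreement_fraction, 1)
  expect_length(same$dropped_features, 0)
  expect_equal(same$delta_rmse_days, 0)

  # disjoint supports: agreement undefined
  r_other <- report_from(B * c(0, 0, 1), c(a = 0, b = 0, c = 0.2))
  dis <- compare_models(r_rel, r_other, 1, 1)
  expect_length(dis$shared_features, 0)
  expect_true(is.na(dis$sign_agreement_fraction))
})

test_that("features rank by signed coefficient with alphabetical ties", {
  B <- cbind(a = rep(0.5, 3), b = rep(-0.3, 3), c = rep(0, 3))
  r <- report_from(B, c(a = 0.5, b = -0.3, c = 0))
  expect_equal(rank_features(r), c("a", "c", "b"))
  r0 <- report_from(B * 0, c(a = 0, b = 0, c = 0))
  expect_equal(rank_features(r0), c("a", "b", "c"))
})

test_that("a dominant positive effect ranks first on most replicates", {
  first <- vapply(1:20, function(s) {
    out <- generate_cohort(cohort_config(
      n_patients = 25, n_analytes = 10, n_undetectable = 0, n_informative = 1,
      beta_magnitude = 1, noise_sd = 0.1, seed = 500 + s))
    if (out$truth$true_beta[out$truth$informative_set] < 0) return(NA)
    tab <- build_cohort_table(filter_low_detection(out$panel))
    fit <- fit_lasso(tab$X, tab$y, 0.05)
    cv <- loocv(tab, alpha = 0.05)
    rank_features(stability_report(cv, fit))[1] == out$truth$informative_set
  }, NA)
  expect_gte(mean(first, na.rm = TRUE), 0.95)
})
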