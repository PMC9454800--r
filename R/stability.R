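#' Fold-wise coefficient stability of a Lasso model
#'
#' Summarizes how stable each feature's coefficient is across the LOOCV
#' folds of a fitted model: per-feature mean and SD over ALL folds (zeros
#' included — statistics are not conditional on inclusion), the percent
#' coefficient of variation
#' \deqn{\%CV = \frac{\mathrm{coefficient\ SD}}{|\mathrm{mean\ coefficient}|}
#'   \times 100\%,}
#' the number of folds in which the feature received a nonzero coefficient,
#' and the full-data coefficient.  %CV is undefined (`NA`) when the fold
#' mean is numerically zero (`|mean| <= 1e-12`).  The cohort-level
#' `aggregate_pct_cv` averages %CV over the features that are nonzero in
#' the full model and have a defined %CV (`NA` when no feature qualifies,
#' e.g. for an empty model); `n_features_all_folds` counts full-model
#' features used in every fold.
#'
#' @param cv a `pfi_cv` from [loocv()].
#' @param full_fit the `lasso_fit` trained on the whole cohort at the same
#'   penalty; its feature set must match the fold coefficient columns.
#' @return Object of class `stability_report`: `features` (data frame with
#'   columns `feature`, `full_model_coefficient`, `fold_mean`, `fold_sd`,
#'   `pct_cv`, `inclusion_count`, `inclusion_fraction`), plus scalars
#'   `n_folds`, `aggregate_pct_cv`, `n_features_full_model`,
#'   `n_features_all_folds`, `alpha`.
#' @export
stability_report <- function(cv, full_fit) {
  stopifnot(inherits(cv, "pfi_cv"), inherits(full_fit, "lasso_fit"))
  if (!identical(colnames(cv$fold_coefficients), full_fit$feature_names))
    stop("fold coefficient columns do not match the full model's features")
  B <- cv$fold_coefficients
  fold_mean <- colMeans(B)
  fold_sd <- apply(B, 2, sd)
  pct_cv <- ifelse(abs(fold_mean) > 1e-12, fold_sd / abs(fold_mean) * 100,
                   NA_real_)
  inclusion <- colSums(B != 0)
  feat <- data.frame(feature = full_fit$feature_names,
                     full_model_coefficient = unname(full_fit$coefficients),
                     fold_mean = unname(fold_mean),
                     fold_sd = unname(fold_sd),
                     pct_cv = unname(pct_cv),
                     inclusion_count = unname(inclusion),
                     inclusion_fraction = unname(inclusion / nrow(B)),
                     stringsAsFactors = FALSE)
  in_full <- full_fit$coefficients != 0
  qual <- in_full & !is.na(pct_cv)
  agg <- if (any(qual)) mean(pct_cv[qual]) else NA_real_
  structure(list(features = feat,
                 n_folds = nrow(B),
                 aggregate_pct_cv = agg,
                 n_features_full_model = sum(in_full),
                 n_features_all_folds = sum(in_full & inclusion == nrow(B)),
                 alpha = full_fit$alpha),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability over %d LOOCV folds at alpha = %.4g\n",
              x$n_folds, x$alpha))
  cat(sprintf("  %d features in the full model; %d used in every fold\n",
              x$n_features_full_model, x$n_features_all_folds))
  cat(sprintf("  aggregate %%CV (full-model features): %.1f%%\n",
              x$aggregate_pct_cv))
  invisible(x)
}

#' Write a stability report as TSV
#'
#' One row per feature: full-model coefficient, fold mean, fold SD, %CV,
#' inclusion count.
#'
#' @param report a [stability_report()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_stability_report <- function(report, file) {
  stopifnot(inherits(report, "stability_report"))
  utils::write.table(report$features, file, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Compare the structure of two Lasso models of one cohort
#'
#' Typically compares the accuracy-optimal and the error-budget-relaxed
#' model: shared/dropped/added support (from the full-model nonzero sets),
#' the fraction of shared features whose coefficient signs agree, and the
#' RMSE and aggregate-%CV deltas (relaxed minus optimal).
#'
#' @param report_opt,report_relaxed [stability_report()]s from the same
#'   cohort table.
#' @param rmse_opt,rmse_relaxed LOOCV RMSEs (days) of the two models.
#' @return Object of class `model_comparison`: `shared_features`,
#'   `dropped_features`, `added_features`, `sign_agreement_fraction` (`NA`
#'   when no features are shared), `delta_rmse_days`,
#'   `delta_aggregate_pct_cv`.
#' @export
compare_models <- function(report_opt, report_relaxed, rmse_opt, rmse_relaxed) {
  stopifnot(inherits(report_opt, "stability_report"),
            inherits(report_relaxed, "stability_report"))
  f1 <- report_opt$features
  f2 <- report_relaxed$features
  s1 <- f1$feature[f1$full_model_coefficient != 0]
  s2 <- f2$feature[f2$full_model_coefficient != 0]
  shared <- intersect(s1, s2)
  agree <- if (length(shared)) {
    c1 <- f1$full_model_coefficient[match(shared, f1$feature)]
    c2 <- f2$full_model_coefficient[match(shared, f2$feature)]
    mean(sign(c1) == sign(c2))
  } else NA_real_
  structure(list(shared_features = shared,
                 dropped_features = setdiff(s1, s2),
                 added_features = setdiff(s2, s1),
                 sign_agreement_fraction = agree,
                 delta_rmse_days = rmse_relaxed - rmse_opt,
                 delta_aggregate_pct_cv =
                   report_relaxed$aggregate_pct_cv - report_opt$aggregate_pct_cv),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: %d shared, %d dropped, %d added features\n",
              length(x$shared_features), length(x$dropped_features),
              length(x$added_features)))
  if (!is.na(x$sign_agreement_fraction))
    cat(sprintf("  sign agreement on shared features: %.0f%%\n",
                100 * x$sign_agreement_fraction))
  cat(sprintf("  delta RMSE = %+.2f days, delta aggregate %%CV = %+.1f\n",
              x$delta_rmse_days, x$delta_aggregate_pct_cv))
  invisible(x)
}

#' Rank features by full-model coefficient
#'
#' Features sorted by signed full-model coefficient, descending (the most
#' positively weighted analyte — longest-PFI association — first); ties
#' broken alphabetically for determinism.
#'
#' @param report a [stability_report()].
#' @return character vector of feature names.
#' @export
rank_features <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  f <- report$features
  f$feature[order(-f$full_model_coefficient, f$feature)]
}
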