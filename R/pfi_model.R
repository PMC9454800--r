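#' Fit a stability-tuned Lasso model of the platinum-free interval
#'
#' The package's front door.  From a raw censored assay panel it runs the
#' full pipeline: the 75% detection filter, censoring imputation, log10 and
#' per-analyte Yeo-Johnson standardization ([build_cohort_table()]),
#' penalty tuning by leave-one-out cross-validation over a log-spaced grid
#' ([tune_alpha()]), selection of the working penalty — the
#' accuracy-optimal one, an error-budget-relaxed one ([relax_alpha()]), or
#' a number you supply — a full-cohort Lasso fit at that penalty, LOOCV at
#' that penalty, and a fold-wise stability report ([stability_report()]).
#'
#' @param panel an [assay_panel()] (raw; filtering happens here).
#' @param alpha `"relaxed"` (default), `"optimal"`, or a positive number.
#' @param budget_days positive; tolerated LOOCV RMSE for the relaxed
#'   penalty (default 20 days).
#' @param grid penalty grid, default [make_alpha_grid()].
#' @param min_detected_fraction detection-filter threshold, default 0.75.
#' @param nested logical; if `TRUE`, also compute the nested-LOOCV RMSE
#'   (slower; an honest generalization estimate for the tuned model).
#' @return Object of class `pfi_lasso` with components `fit`
#'   (`lasso_fit`), `tuning` (`alpha_tuning`), `relaxed`
#'   (`relaxed_alpha`), `cv` (`pfi_cv` at the working penalty),
#'   `stability` (`stability_report`), `table` (`cohort_table`), `alpha`,
#'   `alpha_rule`, `nested` (or `NULL`), `call`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' fit <- pfi_lasso(cohort$panel)
#' print(fit)
#' head(coef(fit))
#' @export
pfi_lasso <- function(panel, alpha = c("relaxed", "optimal"),
                      budget_days = 20, grid = make_alpha_grid(),
                      min_detected_fraction = 0.75, nested = FALSE) {
  stopifnot(inherits(panel, "assay_panel"))
  filtered <- filter_low_detection(panel, min_detected_fraction)
  table <- build_cohort_table(filtered)
  tuning <- tune_alpha(table, grid = grid)
  relaxed <- relax_alpha(tuning, budget_days)
  if (is.numeric(alpha)) {
    rule <- "fixed"
    a <- alpha
  } else {
    rule <- match.arg(alpha)
    a <- if (rule == "relaxed") relaxed$alpha else tuning$optimal_alpha
  }
  fit <- fit_lasso(table$X, table$y, a)
  cv <- loocv(table, alpha = a)
  stab <- stability_report(cv, fit)
  nested_res <- if (isTRUE(nested))
    nested_loocv_rmse(table, grid = grid) else NULL
  structure(list(fit = fit, tuning = tuning, relaxed = relaxed, cv = cv,
                 stability = stab, table = table, alpha = a,
                 alpha_rule = rule, nested = nested_res,
                 cohort_label = table$cohort_labels[1],
                 call = match.call()),
            class = "pfi_lasso")
}

#' @export
print.pfi_lasso <- function(x, ...) {
  cat(sprintf("Lasso PFI model, %s cohort: %d patients, %d analytes after filtering\n",
              x$cohort_label, nrow(x$table$X), ncol(x$table$X)))
  cat(sprintf("  penalty: alpha = %.4g (%s; optimal = %.4g, relaxed@%.0fd = %.4g)\n",
              x$alpha, x$alpha_rule, x$tuning$optimal_alpha,
              x$relaxed$budget_days, x$relaxed$alpha))
  cat(sprintf("  LOOCV RMSE = %.2f days; %d nonzero coefficients\n",
              x$cv$rmse_days, x$fit$n_nonzero))
  if (!is.null(x$nested))
    cat(sprintf("  nested LOOCV RMSE = %.2f days\n", x$nested$rmse_days))
  cat(sprintf("  stability: aggregate %%CV = %.1f%%; %d/%d features in all folds\n",
              x$stability$aggregate_pct_cv,
              x$stability$n_features_all_folds,
              x$stability$n_features_full_model))
  invisible(x)
}

#' @export
coef.pfi_lasso <- function(object, ...) coef(object$fit)

#' Predict PFI in days
#'
#' Without `newdata`, returns the full-cohort model's in-sample
#' predictions, inverted to days.  With `newdata` (an [assay_panel()],
#' e.g. the other treatment cohort), the panel is preprocessed with THIS
#' model's fitted transforms, model features absent from the panel are held
#' at the training-cohort mean, and predictions are returned in days — the
#' cross-cohort protocol of [cross_predict()].
#'
#' @param object a [pfi_lasso()] model.
#' @param newdata optional `assay_panel`.
#' @param ... unused.
#' @return numeric vector of predicted PFIs, days.
#' @export
predict.pfi_lasso <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    pred_t <- object$fit$intercept +
      drop(object$table$X %*% object$fit$coefficients)
    days <- invert_days_safe(pred_t, object$table$pfi_transform,
                             10 * max(object$table$pfi_days))
    return(stats::setNames(days, object$table$patient_ids))
  }
  stopifnot(inherits(newdata, "assay_panel"))
  cp <- cross_predict(object$fit, object$table, newdata)
  stats::setNames(cp$predictions_days, newdata$patient_ids)
}

#' @export
fitted.pfi_lasso <- function(object, ...) predict(object)

#' @export
residuals.pfi_lasso <- function(object, ...) {
  stats::setNames(object$table$pfi_days - predict(object),
                  object$table$patient_ids)
}

#' @export
summary.pfi_lasso <- function(object, ...) {
  feat <- object$stability$features
  feat <- feat[feat$full_model_coefficient != 0, ]
  feat <- feat[order(-abs(feat$full_model_coefficient)), ]
  structure(list(model = object, features = feat), class = "summary.pfi_lasso")
}

#' @export
print.summary.pfi_lasso <- function(x, ...) {
  print(x$model)
  cat("\nNonzero coefficients (by |coefficient|):\n")
  f <- x$features
  f$full_model_coefficient <- round(f$full_model_coefficient, 4)
  f$fold_mean <- round(f$fold_mean, 4)
  f$fold_sd <- round(f$fold_sd, 4)
  f$pct_cv <- round(f$pct_cv, 1)
  print(f, row.names = FALSE)
  invisible(x)
}

#' Diagnostic plots for a fitted PFI Lasso model
#'
#' `which = 1`: the LOOCV tuning curve (RMSE in days vs log10 penalty) with
#' the optimal and working penalties and the error budget marked.
#' `which = 2`: the nonzero full-model coefficients as a horizontal bar
#' chart (positive bars associate with longer PFI).
#' `which = 3`: observed vs LOOCV-predicted PFI in days.
#'
#' @param x a [pfi_lasso()] model.
#' @param which subset of `1:3`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.pfi_lasso <- function(x, which = 1:3, ...) {
  if (1 %in% which) {
    plot(log10(x$tuning$alphas), x$tuning$loocv_rmse_days, type = "l",
         xlab = "log10(alpha)", ylab = "LOOCV RMSE (days)",
         main = "Penalty tuning", ...)
    abline(v = log10(x$tuning$optimal_alpha), lty = 2, col = "grey40")
    abline(v = log10(x$alpha), lty = 1, col = "firebrick")
    abline(h = x$relaxed$budget_days, lty = 3, col = "steelblue")
    legend("topleft", bty = "n", lty = c(2, 1, 3),
           col = c("grey40", "firebrick", "steelblue"),
           legend = c("optimal", "working", "error budget"))
  }
  if (2 %in% which) {
    w <- sort(x$fit$coefficients[x$fit$coefficients != 0])
    if (length(w)) {
      op <- par(mar = c(4, 7, 2, 1))
      on.exit(par(op))
      barplot(w, horiz = TRUE, las = 1, cex.names = 0.6,
              xlab = "coefficient (transformed units)",
              main = "Nonzero coefficients", ...)
    }
  }
  if (3 %in% which) {
    plot(x$cv$observed_days, x$cv$predictions_days,
         xlab = "Observed PFI (days)", ylab = "LOOCV-predicted PFI (days)",
         main = sprintf("LOOCV, RMSE = %.1f days", x$cv$rmse_days), ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}
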