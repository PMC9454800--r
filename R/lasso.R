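#' Fit a Lasso regression at a fixed penalty
#'
#' Minimizes the standard scaled objective
#' \deqn{\frac{1}{2n}\sum_i (y_i - b - x_i^\top w)^2 + \alpha \sum_j |w_j|}
#' with an unpenalized intercept \eqn{b}, by cyclic coordinate descent on
#' the centered Gram system (warm-started along a short internal path for
#' numerical robustness).  Any reported `alpha` is tied to this `1/(2n)`
#' scaling.  Convergence is declared when the largest scaled coefficient
#' update in a sweep falls below 1e-9, well inside the 1e-7 contract.
#'
#' At \eqn{\alpha \ge \alpha_{max} = \max_j |x_j^\top (y - \bar y)|/n} the
#' solution is exactly the null model (all coefficients zero, intercept
#' \eqn{\bar y}); see [alpha_max()].
#'
#' @param X numeric matrix, patients x features, finite; typically the
#'   standardized `X` of a [build_cohort_table()].
#' @param y numeric vector, finite, `length(y) == nrow(X) >= 2`.
#' @param alpha positive scalar penalty.
#' @return Object of class `lasso_fit`: `alpha`, named `coefficients`,
#'   `intercept`, `feature_names`, `n_nonzero`.
#' @export
fit_lasso <- function(X, y, alpha) {
  X <- as.matrix(X)
  check_xy(X, y)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("'alpha' must be a positive finite scalar")
  path <- fit_lasso_path(X, y, alpha)
  new_lasso_fit(alpha, path$beta[, 1], path$intercept[1], colnames2(X))
}

new_lasso_fit <- function(alpha, w, b, feature_names) {
  structure(list(alpha = alpha,
                 coefficients = stats::setNames(as.numeric(w), feature_names),
                 intercept = as.numeric(b),
                 feature_names = feature_names,
                 n_nonzero = sum(w != 0)),
            class = "lasso_fit")
}

check_xy <- function(X, y) {
  if (anyNA(X) || any(!is.finite(X))) stop("'X' must be finite with no NA")
  if (anyNA(y) || any(!is.finite(y))) stop("'y' must be finite with no NA")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2L) stop("need at least 2 observations")
}

colnames2 <- function(X) {
  if (is.null(colnames(X))) sprintf("x%d", seq_len(ncol(X))) else colnames(X)
}

# coordinate-descent path at a decreasing alpha vector (or one alpha, in
# which case a short geometric warm-up path from alpha_max is prepended).
# Returns beta (p x length(alphas), original order) and intercepts.
fit_lasso_path <- function(X, y, alphas, tol = 1e-9, maxit = 300000L) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  G <- crossprod(Xc) / n
  b <- drop(crossprod(Xc, yc)) / n
  amax <- max(abs(b), 1e-300)
  if (length(alphas) == 1L && alphas < amax) {
    warm <- exp(seq(log(amax), log(alphas), length.out = 20L))
    beta <- cd_lasso_path(G, b, warm, tol, maxit)
    beta <- beta[, ncol(beta), drop = FALSE]
  } else {
    ord <- order(alphas, decreasing = TRUE)
    beta <- cd_lasso_path(G, b, alphas[ord], tol, maxit)
    beta <- beta[, order(ord), drop = FALSE]  # back to input order
  }
  intercept <- ybar - drop(crossprod(beta, xbar))
  list(beta = beta, intercept = intercept)
}

#' Smallest penalty giving the all-zero Lasso model
#'
#' \eqn{\alpha_{max} = \max_j |x_j^\top(y - \bar y)| / n} computed on
#' centered data; for any `alpha >= alpha_max` every coefficient is exactly
#' zero (KKT condition).
#'
#' @inheritParams fit_lasso
#' @return positive scalar.
#' @export
alpha_max <- function(X, y) {
  X <- as.matrix(X)
  check_xy(X, y)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  max(abs(drop(crossprod(Xc, y - mean(y)))) / n)
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("Lasso fit: alpha = %.4g, %d of %d nonzero coefficients\n",
              x$alpha, x$n_nonzero, length(x$coefficients)))
  invisible(x)
}

#' @export
coef.lasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' The penalty grid for tuning
#'
#' Log-uniformly spaced, inclusive of both endpoints and strictly
#' increasing.  The default — 201 values from 1e-5 to 1e5 — is the grid
#' used throughout this package's tuning.
#'
#' @param low,high positive endpoints, `low < high`.
#' @param n integer, at least 2.
#' @return numeric vector of length `n`.
#' @export
make_alpha_grid <- function(low = 1e-5, high = 1e5, n = 201L) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high)
    stop("need 0 < low < high")
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  g <- exp(seq(log(low), log(high), length.out = n))
  g[1] <- low
  g[n] <- high
  g
}

#' Leave-one-out cross-validation of a Lasso at fixed penalty
#'
#' Each patient in turn is held out, the model is fitted on the remaining
#' `n - 1`, the held-out transformed PFI is predicted and inverted to days
#' with `pfi_transform`, and the pooled error is summarized as
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum_i (\mathrm{Observed\ PFI}_i -
#'   \mathrm{Pred\ PFI}_i)^2}}
#' on the day scale.  Entirely deterministic.
#'
#' With `nested_transforms = TRUE` (strict mode) the per-column and PFI
#' Yeo-Johnson transforms are refitted inside each training fold from the
#' panel stored in `table`, and the held-out patient is transformed with
#' the training fold's transforms; the default (`FALSE`) keeps the
#' cohort-level transforms, which do not use the held-out label.
#'
#' @param X,y design matrix and transformed outcome (ignored when a
#'   `cohort_table` is passed as `X`).
#' @param alpha positive scalar penalty.
#' @param pfi_transform the outcome's `yj_transform` (taken from the table
#'   when `X` is a `cohort_table`).
#' @param nested_transforms logical; refit transforms within folds.
#' @return Object of class `pfi_cv`: `fold_ids`, `predictions_days`,
#'   `observed_days`, `rmse_days`, `fold_coefficients` (folds x features),
#'   `fold_intercepts`, `alpha`, `n`.
#' @export
loocv <- function(X, y = NULL, alpha, pfi_transform = NULL,
                  nested_transforms = FALSE) {
  if (inherits(X, "cohort_table")) {
    table <- X
    X <- table$X
    y <- table$y
    if (is.null(pfi_transform)) pfi_transform <- table$pfi_transform
  } else {
    table <- NULL
    if (isTRUE(nested_transforms))
      stop("nested_transforms requires a cohort_table input")
  }
  X <- as.matrix(X)
  check_xy(X, y)
  if (is.null(pfi_transform) || !inherits(pfi_transform, "yj_transform"))
    stop("'pfi_transform' must be a fitted yj_transform")
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 observations")
  p <- ncol(X)
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))

  fold_coef <- matrix(0, n, p, dimnames = list(ids, colnames2(X)))
  fold_int <- numeric(n)
  observed_days <- invert_transform(y, pfi_transform)
  cap <- 10 * max(observed_days)
  preds_days <- numeric(n)
  for (i in seq_len(n)) {
    if (isTRUE(nested_transforms)) {
      fold <- fold_tables(table, i)
      fit <- fit_lasso(fold$Xtr, fold$ytr, alpha)
      pred_t <- fit$intercept + sum(fold$xte * fit$coefficients)
      preds_days[i] <- invert_days_safe(pred_t, fold$pfi_transform, cap)
    } else {
      fit <- fit_lasso(X[-i, , drop = FALSE], y[-i], alpha)
      pred_t <- fit$intercept + sum(X[i, ] * fit$coefficients)
      preds_days[i] <- invert_days_safe(pred_t, pfi_transform, cap)
    }
    fold_coef[i, ] <- fit$coefficients
    fold_int[i] <- fit$intercept
  }
  new_pfi_cv(ids, preds_days, observed_days, fold_coef, fold_int, alpha)
}

new_pfi_cv <- function(ids, preds_days, observed_days, fold_coef, fold_int,
                       alpha) {
  structure(list(fold_ids = ids,
                 predictions_days = preds_days,
                 observed_days = observed_days,
                 rmse_days = rmse(observed_days, preds_days),
                 fold_coefficients = fold_coef,
                 fold_intercepts = fold_int,
                 alpha = alpha, n = length(ids)),
            class = "pfi_cv")
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' @export
print.pfi_cv <- function(x, ...) {
  cat(sprintf("LOOCV (%d folds) at alpha = %.4g: RMSE = %.2f days\n",
              x$n, x$alpha, x$rmse_days))
  invisible(x)
}

# refit the preprocessing inside a training fold (strict nested mode)
fold_tables <- function(table, i) {
  panel <- table$panel
  tr_panel <- panel_select_patients(panel, setdiff(seq_along(panel$patient_ids), i))
  m_tr <- impute_censored(tr_panel)
  L_tr <- log10(m_tr)
  m_all <- impute_censored(panel)
  L_te <- log10(m_all)[i, ]
  trans <- lapply(seq_len(ncol(L_tr)), function(j) fit_yeo_johnson(L_tr[, j]))
  Xtr <- vapply(seq_len(ncol(L_tr)),
                function(j) apply_transform(L_tr[, j], trans[[j]]),
                numeric(nrow(L_tr)))
  colnames(Xtr) <- panel$analyte_names
  xte <- vapply(seq_len(ncol(L_tr)),
                function(j) apply_transform(L_te[j], trans[[j]]), numeric(1))
  pfi_t <- fit_yeo_johnson(tr_panel$pfi_days)
  list(Xtr = Xtr, ytr = apply_transform(tr_panel$pfi_days, pfi_t),
       xte = xte, pfi_transform = pfi_t)
}

#' Tune the Lasso penalty by LOOCV over a grid
#'
#' Computes the LOOCV RMSE in days at every grid penalty (one warm-started
#' coordinate-descent path per fold) and the full-data nonzero-coefficient
#' count at each penalty.  The optimal penalty attains the lowest RMSE;
#' exact ties are broken toward the largest (sparsest) penalty.
#'
#' @inheritParams loocv
#' @param grid strictly increasing positive vector, e.g.
#'   [make_alpha_grid()].
#' @return Object of class `alpha_tuning`: `alphas`, `loocv_rmse_days`,
#'   `n_nonzero`, `optimal_alpha`, `optimal_rmse_days`, `n`.
#' @export
tune_alpha <- function(X, y = NULL, grid = make_alpha_grid(),
                       pfi_transform = NULL) {
  if (inherits(X, "cohort_table")) {
    if (is.null(pfi_transform)) pfi_transform <- X$pfi_transform
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  check_xy(X, y)
  if (is.null(pfi_transform) || !inherits(pfi_transform, "yj_transform"))
    stop("'pfi_transform' must be a fitted yj_transform")
  if (any(!is.finite(grid)) || any(grid <= 0) || any(diff(grid) <= 0) ||
      length(grid) < 2L)
    stop("'grid' must be a strictly increasing positive vector")
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 observations")
  na <- length(grid)
  preds_t <- matrix(0, n, na)
  for (i in seq_len(n)) {
    path <- fit_lasso_path(X[-i, , drop = FALSE], y[-i], grid)
    preds_t[i, ] <- path$intercept + drop(X[i, ] %*% path$beta)
  }
  observed_days <- invert_transform(y, pfi_transform)
  preds_days <- invert_days_safe(preds_t, pfi_transform, 10 * max(observed_days))
  rmse_days <- sqrt(colMeans((observed_days - preds_days)^2))
  full <- fit_lasso_path(X, y, grid)
  n_nonzero <- colSums(full$beta != 0)
  mins <- which(rmse_days == min(rmse_days))
  structure(list(alphas = grid, loocv_rmse_days = rmse_days,
                 n_nonzero = unname(n_nonzero),
                 optimal_alpha = grid[max(mins)],
                 optimal_rmse_days = min(rmse_days), n = n),
            class = "alpha_tuning")
}

#' @export
print.alpha_tuning <- function(x, ...) {
  cat(sprintf("Penalty tuning over %d alphas in [%.3g, %.3g]\n",
              length(x$alphas), min(x$alphas), max(x$alphas)))
  cat(sprintf("  optimal alpha = %.4g (LOOCV RMSE = %.2f days)\n",
              x$optimal_alpha, x$optimal_rmse_days))
  invisible(x)
}

#' Nested leave-one-out cross-validation RMSE
#'
#' The honest generalization-error estimate for a tuned model: the outer
#' loop holds out one patient; the inner loop runs [tune_alpha()] on the
#' remaining `n - 1` to choose a penalty; a model at that penalty, trained
#' on the same `n - 1`, predicts the outer case; the `n` outer errors are
#' pooled into one RMSE in days.
#'
#' @inheritParams tune_alpha
#' @return list with `rmse_days`, `chosen_alphas` (one inner-loop choice
#'   per outer fold), `predictions_days`, `observed_days`, `n`.
#' @export
nested_loocv_rmse <- function(X, y = NULL, grid = make_alpha_grid(),
                              pfi_transform = NULL) {
  if (inherits(X, "cohort_table")) {
    if (is.null(pfi_transform)) pfi_transform <- X$pfi_transform
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  check_xy(X, y)
  n <- nrow(X)
  if (n < 4L) stop("nested LOOCV needs at least 4 observations")
  chosen <- numeric(n)
  preds_days <- numeric(n)
  for (i in seq_len(n)) {
    inner <- tune_alpha(X[-i, , drop = FALSE], y[-i], grid, pfi_transform)
    chosen[i] <- inner$optimal_alpha
    fit <- fit_lasso(X[-i, , drop = FALSE], y[-i], chosen[i])
    pred_t <- fit$intercept + sum(X[i, ] * fit$coefficients)
    preds_days[i] <- pred_t
  }
  observed_days <- invert_transform(y, pfi_transform)
  preds_days <- invert_days_safe(preds_days, pfi_transform, 10 * max(observed_days))
  list(rmse_days = rmse(observed_days, preds_days), chosen_alphas = chosen,
       predictions_days = preds_days, observed_days = observed_days, n = n)
}

#' Relax the penalty within an error budget
#'
#' Formalizes "increase the penalty until the cross-validated error reaches
#' a tolerable level" as: the largest grid penalty whose LOOCV RMSE stays
#' within `error_budget_days`.  A 20-day budget is the default — on the
#' scale of clinical forecasting horizons, and chosen in the motivating
#' study because only one patient per cohort had a PFI under 20 days.  If
#' no grid point satisfies the budget the optimal penalty is returned with
#' `feasible = FALSE`.
#'
#' @param curve an `alpha_tuning` from [tune_alpha()].
#' @param error_budget_days positive; tolerated LOOCV RMSE in days.
#' @return Object of class `relaxed_alpha`: `alpha`, `rmse_days` (at that
#'   penalty), `budget_days`, `feasible`.
#' @export
relax_alpha <- function(curve, error_budget_days = 20) {
  stopifnot(inherits(curve, "alpha_tuning"))
  if (!is.numeric(error_budget_days) || length(error_budget_days) != 1L ||
      is.na(error_budget_days) || error_budget_days <= 0)
    stop("'error_budget_days' must be a positive scalar")
  ok <- which(curve$loocv_rmse_days <= error_budget_days)
  if (length(ok)) {
    k <- max(ok)
    structure(list(alpha = curve$alphas[k],
                   rmse_days = curve$loocv_rmse_days[k],
                   budget_days = error_budget_days, feasible = TRUE),
              class = "relaxed_alpha")
  } else {
    structure(list(alpha = curve$optimal_alpha,
                   rmse_days = curve$optimal_rmse_days,
                   budget_days = error_budget_days, feasible = FALSE),
              class = "relaxed_alpha")
  }
}

#' @export
print.relaxed_alpha <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("Relaxed alpha = %.4g (LOOCV RMSE %.2f <= budget %.1f days)\n",
                x$alpha, x$rmse_days, x$budget_days))
  else
    cat(sprintf("Budget of %.1f days infeasible; falling back to optimal alpha %.4g (RMSE %.2f days)\n",
                x$budget_days, x$alpha, x$rmse_days))
  invisible(x)
}

#' Predict one cohort's PFI with another cohort's model
#'
#' Preprocesses the target panel with the SOURCE cohort's fitted transforms
#' (imputation, log10, the source's per-analyte Yeo-Johnson), predicts on
#' the transformed scale, inverts to days with the source PFI transform,
#' and reports the RMSE against the target cohort's observed PFI.  Model
#' features absent from the target panel contribute 0 in standardized
#' space, i.e. are held at the source-cohort mean (the least-information
#' default); they are listed in the result.
#'
#' @param fit a `lasso_fit` trained on the source cohort.
#' @param source_table the source [build_cohort_table()] (provides the
#'   fitted transforms).
#' @param target_panel an [assay_panel()] for the other cohort (already
#'   detection-filtered within its own cohort).
#' @return list with `rmse_days`, `predictions_days`, `observed_days`,
#'   `missing_features`, `n`.
#' @export
cross_predict <- function(fit, source_table, target_panel) {
  stopifnot(inherits(fit, "lasso_fit"), inherits(source_table, "cohort_table"),
            inherits(target_panel, "assay_panel"))
  overlap <- intersect(fit$feature_names, target_panel$analyte_names)
  if (!length(overlap))
    stop("no analytes shared between the model and the target panel")
  m <- impute_censored(target_panel)
  L <- log10(m)
  n <- nrow(L)
  Xt <- matrix(0, n, length(fit$feature_names),
               dimnames = list(target_panel$patient_ids, fit$feature_names))
  for (f in overlap)
    Xt[, f] <- apply_transform(L[, f], source_table$column_transforms[[f]])
  preds_t <- fit$intercept + drop(Xt %*% fit$coefficients)
  preds_days <- invert_days_safe(preds_t, source_table$pfi_transform,
                                 10 * max(source_table$pfi_days))
  list(rmse_days = rmse(target_panel$pfi_days, preds_days),
       predictions_days = preds_days,
       observed_days = target_panel$pfi_days,
       missing_features = setdiff(fit$feature_names, overlap),
       n = n)
}
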