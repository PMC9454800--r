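#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox power transform to the whole
#' real line.  For a power parameter \eqn{\lambda}:
#' \deqn{\psi(y,\lambda) = ((y+1)^\lambda - 1)/\lambda  \quad (y \ge 0, \lambda \ne 0)}
#' \deqn{\psi(y,\lambda) = \log(y+1)                    \quad (y \ge 0, \lambda = 0)}
#' \deqn{\psi(y,\lambda) = -((1-y)^{2-\lambda} - 1)/(2-\lambda) \quad (y < 0, \lambda \ne 2)}
#' \deqn{\psi(y,\lambda) = -\log(1-y)                   \quad (y < 0, \lambda = 2)}
#' \eqn{\psi} is strictly increasing in `y` for every \eqn{\lambda}, so it
#' preserves patient rank order.
#'
#' `fit_yeo_johnson()` estimates \eqn{\lambda} by maximizing the Gaussian
#' profile log-likelihood of \eqn{\psi(v,\lambda)}, including the Jacobian
#' term \eqn{(\lambda-1)\sum_i \mathrm{sign}(v_i)\log(|v_i|+1)}, with a
#' bounded scalar search over \eqn{\lambda \in [-5, 5]} (tolerance 1e-8).
#' The returned transform also records the post-transform mean and SD so
#' that [apply_transform()] yields a zero-mean, unit-SD vector: penalized
#' regression is scale-sensitive and standardization makes the L1 penalty
#' act uniformly across analytes.
#'
#' @param v numeric vector, finite, length at least 3, non-constant.
#' @return An object of class `yj_transform`: a list with elements `kind`
#'   (`"yeo_johnson"`), `lambda`, `post_mean`, `post_sd`.
#' @seealso [apply_transform()], [invert_transform()]
#' @examples
#' t <- fit_yeo_johnson(exp(rnorm(50)))
#' z <- apply_transform(exp(rnorm(50)), t)
#' @export
fit_yeo_johnson <- function(v) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("'v' must be a finite numeric vector")
  if (length(v) < 3L)
    stop("'v' must have length >= 3 to fit a transform")
  if (diff(range(v)) == 0)
    stop("'v' is constant: the Yeo-Johnson lambda is unidentifiable")
  n <- length(v)
  jac <- sum(sign(v) * log1p(abs(v)))
  negll <- function(lambda) {
    psi <- yj_psi(v, lambda)
    s2 <- mean((psi - mean(psi))^2)
    -(-0.5 * n * log(s2) + (lambda - 1) * jac)
  }
  opt <- optimize(negll, interval = c(-5, 5), tol = 1e-8)
  lambda <- opt$minimum
  psi <- yj_psi(v, lambda)
  new_yj_transform(lambda, mean(psi), sd(psi))
}

new_yj_transform <- function(lambda, post_mean, post_sd) {
  if (!is.finite(post_sd) || post_sd <= 0)
    stop("post_sd must be a positive finite number")
  structure(list(kind = "yeo_johnson", lambda = lambda,
                 post_mean = post_mean, post_sd = post_sd),
            class = "yj_transform")
}

#' @export
print.yj_transform <- function(x, ...) {
  cat(sprintf("Yeo-Johnson transform: lambda = %.4f, post mean = %.4f, post SD = %.4f\n",
              x$lambda, x$post_mean, x$post_sd))
  invisible(x)
}

# raw Yeo-Johnson psi; expm1/log1p keep the lambda -> 0 and lambda -> 2
# branches numerically continuous
yj_psi <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (any(pos)) {
    if (abs(lambda) > 1e-10) {
      out[pos] <- expm1(lambda * log1p(y[pos])) / lambda
    } else {
      out[pos] <- log1p(y[pos])
    }
  }
  if (any(!pos)) {
    lam2 <- 2 - lambda
    if (abs(lam2) > 1e-10) {
      out[!pos] <- -expm1(lam2 * log1p(-y[!pos])) / lam2
    } else {
      out[!pos] <- -log1p(-y[!pos])
    }
  }
  dim(out) <- dim(y)
  out
}

yj_psi_inverse <- function(u, lambda) {
  out <- numeric(length(u))
  pos <- u >= 0  # psi(0) = 0 and psi is increasing, so sign(psi) = sign(y)
  if (any(pos)) {
    if (abs(lambda) > 1e-10) {
      arg <- lambda * u[pos] + 1
      if (any(arg <= 0))
        stop("value outside the range of the Yeo-Johnson transform for lambda = ",
             format(lambda))
      out[pos] <- expm1(log(arg) / lambda)
    } else {
      out[pos] <- expm1(u[pos])
    }
  }
  if (any(!pos)) {
    lam2 <- 2 - lambda
    if (abs(lam2) > 1e-10) {
      arg <- 1 - lam2 * u[!pos]
      if (any(arg <= 0))
        stop("value outside the range of the Yeo-Johnson transform for lambda = ",
             format(lambda))
      out[!pos] <- -expm1(log(arg) / lam2)
    } else {
      out[!pos] <- -expm1(-u[!pos])
    }
  }
  dim(out) <- dim(u)
  out
}

#' Apply or invert a fitted Yeo-Johnson transform
#'
#' `apply_transform()` maps data to the standardized transformed scale,
#' `(psi(v, lambda) - post_mean) / post_sd`; `invert_transform()` maps back,
#' so `invert_transform(apply_transform(v, t), t)` recovers `v` to within
#' 1e-8 relative error.  Inversion raises an error when a value maps outside
#' the range of \eqn{\psi} for the fitted \eqn{\lambda} (possible for
#' \eqn{\lambda < 0} or \eqn{\lambda > 2}).
#'
#' @param v,z numeric vector or matrix (for `invert_transform`, values on
#'   the standardized transformed scale).
#' @param t a `yj_transform` from [fit_yeo_johnson()].
#' @return numeric vector/matrix of the same shape.
#' @export
apply_transform <- function(v, t) {
  stopifnot(inherits(t, "yj_transform"))
  (yj_psi(v, t$lambda) - t$post_mean) / t$post_sd
}

#' @rdname apply_transform
#' @export
invert_transform <- function(z, t) {
  stopifnot(inherits(t, "yj_transform"))
  if (anyNA(z) || any(!is.finite(z))) stop("'z' must be finite")
  yj_psi_inverse(z * t$post_sd + t$post_mean, t$lambda)
}

# Saturating inversion for model PREDICTIONS (not a round-trip): the
# transformed prediction is clamped into psi's attainable range (psi is
# bounded below by -1/(lambda-2) for lambda > 2 and above by -1/lambda for
# lambda < 0), and the resulting days are capped at [0, cap_days].  Without
# this, penalty-grid tuning would abort whenever an overfit fold
# extrapolates beyond the fitted transform's range; a saturated prediction
# contributes a large-but-data-scaled error instead.
invert_days_safe <- function(z, t, cap_days) {
  u <- z * t$post_sd + t$post_mean
  lambda <- t$lambda
  if (lambda > 2) {
    lo <- -1 / (lambda - 2)
    u <- pmax(u, lo * (1 - 1e-9))
  }
  if (lambda < 0) {
    hi <- -1 / lambda
    u <- pmin(u, hi * (1 - 1e-9))
  }
  y <- yj_psi_inverse(u, lambda)
  pmin(pmax(y, 0), cap_days)
}
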