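# Independent oracles and small fixtures used across the suite.

# KKT optimality certificate for the Lasso objective
# (1/(2n)) * RSS + alpha * ||w||_1 with unpenalized intercept.
# Independent of the solver: works from the raw (X, y, fit) triple.
kkt_violation <- function(X, y, fit) {
  n <- nrow(X)
  r <- y - fit$intercept - drop(X %*% fit$coefficients)
  g <- drop(crossprod(X, r)) / n     # (1/n) X^T r, the negative gradient
  w <- fit$coefficients
  viol_zero <- max(0, abs(g[w == 0]) - fit$alpha)
  viol_nonzero <- if (any(w != 0))
    max(abs(g[w != 0] - fit$alpha * sign(w[w != 0]))) else 0
  viol_intercept <- abs(mean(r))     # intercept stationarity
  max(viol_zero, viol_nonzero, viol_intercept)
}

# closed-form Lasso solution for a single centered feature:
# w = S(x'y/n, alpha) / (x'x/n)
soft_threshold <- function(z, a) sign(z) * max(0, abs(z) - a)
single_feature_lasso <- function(x, y, alpha) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  soft_threshold(sum(xc * yc) / n, alpha) / (sum(xc * xc) / n)
}

# random regression problem with correlated columns
random_problem <- function(n, p, rho = 0.5) {
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z + rho * matrix(rnorm(n), n, p)   # shared factor induces correlation
  X <- scale(X)[, , drop = FALSE]
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  beta <- numeric(p)
  k <- max(1L, p %/% 4L)
  beta[sample.int(p, k)] <- rnorm(k)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y)
}

# hand-made 10-patient, 4-analyte panel with placed censoring:
#   A_low  : 3 of 10 below  -> detected 7/10 = 0.70 < 0.75, removed
#   B_keep : 2 of 10 below  -> detected 0.80, retained
#   C_high : 1 of 10 above  -> detected 1.00, retained
#   D_full : no censoring   -> retained
make_test_panel <- function() {
  n <- 10
  conc <- cbind(A_low = c(NA, NA, NA, 50, 60, 70, 80, 90, 100, 110),
                B_keep = c(NA, NA, 30, 40, 50, 60, 70, 80, 90, 100),
                C_high = c(NA, 200, 300, 400, 500, 600, 700, 800, 900, 950),
                D_full = seq(110, 200, by = 10))
  flags <- matrix("none", n, 4, dimnames = list(NULL, colnames(conc)))
  flags[1:3, "A_low"] <- "below"
  flags[1:2, "B_keep"] <- "below"
  flags[1, "C_high"] <- "above"
  assay_panel(patient_ids = sprintf("P%02d", 1:n),
              cohort_labels = "NACT",
              pfi_days = c(30, 60, 90, 120, 150, 180, 220, 260, 320, 400),
              concentrations = conc, censor_flags = flags,
              analyte_names = colnames(conc),
              lower_limit = c(4, 6, 10, 1),
              upper_limit = c(1000, 1000, 500, 1000),
              dilution_factor = c(2, 1, 2, 1))
}

# small strong-signal cohort used by several tests
make_signal_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(n_analytes = 57, n_undetectable = 0,
                                seed = seed, ...))
}

panel_drop_analyte <- function(panel, analyte) {
  keep <- setdiff(seq_along(panel$analyte_names),
                  match(analyte, panel$analyte_names))
  pfilasso:::panel_select_analytes(panel, keep)
}

# raw psi at a forced lambda, via a transform with identity standardization
yj_psi_at <- function(y, lambda) {
  t <- structure(list(kind = "yeo_johnson", lambda = lambda,
                      post_mean = 0, post_sd = 1), class = "yj_transform")
  apply_transform(y, t)
}
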