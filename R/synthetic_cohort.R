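#' Synthetic-cohort generator configuration
#'
#' Parameterizes [generate_cohort()].  The defaults emulate the study
#' conditions the package targets: a 25-patient neoadjuvant (NACT) cohort
#' assayed on a 116-analyte multiplex panel of which roughly half are
#' effectively undetectable (their detection limit sits near the top of the
#' concentration distribution, so they fail the 75% detection filter and
#' about 57 analytes survive), heavy-tailed log-normal concentrations whose
#' raw coefficient of variation is typically above 100%, mild assay
#' censoring (10% below the detection limit, 2% above the top standard),
#' and a sparse linear signal — a handful of informative analytes driving
#' the platinum-free interval on the transformed scale.
#'
#' @param n_patients positive integer, cohort size.
#' @param n_analytes positive integer, analytes assayed (before filtering).
#' @param n_informative non-negative integer, analytes carrying signal;
#'   drawn from the detectable set.
#' @param n_undetectable non-negative integer, analytes whose detection
#'   limit is placed at `undetectable_quantile` of their concentration
#'   distribution so they fail a 75% detection filter.
#' @param beta_magnitude positive, absolute effect per informative analyte
#'   on the standardized transformed scale (signs are randomized).
#' @param noise_sd positive, residual SD of the transformed PFI.
#' @param log_mean_range,log_sd_range length-2 numeric; per-analyte mean and
#'   SD of natural-log concentration (pg/mL) are drawn uniformly from these.
#' @param left_censor_quantile in `[0, 1)`, lower detection limit placed at
#'   this quantile of each detectable analyte's distribution.
#' @param right_censor_quantile in `(0, 1]`, top standard placed here.
#' @param undetectable_quantile quantile where undetectable analytes' LODs
#'   are placed (must exceed 0.25 for them to fail a 75% filter).
#' @param dilution_factor positive, assay dilution (shared by all analytes).
#' @param pfi_days_center,pfi_days_scale positive; the transformed-scale
#'   signal is mapped to days by an affine shift,
#'   `center + scale * signal / sd(signal)`, so the PFI has mean `center`
#'   and SD `scale` days regardless of effect and noise settings.
#' @param cohort_label `"NACT"` or `"PDS"`.
#' @param seed integer seeding the cohort's private RNG stream.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 25, n_analytes = 116,
                          n_informative = 5, n_undetectable = 59,
                          beta_magnitude = 0.8, noise_sd = 0.2,
                          log_mean_range = c(1, 6),
                          log_sd_range = c(0.8, 1.5),
                          left_censor_quantile = 0.10,
                          right_censor_quantile = 0.98,
                          undetectable_quantile = 0.95,
                          dilution_factor = 2,
                          pfi_days_center = 166, pfi_days_scale = 40,
                          cohort_label = "NACT", seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_analytes = as.integer(n_analytes),
              n_informative = as.integer(n_informative),
              n_undetectable = as.integer(n_undetectable),
              beta_magnitude = beta_magnitude, noise_sd = noise_sd,
              log_mean_range = log_mean_range, log_sd_range = log_sd_range,
              left_censor_quantile = left_censor_quantile,
              right_censor_quantile = right_censor_quantile,
              undetectable_quantile = undetectable_quantile,
              dilution_factor = dilution_factor,
              pfi_days_center = pfi_days_center,
              pfi_days_scale = pfi_days_scale,
              cohort_label = cohort_label, seed = as.integer(seed))
  if (cfg$n_analytes < 1L) stop("n_analytes must be positive")
  if (cfg$n_patients < 1L) stop("n_patients must be positive")
  if (cfg$n_informative < 0L ||
      cfg$n_informative > cfg$n_analytes - cfg$n_undetectable)
    stop("n_informative must lie in [0, n_analytes - n_undetectable]")
  if (cfg$n_undetectable < 0L || cfg$n_undetectable > cfg$n_analytes)
    stop("n_undetectable must lie in [0, n_analytes]")
  if (beta_magnitude <= 0 || noise_sd <= 0)
    stop("beta_magnitude and noise_sd must be positive")
  if (left_censor_quantile < 0 || left_censor_quantile >= 1 ||
      right_censor_quantile <= 0 || right_censor_quantile > 1 ||
      left_censor_quantile >= right_censor_quantile)
    stop("need 0 <= left_censor_quantile < right_censor_quantile <= 1")
  if (any(log_sd_range <= 0)) stop("log_sd_range must be positive")
  if (dilution_factor <= 0) stop("dilution_factor must be positive")
  if (pfi_days_center <= 0 || pfi_days_scale <= 0)
    stop("pfi_days_center and pfi_days_scale must be positive")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic assay cohort with known ground truth
#'
#' Draws per-analyte log-normal concentrations, places detection limits at
#' the configured quantiles of each analyte's true distribution, flags and
#' blanks out-of-range cells, and constructs the platinum-free interval as
#' an affine map to days of a sparse linear combination of the informative
#' analytes' standardized log-concentrations plus Gaussian noise:
#' `pfi = center + scale * (Z %*% beta + eps) / sd(Z %*% beta + eps)`.
#'
#' The generator uses a private RNG stream seeded from `config$seed`; the
#' caller's RNG state is untouched and identical configs give bit-identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list with components `panel` (an [assay_panel()]; censored
#'   cells are `NA`) and `truth` (class `cohort_truth`: `true_beta`,
#'   `informative_set`, `undetectable_set`, `noise_sd`, the pre-censoring
#'   `concentrations`, per-analyte `log_mean`/`log_sd`, the realized
#'   per-analyte censoring fractions, and the PFI mapping parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_private_rng(config$seed, {
    n <- config$n_patients
    p <- config$n_analytes
    mu <- runif(p, config$log_mean_range[1], config$log_mean_range[2])
    sig <- runif(p, config$log_sd_range[1], config$log_sd_range[2])
    undet <- sort(sample.int(p, config$n_undetectable))
    detectable <- setdiff(seq_len(p), undet)
    informative <- sort(sample(detectable, config$n_informative))
    beta <- numeric(p)
    if (config$n_informative > 0)
      beta[informative] <- config$beta_magnitude *
        sample(c(-1, 1), config$n_informative, replace = TRUE)

    Z <- matrix(rnorm(n * p), n, p)
    conc <- exp(sweep(sweep(Z, 2, sig, `*`), 2, mu, `+`))

    loq <- ifelse(seq_len(p) %in% undet,
                  config$undetectable_quantile, config$left_censor_quantile)
    lower_sample <- qlnorm(loq, mu, sig)
    lower_sample[loq == 0] <- 0  # no left censoring
    upper_sample <- qlnorm(config$right_censor_quantile, mu, sig)
    if (config$right_censor_quantile == 1) upper_sample <- rep(Inf, p)
    eps <- rnorm(n, 0, config$noise_sd)
    signal <- drop(Z %*% beta) + eps
    # affine map to days, normalized so the PFI has SD pfi_days_scale and
    # mean pfi_days_center whatever the effect/noise configuration
    sd_signal <- sqrt(sum(beta^2) + config$noise_sd^2)
    pfi <- config$pfi_days_center + config$pfi_days_scale * signal / sd_signal
    if (any(pfi <= 0))
      stop("generated PFI not positive for all patients: ",
           "config infeasible (reduce pfi_days_scale or noise)")

    # finite limits are required by the panel; cap the unbounded cases just
    # outside the observed range so no cell is flagged
    lo <- ifelse(is.finite(lower_sample) & lower_sample > 0, lower_sample,
                 pmin(apply(conc, 2, min) * 0.5, 1e-12))
    hi <- ifelse(is.finite(upper_sample), upper_sample,
                 apply(conc, 2, max) * 2)
    flags <- apply_censoring(conc, lo, hi)
    shown <- conc
    shown[flags != "none"] <- NA_real_

    ids <- sprintf("%s-P%03d", config$cohort_label, seq_len(n))
    analytes <- sprintf("A%03d", seq_len(p))
    panel <- assay_panel(
      patient_ids = ids, cohort_labels = config$cohort_label, pfi_days = pfi,
      concentrations = shown, censor_flags = flags, analyte_names = analytes,
      lower_limit = lo / config$dilution_factor,
      upper_limit = hi / config$dilution_factor,
      dilution_factor = config$dilution_factor)
    truth <- structure(list(
      true_beta = stats::setNames(beta, analytes),
      informative_set = analytes[informative],
      undetectable_set = analytes[undet],
      noise_sd = config$noise_sd,
      concentrations = `dimnames<-`(conc, list(ids, analytes)),
      log_mean = stats::setNames(mu, analytes),
      log_sd = stats::setNames(sig, analytes),
      realized_censoring = cbind(below = colMeans(flags == "below"),
                                 above = colMeans(flags == "above")),
      pfi_days_center = config$pfi_days_center,
      pfi_days_scale = config$pfi_days_scale,
      pfi_signal_sd = sd_signal,
      config = config), class = "cohort_truth")
    list(panel = panel, truth = truth)
  })
}

# evaluate expr under a private RNG stream; global .Random.seed is restored
with_private_rng <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth the `cohort_truth` component of [generate_cohort()]'s value.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ground_truth <- function(truth, file) {
  stopifnot(inherits(truth, "cohort_truth"))
  out <- list(true_beta = as.list(truth$true_beta),
              informative_set = truth$informative_set,
              undetectable_set = truth$undetectable_set,
              noise_sd = truth$noise_sd,
              realized_censoring = as.data.frame(truth$realized_censoring),
              pfi_days_center = truth$pfi_days_center,
              pfi_days_scale = truth$pfi_days_scale,
              config = unclass(truth$config))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
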