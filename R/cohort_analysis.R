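#' Descriptive comparison of the two treatment cohorts
#'
#' The descriptive layer run before any modeling:
#' \itemize{
#'   \item PFI distributions compared by a two-sided Mann-Whitney U test
#'     (normal approximation with tie correction, no continuity
#'     correction);
#'   \item per-analyte two-sample t-tests (equal variance, two-tailed,
#'     un-corrected for multiplicity — deliberate, and the number of tests
#'     is reported alongside) on log10 imputed concentrations, for analytes
#'     present in both panels;
#'   \item per-analyte raw-scale percent coefficient of variation
#'     (SD/mean x 100 of imputed concentrations) within each cohort.
#' }
#'
#' @param panel_nact,panel_pds [assay_panel()]s, each already
#'   detection-filtered within its own cohort.
#' @return Object of class `cohort_summary`: `cohorts` (data frame: label,
#'   n, PFI mean/median in days), `pfi_test` (list: `U`, `p`), `analytes`
#'   (data frame: analyte, per-cohort raw %CV, t statistic and p-value),
#'   `n_tests`, `excluded_analytes` (present in only one panel).
#' @export
summarize_cohorts <- function(panel_nact, panel_pds) {
  stopifnot(inherits(panel_nact, "assay_panel"),
            inherits(panel_pds, "assay_panel"))
  m1 <- impute_censored(panel_nact)
  m2 <- impute_censored(panel_pds)
  common <- intersect(panel_nact$analyte_names, panel_pds$analyte_names)
  excluded <- union(setdiff(panel_nact$analyte_names, common),
                    setdiff(panel_pds$analyte_names, common))
  if (!length(common)) stop("the two panels share no analytes")

  wt <- wilcox.test(panel_nact$pfi_days, panel_pds$pfi_days,
                    exact = FALSE, correct = FALSE)
  tests <- t(vapply(common, function(a) {
    tt <- t.test(log10(m1[, a]), log10(m2[, a]), var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }, numeric(2)))
  pct_cv_raw <- function(v) sd(v) / mean(v) * 100
  analytes <- data.frame(
    analyte = common,
    pct_cv_raw_nact = vapply(common, function(a) pct_cv_raw(m1[, a]), 0),
    pct_cv_raw_pds = vapply(common, function(a) pct_cv_raw(m2[, a]), 0),
    t_statistic = unname(tests[, 1]),
    t_p_value = unname(tests[, 2]),
    row.names = NULL, stringsAsFactors = FALSE)
  cohorts <- data.frame(
    cohort = c("NACT", "PDS"),
    n = c(length(panel_nact$patient_ids), length(panel_pds$patient_ids)),
    pfi_mean_days = c(mean(panel_nact$pfi_days), mean(panel_pds$pfi_days)),
    pfi_median_days = c(median(panel_nact$pfi_days), median(panel_pds$pfi_days)))
  structure(list(cohorts = cohorts,
                 pfi_test = list(U = unname(wt$statistic), p = wt$p.value),
                 analytes = analytes,
                 n_tests = length(common),
                 excluded_analytes = excluded),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  for (i in seq_len(nrow(x$cohorts)))
    cat(sprintf("  %s: n = %d, mean PFI = %.0f days, median = %.0f days\n",
                x$cohorts$cohort[i], x$cohorts$n[i],
                x$cohorts$pfi_mean_days[i], x$cohorts$pfi_median_days[i]))
  cat(sprintf("  PFI Mann-Whitney U = %.1f, p = %.4g\n",
              x$pfi_test$U, x$pfi_test$p))
  cat(sprintf("  %d per-analyte t-tests (un-corrected); %d analytes with raw %%CV > 100%% in either cohort\n",
              x$n_tests,
              sum(x$analytes$pct_cv_raw_nact > 100 |
                    x$analytes$pct_cv_raw_pds > 100)))
  invisible(x)
}

#' Patient-by-patient similarity matrix
#'
#' Pearson correlation between every pair of patients' normalized analyte
#' profiles: entry (i, j) correlates patient i's and patient j's rows of
#' the combined transformed matrix.  Use [pooled_normalized_matrix()] to
#' build the input across two cohorts.
#'
#' @param X_combined numeric matrix, patients x analytes, normalized.
#' @return symmetric numeric matrix with unit diagonal and entries in
#'   `[-1, 1]`, patient ids as dimnames; class `similarity_matrix`.
#' @export
patient_similarity <- function(X_combined) {
  X_combined <- as.matrix(X_combined)
  if (anyNA(X_combined) || any(!is.finite(X_combined)))
    stop("'X_combined' must be finite")
  if (ncol(X_combined) < 2L)
    stop("need at least 2 analytes to correlate patient profiles")
  v <- apply(X_combined, 1, sd)
  if (any(v == 0))
    stop("patient(s) with zero variance across analytes: ",
         paste(rownames(X_combined)[v == 0], collapse = ", "))
  S <- cor(t(X_combined))
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Pooled normalized matrix over the analyte intersection of two panels
#'
#' Imputes and log10-transforms both panels, then fits one standardizing
#' Yeo-Johnson transform per shared analyte on the pooled values and
#' applies it, yielding a single normalized matrix over all patients of
#' both cohorts — the input to [patient_similarity()].
#'
#' @param panel_a,panel_b [assay_panel()]s (detection-filtered).
#' @return numeric matrix, (patients of a + patients of b) x shared
#'   analytes.
#' @export
pooled_normalized_matrix <- function(panel_a, panel_b) {
  common <- intersect(panel_a$analyte_names, panel_b$analyte_names)
  if (!length(common)) stop("the two panels share no analytes")
  L <- rbind(log10(impute_censored(panel_a))[, common, drop = FALSE],
             log10(impute_censored(panel_b))[, common, drop = FALSE])
  rownames(L) <- c(panel_a$patient_ids, panel_b$patient_ids)
  X <- vapply(common, function(a) {
    t <- fit_yeo_johnson(L[, a])
    apply_transform(L[, a], t)
  }, numeric(nrow(L)))
  rownames(X) <- rownames(L)
  X
}

#' Write a similarity matrix as square CSV
#'
#' Patient ids appear as both the header row and the first column.
#'
#' @param S a [patient_similarity()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_similarity_matrix <- function(S, file) {
  utils::write.csv(as.data.frame(unclass(S)), file, row.names = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}
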