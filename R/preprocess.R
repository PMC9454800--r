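#' Remove analytes detected in too few patients
#'
#' Assay QC rule: an analyte is retained iff the fraction of patients in
#' which it is detected — flag not `"below"`, so above-range cells count as
#' detected (they are measurable signal) — is at least
#' `min_detected_fraction`.  Cells recorded as exactly 0 with flag `"none"`
#' are treated as below-limit first (a literal zero concentration is an
#' instrument artifact).
#'
#' @param panel an [assay_panel()].
#' @param min_detected_fraction in `(0, 1]`; default 0.75 (the usual
#'   "detected in at least 75% of patients" rule).
#' @return The panel restricted to retained analytes, with a `provenance`
#'   attribute (data frame of removed analytes and their detection
#'   fractions).  Raises an error, with the removal table attached as the
#'   condition's `removals` field, if nothing survives.
#' @export
filter_low_detection <- function(panel, min_detected_fraction = 0.75) {
  stopifnot(inherits(panel, "assay_panel"))
  if (!(min_detected_fraction > 0 && min_detected_fraction <= 1))
    stop("min_detected_fraction must be in (0, 1]")
  panel <- normalize_zero_cells(panel)
  detected <- colMeans(panel$censor_flags != "below")
  keep <- detected >= min_detected_fraction
  removals <- data.frame(analyte = panel$analyte_names[!keep],
                         detected_fraction = unname(detected[!keep]))
  if (!any(keep)) {
    cond <- simpleError("all analytes removed by the detection filter")
    cond$removals <- removals
    stop(cond)
  }
  out <- panel_select_analytes(panel, which(keep))
  attr(out, "provenance") <- list(
    filter = list(min_detected_fraction = min_detected_fraction,
                  n_assayed = length(panel$analyte_names),
                  n_retained = sum(keep), removed = removals))
  out
}

# cells that are exactly 0 with flag "none" become below-limit flags
normalize_zero_cells <- function(panel) {
  zero <- panel$censor_flags == "none" & !is.na(panel$concentrations) &
    panel$concentrations == 0
  if (any(zero)) {
    panel$censor_flags[zero] <- "below"
    panel$concentrations[zero] <- NA_real_
  }
  panel
}

#' Impute censored concentrations from the assay limits
#'
#' Standard limit-based rules for multiplexed immunoassays: a cell below
#' the detection limit becomes half the detection limit times the assay
#' dilution factor, `0.5 * lower_limit * dilution_factor`; a cell above the
#' top standard becomes twice the maximum times the dilution,
#' `2 * upper_limit * dilution_factor`; detected cells pass through
#' unchanged.  Idempotent: re-imputing a complete matrix with the same
#' flags changes nothing.
#'
#' @param panel an [assay_panel()].
#' @return numeric matrix (patients x analytes, pg/mL) with no missing
#'   entries.
#' @export
impute_censored <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  if (any(!is.finite(panel$lower_limit)) || any(panel$lower_limit <= 0) ||
      any(!is.finite(panel$upper_limit)) || any(panel$upper_limit <= 0))
    stop("assay limits must be finite and positive for imputation")
  panel <- normalize_zero_cells(panel)
  m <- panel$concentrations
  p <- ncol(m)
  below_val <- matrix(0.5 * panel$lower_limit * panel$dilution_factor,
                      nrow(m), p, byrow = TRUE)
  above_val <- matrix(2 * panel$upper_limit * panel$dilution_factor,
                      nrow(m), p, byrow = TRUE)
  m[panel$censor_flags == "below"] <- below_val[panel$censor_flags == "below"]
  m[panel$censor_flags == "above"] <- above_val[panel$censor_flags == "above"]
  m
}

#' Build the model-ready cohort table
#'
#' Runs the fixed preprocessing chain on a detection-filtered panel:
#' impute censored cells ([impute_censored()]), `log10` every
#' concentration, fit and apply a standardizing Yeo-Johnson transform per
#' analyte column, and fit and apply one to the PFI (days).  Every step is
#' strictly monotone, so patient rank order per analyte is preserved.  All
#' fitted transforms are retained so predictions can be mapped back to
#' days.  Transforms are fitted once on the full cohort (they do not use
#' the outcome except for the PFI's own transform); see [loocv()] for a
#' strict mode that refits them inside each training fold.
#'
#' @param panel an [assay_panel()], already detection-filtered.
#' @return An object of class `cohort_table`: list with `X` (patients x
#'   analytes, zero mean and unit SD per column), `y` (transformed PFI,
#'   zero mean, unit SD), `feature_names`, `column_transforms` (named list
#'   of `yj_transform`), `pfi_transform`, `pfi_days`, `patient_ids`,
#'   `cohort_labels`, `panel` (the input, for fold-wise refitting) and
#'   `provenance`.
#' @export
build_cohort_table <- function(panel) {
  stopifnot(inherits(panel, "assay_panel"))
  m <- impute_censored(panel)
  if (any(m <= 0)) stop("non-positive imputed concentration")
  L <- log10(m)
  transforms <- lapply(seq_len(ncol(L)), function(j) fit_yeo_johnson(L[, j]))
  names(transforms) <- panel$analyte_names
  X <- vapply(seq_len(ncol(L)),
              function(j) apply_transform(L[, j], transforms[[j]]),
              numeric(nrow(L)))
  dimnames(X) <- list(panel$patient_ids, panel$analyte_names)
  pfi_t <- fit_yeo_johnson(panel$pfi_days)
  y <- apply_transform(panel$pfi_days, pfi_t)
  structure(list(
    X = X, y = y, feature_names = panel$analyte_names,
    column_transforms = transforms, pfi_transform = pfi_t,
    pfi_days = panel$pfi_days, patient_ids = panel$patient_ids,
    cohort_labels = panel$cohort_labels, panel = panel,
    provenance = c(attr(panel, "provenance"),
                   list(pipeline = c("impute_censored", "log10",
                                     "yeo_johnson_per_column",
                                     "yeo_johnson_pfi")))
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d patients x %d analytes (standardized), PFI lambda = %.3f\n",
              nrow(x$X), ncol(x$X), x$pfi_transform$lambda))
  invisible(x)
}

#' Serialize a cohort table (CSV matrix + JSON transforms)
#'
#' Writes `X` and `y` as one CSV (patient id, transformed PFI, then one
#' column per analyte) and the fitted transform parameters plus provenance
#' as JSON.
#'
#' @param table a [build_cohort_table()] result.
#' @param csv_file,json_file output paths.
#' @return `csv_file`, invisibly.
#' @export
write_cohort_table <- function(table, csv_file, json_file) {
  stopifnot(inherits(table, "cohort_table"))
  df <- data.frame(patient_id = table$patient_ids, y = table$y,
                   table$X, check.names = FALSE)
  utils::write.csv(df, csv_file, row.names = FALSE, fileEncoding = "UTF-8")
  tr <- lapply(table$column_transforms, unclass)
  jsonlite::write_json(list(column_transforms = tr,
                            pfi_transform = unclass(table$pfi_transform),
                            provenance = table$provenance),
                       json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_file)
}
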