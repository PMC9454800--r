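#' Construct an assay panel
#'
#' An `assay_panel` holds one cohort's multiplexed bead-based immunoassay
#' export: a patients-by-analytes concentration matrix (pg/mL) with per-cell
#' censoring flags, per-analyte assay limits and dilution factors, plus each
#' patient's treatment-cohort label and platinum-free interval (PFI) in days.
#' Cells flagged `"below"` (under the lower detection limit, LOD) or
#' `"above"` (over the top standard, ULOQ) carry `NA` concentrations; the
#' imputation rules in [impute_censored()] fill them from the limits.
#'
#' Limits are stored on the assay scale: a sample-scale concentration is
#' out of range when it falls below `lower_limit * dilution_factor` or above
#' `upper_limit * dilution_factor`.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param cohort_labels character vector, `"NACT"` or `"PDS"`, recycled if
#'   length 1.
#' @param pfi_days positive numeric vector, days from end of chemotherapy to
#'   recurrence.
#' @param concentrations numeric matrix, patients x analytes, pg/mL at
#'   sample scale; `NA` where censored.
#' @param censor_flags character matrix of `"none"`, `"below"`, `"above"`,
#'   same shape as `concentrations`.
#' @param analyte_names character vector of analyte names.
#' @param lower_limit,upper_limit numeric vectors per analyte, assay-scale
#'   pg/mL; `lower_limit < upper_limit`.
#' @param dilution_factor positive numeric vector per analyte (recycled if
#'   length 1).
#' @return An object of class `assay_panel`.
#' @export
assay_panel <- function(patient_ids, cohort_labels, pfi_days,
                        concentrations, censor_flags, analyte_names,
                        lower_limit, upper_limit, dilution_factor = 1) {
  n <- length(patient_ids)
  p <- length(analyte_names)
  concentrations <- as.matrix(concentrations)
  censor_flags <- as.matrix(censor_flags)
  if (length(cohort_labels) == 1L) cohort_labels <- rep(cohort_labels, n)
  if (length(dilution_factor) == 1L) dilution_factor <- rep(dilution_factor, p)
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids")
  if (anyDuplicated(analyte_names)) stop("duplicated analyte names")
  if (!all(dim(concentrations) == c(n, p)) || !all(dim(censor_flags) == c(n, p)))
    stop("matrix dimensions inconsistent with patient/analyte lists")
  if (length(pfi_days) != n || length(cohort_labels) != n)
    stop("per-patient vectors inconsistent with patient list")
  if (length(lower_limit) != p || length(upper_limit) != p ||
      length(dilution_factor) != p)
    stop("per-analyte vectors inconsistent with analyte list")
  if (!all(cohort_labels %in% c("NACT", "PDS")))
    stop("cohort labels must be 'NACT' or 'PDS'")
  if (anyNA(pfi_days) || any(pfi_days <= 0))
    stop("pfi_days must be positive for all patients")
  if (any(!is.finite(lower_limit)) || any(!is.finite(upper_limit)) ||
      any(lower_limit >= upper_limit))
    stop("limits must be finite with lower_limit < upper_limit")
  if (any(dilution_factor <= 0)) stop("dilution factors must be positive")
  if (!all(censor_flags %in% c("none", "below", "above")))
    stop("censor flags must be 'none', 'below' or 'above'")
  obs <- censor_flags == "none"
  if (any(!is.finite(concentrations[obs])) || any(concentrations[obs] < 0))
    stop("unflagged concentrations must be finite and >= 0")
  dimnames(concentrations) <- list(patient_ids, analyte_names)
  dimnames(censor_flags) <- list(patient_ids, analyte_names)
  structure(list(
    patient_ids = as.character(patient_ids),
    cohort_labels = as.character(cohort_labels),
    pfi_days = as.numeric(pfi_days),
    analyte_names = as.character(analyte_names),
    concentrations = concentrations,
    censor_flags = censor_flags,
    lower_limit = stats::setNames(as.numeric(lower_limit), analyte_names),
    upper_limit = stats::setNames(as.numeric(upper_limit), analyte_names),
    dilution_factor = stats::setNames(as.numeric(dilution_factor), analyte_names)
  ), class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  frac <- c(below = mean(x$censor_flags == "below"),
            above = mean(x$censor_flags == "above"))
  cat(sprintf("Assay panel: %d patients (%s), %d analytes\n",
              length(x$patient_ids),
              paste(sprintf("%d %s", table(x$cohort_labels),
                            names(table(x$cohort_labels))), collapse = ", "),
              length(x$analyte_names)))
  cat(sprintf("  PFI: median %.0f days (range %.0f-%.0f)\n",
              median(x$pfi_days), min(x$pfi_days), max(x$pfi_days)))
  cat(sprintf("  censored cells: %.1f%% below LOD, %.1f%% above ULOQ\n",
              100 * frac["below"], 100 * frac["above"]))
  invisible(x)
}

#' Flag out-of-range concentrations
#'
#' Compares a sample-scale concentration matrix against per-analyte lower
#' and upper limits (already on the sample scale) and returns a flag matrix.
#' Values exactly equal to a limit count as detectable (strict inequalities):
#' the instrument reports in-range values at the limits.
#'
#' @param concentrations numeric matrix, patients x analytes.
#' @param lower_limits,upper_limits numeric vectors, one value per analyte,
#'   finite, `lower < upper` elementwise.
#' @return character matrix of `"none"`, `"below"`, `"above"`.
#' @export
apply_censoring <- function(concentrations, lower_limits, upper_limits) {
  concentrations <- as.matrix(concentrations)
  p <- ncol(concentrations)
  if (length(lower_limits) != p || length(upper_limits) != p)
    stop("limit vectors must have one entry per analyte column")
  if (any(!is.finite(lower_limits)) || any(!is.finite(upper_limits)))
    stop("limits must be finite")
  if (any(lower_limits >= upper_limits))
    stop("lower limit must be below upper limit for every analyte")
  lo <- matrix(lower_limits, nrow(concentrations), p, byrow = TRUE)
  hi <- matrix(upper_limits, nrow(concentrations), p, byrow = TRUE)
  flags <- matrix("none", nrow(concentrations), p,
                  dimnames = dimnames(concentrations))
  flags[concentrations < lo] <- "below"
  flags[concentrations > hi] <- "above"
  flags
}

#' Read and write the assay-panel CSV dialect
#'
#' One wide UTF-8 CSV with columns `patient_id`, `cohort`, `pfi_days`, then
#' one column per analyte; censored cells hold the literal strings `<LOD`
#' and `>ULOQ`.  A companion analyte-metadata CSV has columns `analyte`,
#' `lower_limit_pg_ml`, `upper_limit_pg_ml`, `dilution_factor` (limits on
#' the assay scale).
#'
#' @param panel an [assay_panel()].
#' @param file,meta_file paths for the wide table and the analyte metadata.
#' @return `read_assay_panel()` returns an `assay_panel`;
#'   `write_assay_panel()` returns `file` invisibly.
#' @export
write_assay_panel <- function(panel, file, meta_file) {
  stopifnot(inherits(panel, "assay_panel"))
  cells <- matrix(format_num(panel$concentrations),
                  nrow(panel$concentrations), ncol(panel$concentrations))
  cells[panel$censor_flags == "below"] <- "<LOD"
  cells[panel$censor_flags == "above"] <- ">ULOQ"
  df <- data.frame(patient_id = panel$patient_ids,
                   cohort = panel$cohort_labels,
                   pfi_days = format_num(panel$pfi_days),
                   cells, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- panel$analyte_names
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  meta <- data.frame(analyte = panel$analyte_names,
                     lower_limit_pg_ml = format_num(panel$lower_limit),
                     upper_limit_pg_ml = format_num(panel$upper_limit),
                     dilution_factor = format_num(panel$dilution_factor),
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, meta_file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

format_num <- function(x) trimws(formatC(as.numeric(x), format = "g", digits = 17))

#' @rdname write_assay_panel
#' @export
read_assay_panel <- function(file, meta_file) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  meta <- utils::read.csv(meta_file, fileEncoding = "UTF-8")
  need <- c("patient_id", "cohort", "pfi_days")
  if (!all(need %in% names(df)))
    stop("panel CSV must have columns patient_id, cohort, pfi_days")
  analytes <- setdiff(names(df), need)
  if (!setequal(analytes, meta$analyte))
    stop("analyte metadata does not match panel columns")
  meta <- meta[match(analytes, meta$analyte), ]
  cells <- as.matrix(df[analytes])
  flags <- matrix("none", nrow(cells), ncol(cells))
  flags[cells == "<LOD"] <- "below"
  flags[cells == ">ULOQ"] <- "above"
  conc <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  conc[flags != "none"] <- NA_real_
  assay_panel(patient_ids = df$patient_id,
              cohort_labels = df$cohort,
              pfi_days = as.numeric(df$pfi_days),
              concentrations = conc,
              censor_flags = flags,
              analyte_names = analytes,
              lower_limit = meta$lower_limit_pg_ml,
              upper_limit = meta$upper_limit_pg_ml,
              dilution_factor = meta$dilution_factor)
}

# restrict a panel to a subset of analytes (keeps per-analyte metadata aligned)
panel_select_analytes <- function(panel, keep) {
  panel$analyte_names <- panel$analyte_names[keep]
  panel$concentrations <- panel$concentrations[, keep, drop = FALSE]
  panel$censor_flags <- panel$censor_flags[, keep, drop = FALSE]
  panel$lower_limit <- panel$lower_limit[keep]
  panel$upper_limit <- panel$upper_limit[keep]
  panel$dilution_factor <- panel$dilution_factor[keep]
  panel
}

# restrict a panel to a subset of patients
panel_select_patients <- function(panel, keep) {
  panel$patient_ids <- panel$patient_ids[keep]
  panel$cohort_labels <- panel$cohort_labels[keep]
  panel$pfi_days <- panel$pfi_days[keep]
  panel$concentrations <- panel$concentrations[keep, , drop = FALSE]
  panel$censor_flags <- panel$censor_flags[keep, , drop = FALSE]
  panel
}
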