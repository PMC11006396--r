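#' @keywords internal
"_PACKAGE"

# Closed vocabularies for categorical record fields.
record_vocab <- list(
  thermoregulation = c("endotherm", "ectotherm"),
  fertilization_mode = c("internal", "external"),
  diluent = c("carbohydrate_free", "carbohydrate_containing"),
  diluent_job = c("activator", "extender", "unknown"),
  handling = c("fresh", "cooled", "frozen_thawed", "unknown"),
  reporting = c("actual", "standardized")
)

record_columns <- c(
  "species", "thermoregulation", "fertilization_mode", "diluent",
  "diluent_job", "handling", "concentration_sperm_per_ml",
  "rate_ul_o2_per_h", "reporting", "std_concentration_sperm_per_ml",
  "assay_volume_ml", "n_replicates", "source"
)

#' Validate a table of sperm metabolic records
#'
#' Checks every row of a record table against the package schema and its
#' invariants: concentration and rate strictly positive, categorical fields
#' drawn from the closed vocabularies, and standardized records carrying the
#' standard concentration they were rescaled to. Validation is total: every
#' offending row is reported with its row number; nothing is silently
#' dropped. A record whose `reporting` is `"standardized"` may have a
#' missing measured concentration — such rows cannot enter the scaling fit
#' and are flagged by [fit_eligible()] rather than deleted, preserving an
#' audit trail of the exclusion.
#'
#' @param records a data.frame with the columns listed under
#'   [read_records()].
#' @return `records`, invisibly, if valid; otherwise an error listing every
#'   offending row and the reason.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols)) {
    stop("record table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
    }
  }
  conc <- records$concentration_sperm_per_ml
  rate <- records$rate_ul_o2_per_h
  std <- records$std_concentration_sperm_per_ml
  standardized <- records$reporting == "standardized"

  note(which(!is.na(conc) & conc <= 0),
       "concentration_sperm_per_ml must be > 0")
  note(which(is.na(conc) & !standardized),
       "missing concentration on a non-standardized record")
  note(which(is.na(rate) | rate <= 0), "rate_ul_o2_per_h must be > 0")
  note(which(standardized & (is.na(std) | std <= 0)),
       "reporting = standardized requires a positive std_concentration_sperm_per_ml")
  for (field in names(record_vocab)) {
    vals <- records[[field]]
    bad <- which(is.na(vals) | !(vals %in% record_vocab[[field]]))
    note(bad, sprintf("unknown %s (allowed: %s)", field,
                      paste(record_vocab[[field]], collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid metabolic records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(records)
}

#' Which records can enter the scaling fit?
#'
#' A record is fit-eligible when its measured concentration is known and
#' positive. Standardized records that never reported the concentration at
#' which respiration was actually measured cannot be back-calculated and are
#' excluded from model fitting (but retained in the table).
#'
#' @param records a validated record table.
#' @return logical vector, one element per row.
#' @export
fit_eligible <- function(records) {
  !is.na(records$concentration_sperm_per_ml) &
    records$concentration_sperm_per_ml > 0
}

#' Flag duplicate records
#'
#' Marks rows whose (species, source, concentration, rate) tuple repeats an
#' earlier row. Duplicates are flagged rather than merged; the compilation
#' this schema mirrors gives no deduplication rule.
#'
#' @param records a record table.
#' @return logical vector, `TRUE` for second and later occurrences.
#' @export
flag_duplicates <- function(records) {
  duplicated(records[c("species", "source", "concentration_sperm_per_ml",
                       "rate_ul_o2_per_h")])
}

#' Read and write sperm metabolic-rate records
#'
#' The on-disk format is a UTF-8, comma-separated file with a header and
#' `.` decimal point; scientific notation is accepted for concentrations.
#' Columns, in order:
#'
#' * `species` — species label (free text).
#' * `thermoregulation` — `endotherm` or `ectotherm`.
#' * `fertilization_mode` — `internal` or `external`.
#' * `diluent` — `carbohydrate_free` or `carbohydrate_containing`.
#' * `diluent_job` — `activator`, `extender` or `unknown`.
#' * `handling` — `fresh`, `cooled`, `frozen_thawed` or `unknown`.
#' * `concentration_sperm_per_ml` — measured sperm concentration (> 0; may
#'   be empty only when `reporting` is `standardized`).
#' * `rate_ul_o2_per_h` — ejaculate-level oxygen consumption, µl O2 h^-1.
#' * `reporting` — `actual` (rate reported at the measured concentration)
#'   or `standardized` (rate linearly rescaled to a standard concentration).
#' * `std_concentration_sperm_per_ml` — the standard concentration, required
#'   when `reporting` is `standardized`.
#' * `assay_volume_ml` — chamber volume if known (else empty; a 1 ml default
#'   is applied by [per_capita_rate()]).
#' * `n_replicates` — replicate count if known.
#' * `source` — provenance (free text).
#'
#' `write_records()` writes numeric fields at full double precision so a
#' write/read cycle is lossless.
#'
#' @param path file path.
#' @param records a record data.frame (or `synthetic_dataset`).
#' @param validate validate after reading / before writing (default `TRUE`).
#' @return `read_records()` returns the validated record data.frame;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(
                               species = "character",
                               thermoregulation = "character",
                               fertilization_mode = "character",
                               diluent = "character",
                               diluent_job = "character",
                               handling = "character",
                               concentration_sperm_per_ml = "numeric",
                               rate_ul_o2_per_h = "numeric",
                               reporting = "character",
                               std_concentration_sperm_per_ml = "numeric",
                               assay_volume_ml = "numeric",
                               n_replicates = "integer",
                               source = "character"
                             ))
  if (validate) validate_records(records)
  records
}

#' @rdname read_records
#' @export
write_records <- function(records, path, validate = TRUE) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  if (validate) validate_records(records)
  out <- records[record_columns]
  for (col in c("concentration_sperm_per_ml", "rate_ul_o2_per_h",
                "std_concentration_sperm_per_ml", "assay_volume_ml")) {
    out[[col]] <- vapply(out[[col]], function(x) {
      if (is.na(x)) "" else format(x, digits = 17, scientific = TRUE)
    }, character(1))
  }
  # quote only the genuinely textual columns so numeric fields parse under
  # strict colClasses on the way back in
  quote_cols <- which(record_columns %in%
                        c("species", "thermoregulation",
                          "fertilization_mode", "diluent", "diluent_job",
                          "handling", "reporting", "source"))
  utils::write.table(out, path, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double", quote = quote_cols)
  invisible(path)
}

#' Back-calculate an actual metabolic rate from a standardized report
#'
#' Inverts the linear standardization convention \eqn{Z = R \cdot C_{std} /
#' C}: given a rate reported at a standard concentration and the
#' concentration at which respiration was actually measured, returns the
#' rate the original measurement produced,
#' \eqn{R = Z / C_{std} \times C}. For example, a report of 1.34 µl O2 h^-1
#' standardized to 10^8 sperm ml^-1 but measured at 3e8 sperm ml^-1
#' back-calculates to 4.02 µl O2 h^-1. This is the same linear
#' transformation the original authors applied, run in reverse; it involves
#' no scaling assumption beyond theirs.
#'
#' @param standardized_rate reported standardized rate, µl O2 h^-1 (> 0).
#' @param std_concentration concentration the rate was standardized to,
#'   sperm ml^-1 (> 0).
#' @param actual_concentration concentration at which respiration was
#'   measured, sperm ml^-1 (> 0).
#' @return actual metabolic rate, µl O2 h^-1. Vectorized.
#' @examples
#' back_calculate_actual_rate(1.34, 1e8, 3e8)  # 4.02
#' @export
back_calculate_actual_rate <- function(standardized_rate, std_concentration,
                                       actual_concentration) {
  if (any(standardized_rate <= 0) || any(std_concentration <= 0) ||
      any(actual_concentration <= 0)) {
    stop("all arguments to back_calculate_actual_rate must be > 0",
         call. = FALSE)
  }
  standardized_rate / std_concentration * actual_concentration
}

#' Harmonize a record table to actual measured rates
#'
#' Replaces each standardized record's rate by its back-calculated actual
#' rate (at the measured concentration) and relabels it `reporting =
#' "actual"`. Standardized records whose measured concentration is unknown
#' cannot be recovered; they are left untouched and counted in the
#' `n_unrecoverable` attribute (they remain excluded from fitting via
#' [fit_eligible()]).
#'
#' @param records a validated record table.
#' @return the harmonized table, with attribute `n_unrecoverable`.
#' @export
harmonize_records <- function(records) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  validate_records(records)
  std <- records$reporting == "standardized"
  recoverable <- std & fit_eligible(records)
  if (any(recoverable)) {
    records$rate_ul_o2_per_h[recoverable] <- back_calculate_actual_rate(
      records$rate_ul_o2_per_h[recoverable],
      records$std_concentration_sperm_per_ml[recoverable],
      records$concentration_sperm_per_ml[recoverable]
    )
    records$reporting[recoverable] <- "actual"
  }
  attr(records, "n_unrecoverable") <- sum(std & !recoverable)
  records
}

#' Per capita metabolic rate
#'
#' Converts an ejaculate-level rate to a per-spermatozoon rate:
#' \eqn{R / (C \cdot V)} with concentration \eqn{C} in sperm ml^-1 and
#' chamber volume \eqn{V} in ml (per-record `assay_volume_ml` when present,
#' else `default_volume_ml`). Units: µl O2 spermatozoon^-1 h^-1. The
#' log-log slope of the per-capita rate against concentration equals the
#' ejaculate-level slope minus one whenever the volume is constant, so
#' scaling conclusions are invariant to the volume default.
#'
#' @param records a record table with known concentrations.
#' @param default_volume_ml assay volume assumed when unreported (ml).
#' @return numeric vector of per capita rates.
#' @examples
#' r <- data.frame(concentration_sperm_per_ml = 3e8,
#'                 rate_ul_o2_per_h = 4.02, assay_volume_ml = NA_real_)
#' per_capita_rate(r)  # 1.34e-08
#' @export
per_capita_rate <- function(records, default_volume_ml = 1) {
  conc <- records$concentration_sperm_per_ml
  if (any(is.na(conc))) {
    stop("per_capita_rate: missing measured concentration; harmonize and ",
         "filter with fit_eligible() first", call. = FALSE)
  }
  vol <- records$assay_volume_ml
  if (is.null(vol)) vol <- rep(NA_real_, nrow(records))
  vol <- ifelse(is.na(vol), default_volume_ml, vol)
  records$rate_ul_o2_per_h / (conc * vol)
}
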