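#' Longitudinal PK datasets
#'
#' Datasets follow the conventional event-record layout: one row per dose or
#' observation, with columns
#' \describe{
#'   \item{ID}{subject identifier}
#'   \item{TIME}{hours since the subject's first dose, non-decreasing within ID}
#'   \item{EVID}{1 = dose event, 0 = observation}
#'   \item{AMT, DUR}{dose amount (mg) and infusion duration (h); dose rows only}
#'   \item{DV}{observed concentration (mg/L); observation rows only}
#'   \item{MDV}{missing-DV flag (1 on dose rows)}
#'   \item{EXCL}{TRUE when the observation lies outside the assay calibration
#'     range of 2–50 mg/L and is excluded from fitting}
#' }
#' plus covariate columns (WT, SCR, DFI, DA, ...) constant within subject.
#'
#' `read_pk_dataset()` validates the layout and (re)applies the calibration
#' filter; `write_pk_dataset()` writes a CSV that round-trips losslessly.
#'
#' @param path Path to a CSV file.
#' @param calibration Two-element numeric range (mg/L) of the assay; values
#'   outside it are flagged `EXCL = TRUE`, never altered or dropped.
#' @return A tibble in event-record form.
#' @name pk_dataset_io
NULL

CALIBRATION_RANGE <- c(2, 50)
RESERVED_COLS <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV", "EXCL")

#' @rdname pk_dataset_io
#' @export
read_pk_dataset <- function(path, calibration = CALIBRATION_RANGE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warn("Empty PK dataset.")
    return(as_tibble(df))
  }
  validate_pk_dataset(as_tibble(df), calibration = calibration,
                      recompute_excl = TRUE)
}

#' @rdname pk_dataset_io
#' @param data Event-record tibble.
#' @export
write_pk_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate an event-record PK dataset
#'
#' Checks the structural invariants (required columns, dose rows carry
#' AMT/DUR and no DV, observation rows the reverse, TIME non-decreasing
#' within subject) and applies the calibration-range exclusion flag. An
#' existing `EXCL` column is preserved unless `recompute_excl = TRUE`, so a
#' flag set on load is never silently overridden downstream.
#'
#' @inheritParams pk_dataset_io
#' @param recompute_excl Recompute the exclusion flag from `calibration`?
#'   Defaults to `TRUE` only when the column is absent.
#' @return The validated tibble with a logical `EXCL` column.
#' @export
validate_pk_dataset <- function(data, calibration = CALIBRATION_RANGE,
                                recompute_excl = !("EXCL" %in% names(data))) {
  data <- as_tibble(data)
  need <- c("ID", "TIME", "EVID")
  missing_col <- setdiff(need, names(data))
  if (length(missing_col)) {
    abort(paste0("Missing required column(s): ", paste(missing_col, collapse = ", ")))
  }
  if (!"AMT" %in% names(data)) data$AMT <- NA_real_
  if (!"DUR" %in% names(data)) data$DUR <- NA_real_
  if (!"DV" %in% names(data)) data$DV <- NA_real_
  if (!"MDV" %in% names(data)) data$MDV <- ifelse(data$EVID == 1, 1L, 0L)

  dose <- data$EVID == 1
  if (any(dose & (is.na(data$AMT) | is.na(data$DUR)))) {
    abort(paste0("Dose row(s) without AMT/DUR: rows ",
                 paste(utils::head(which(dose & (is.na(data$AMT) | is.na(data$DUR))), 5),
                       collapse = ", ")))
  }
  if (any(dose & !is.na(data$DV))) {
    abort(paste0("Dose row(s) carrying DV: rows ",
                 paste(utils::head(which(dose & !is.na(data$DV)), 5), collapse = ", ")))
  }
  if (any(!dose & is.na(data$DV))) {
    abort(paste0("Observation row(s) without DV: rows ",
                 paste(utils::head(which(!dose & is.na(data$DV)), 5), collapse = ", ")))
  }
  if (any(data$TIME < 0)) abort("TIME must be non-negative.")
  mono <- tapply(data$TIME, data$ID, function(t) all(diff(t) >= 0))
  if (!all(mono)) {
    abort(paste0("TIME not non-decreasing within ID: ",
                 paste(names(mono)[!mono], collapse = ", ")))
  }
  if (any(!dose & data$DV <= 0, na.rm = TRUE)) {
    abort("Observed concentrations must be strictly positive.")
  }
  if (recompute_excl) {
    data$EXCL <- !dose & (data$DV < calibration[1] | data$DV > calibration[2])
  }
  data
}

# Internal: split an event-record dataset into per-subject pieces and build
# the flat arrays consumed by the C++ objective. Excluded observations are
# dropped here (flagging happens upstream and is never destructive).
as_subject_list <- function(data) {
  data <- validate_pk_dataset(data)
  ids <- unique(data$ID)
  subjects <- lapply(ids, function(id) {
    rows <- data[data$ID == id, ]
    dose <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0 & !rows$EXCL, ]
    covs <- rows[1, setdiff(names(rows), RESERVED_COLS), drop = FALSE]
    list(id = id,
         doses = tibble(time = dose$TIME, amt = dose$AMT, dur = dose$DUR),
         obs = tibble(time = obs$TIME, dv = obs$DV),
         covariates = as_tibble(covs))
  })
  keep <- vapply(subjects, function(s) nrow(s$obs) > 0 && nrow(s$doses) > 0, logical(1))
  if (any(!keep)) {
    warn(paste0(sum(!keep), " subject(s) dropped: no fittable observations ",
                "after the calibration filter."))
  }
  subjects[keep]
}

# Internal: flatten a subject list for foce_ofv_cpp
flatten_subjects <- function(subjects) {
  nobs <- vapply(subjects, function(s) nrow(s$obs), integer(1))
  nd <- vapply(subjects, function(s) nrow(s$doses), integer(1))
  list(
    y = unlist(lapply(subjects, function(s) s$obs$dv), use.names = FALSE),
    tobs = unlist(lapply(subjects, function(s) s$obs$time), use.names = FALSE),
    obs_ptr = as.integer(c(0, cumsum(nobs))),
    dtime = unlist(lapply(subjects, function(s) s$doses$time), use.names = FALSE),
    damt = unlist(lapply(subjects, function(s) s$doses$amt), use.names = FALSE),
    ddur = unlist(lapply(subjects, function(s) s$doses$dur), use.names = FALSE),
    dose_ptr = as.integer(c(0, cumsum(nd))),
    covariates = dplyr::bind_rows(lapply(subjects, function(s) s$covariates)),
    ids = unlist(lapply(subjects, function(s) s$id), use.names = FALSE),
    nobs = nobs
  )
}
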