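#' Code-event and patient-record tables
#'
#' The pipeline works on three plain data frames:
#'
#' * register events — one row per procedure code occurrence in the
#'   administrative register: `patient_id`, `hospital_id`, `admission_date`
#'   (the register keys codes to the admission, not the operation day), `code`.
#' * chart events — one row per code occurrence abstracted from the patient
#'   chart: `patient_id`, `hospital_id`, `surgery_date`, `code`,
#'   `note_source` (`"surgical_note"` or `"other_note"`), `verifiable`
#'   (`FALSE` when the chart lacked enough information to determine the type
#'   of surgery).
#' * patient records — one row per reviewed patient: `patient_id`,
#'   `hospital_id` (home hospital, used for clustering patients that have no
#'   events), `chart_available`, `chart_has_ibd_surgery`,
#'   `excluded_insufficient` (chart mentions surgery but cannot be validated).
#'
#' `register_events()`, `chart_events()` and `patient_records()` build
#' validated tables from vectors; the `read_*`/`write_*` functions exchange
#' them as UTF-8 comma-separated files with ISO-8601 dates and a header row.
#'
#' @name event-tables
NULL

REGISTER_COLS <- c("patient_id", "hospital_id", "admission_date", "code")
CHART_COLS    <- c("patient_id", "hospital_id", "surgery_date", "code",
                   "note_source", "verifiable")
PATIENT_COLS  <- c("patient_id", "hospital_id", "chart_available",
                   "chart_has_ibd_surgery", "excluded_insufficient")

#' @rdname event-tables
#' @param patient_id,hospital_id opaque identifier strings.
#' @param admission_date,surgery_date `Date` vectors (or ISO-8601 strings).
#' @param code procedure-code text.
#' @param study_window length-2 `Date` vector; events outside it are rejected.
#' @export
register_events <- function(patient_id = character(), hospital_id = character(),
                            admission_date = as.Date(character()),
                            code = character(),
                            study_window = default_study_window()) {
  df <- data.frame(patient_id = as.character(patient_id),
                   hospital_id = as.character(hospital_id),
                   admission_date = as.Date(admission_date),
                   code = as.character(code), stringsAsFactors = FALSE)
  validate_events(df, "register", study_window)
}

#' @rdname event-tables
#' @param note_source `"surgical_note"` or `"other_note"`.
#' @param verifiable logical; `FALSE` flags codes whose surgery type could not
#'   be determined from the chart.
#' @export
chart_events <- function(patient_id = character(), hospital_id = character(),
                         surgery_date = as.Date(character()), code = character(),
                         note_source = "surgical_note", verifiable = TRUE,
                         study_window = default_study_window()) {
  n <- length(patient_id)
  df <- data.frame(patient_id = as.character(patient_id),
                   hospital_id = as.character(hospital_id),
                   surgery_date = as.Date(surgery_date),
                   code = as.character(code),
                   note_source = rep_len(as.character(note_source), n),
                   verifiable = rep_len(as.logical(verifiable), n),
                   stringsAsFactors = FALSE)
  validate_events(df, "chart", study_window)
}

#' @rdname event-tables
#' @param chart_available chart was physically retrievable for review.
#' @param chart_has_ibd_surgery chart documents IBD-related surgery.
#' @param excluded_insufficient chart documents surgery but with insufficient
#'   detail to validate; implies `chart_has_ibd_surgery`.
#' @export
patient_records <- function(patient_id, hospital_id,
                            chart_available = TRUE,
                            chart_has_ibd_surgery = FALSE,
                            excluded_insufficient = FALSE) {
  n <- length(patient_id)
  df <- data.frame(patient_id = as.character(patient_id),
                   hospital_id = as.character(hospital_id),
                   chart_available = rep_len(as.logical(chart_available), n),
                   chart_has_ibd_surgery = rep_len(as.logical(chart_has_ibd_surgery), n),
                   excluded_insufficient = rep_len(as.logical(excluded_insufficient), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in patient records", call. = FALSE)
  }
  if (any(df$excluded_insufficient & !df$chart_has_ibd_surgery)) {
    stop("excluded_insufficient patients must have chart_has_ibd_surgery = TRUE",
         call. = FALSE)
  }
  df
}

default_study_window <- function() as.Date(c("1966-01-01", "2014-12-31"))

date_col <- function(source) {
  if (source == "register") "admission_date" else "surgery_date"
}

validate_events <- function(df, source, study_window) {
  dcol <- date_col(source)
  if (anyNA(df[[dcol]])) stop(sprintf("missing or unparseable %s", dcol), call. = FALSE)
  if (any(!nzchar(trimws(df$code)))) stop("empty procedure code", call. = FALSE)
  if (!is.null(study_window)) {
    out <- df[[dcol]] < study_window[1L] | df[[dcol]] > study_window[2L]
    if (any(out)) {
      stop(sprintf("%d event date(s) outside the study window %s..%s",
                   sum(out), study_window[1L], study_window[2L]), call. = FALSE)
    }
  }
  if (source == "chart") {
    bad <- setdiff(unique(df$note_source), c("surgical_note", "other_note"))
    if (length(bad)) {
      stop(sprintf("unknown note_source value(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(df$verifiable)) stop("verifiable must be TRUE/FALSE", call. = FALSE)
  }
  df
}

# Strict ISO-8601 date parsing; reports 1-based data-file line numbers
# (header is line 1) for every bad row rather than skipping silently.
parse_iso_dates <- function(x, what, path) {
  x <- trimws(as.character(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!ok | is.na(d))
  if (length(bad)) {
    stop(sprintf("%s: invalid %s on line(s) %s (expected ISO-8601 calendar dates, got e.g. '%s')",
                 path, what, paste(utils::head(bad + 1L, 5L), collapse = ", "),
                 x[bad[1L]]), call. = FALSE)
  }
  d
}

parse_logical <- function(x, what, path) {
  v <- as.logical(trimws(as.character(x)))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: invalid %s on line(s) %s (expected TRUE/FALSE)",
                 path, what, paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  v
}

require_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read code events from a CSV file
#'
#' Expects the column schema of [register_events()] or [chart_events()]
#' according to `source`. Dates must be ISO-8601; rows with unparseable
#' mandatory fields raise an error naming the offending line, they are never
#' skipped silently.
#'
#' @param path CSV file path.
#' @param source `"register"` or `"chart"`.
#' @param study_window length-2 `Date` vector of admissible event dates, or
#'   `NULL` to skip the window check.
#' @return an event data frame (see [event-tables]).
#' @export
read_events <- function(path, source = c("register", "chart"),
                        study_window = default_study_window()) {
  source <- match.arg(source)
  if (!file.exists(path)) stop(sprintf("event file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- if (source == "register") REGISTER_COLS else CHART_COLS
  require_columns(raw, need, path)
  dcol <- date_col(source)
  raw[[dcol]] <- parse_iso_dates(raw[[dcol]], dcol, path)
  if (source == "chart") raw$verifiable <- parse_logical(raw$verifiable, "verifiable", path)
  validate_events(raw[need], source, study_window)
}

#' Write code events to a CSV file
#'
#' @param events an event data frame from [register_events()],
#'   [chart_events()] or [read_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- if ("admission_date" %in% names(events)) REGISTER_COLS else CHART_COLS
  require_columns(events, cols, "event table")
  utils::write.csv(events[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read patient records from a CSV file
#'
#' @inheritParams read_events
#' @return a patient-record data frame (see [patient_records()]).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop(sprintf("patient file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  require_columns(raw, PATIENT_COLS, path)
  patient_records(raw$patient_id, raw$hospital_id,
                  parse_logical(raw$chart_available, "chart_available", path),
                  parse_logical(raw$chart_has_ibd_surgery, "chart_has_ibd_surgery", path),
                  parse_logical(raw$excluded_insufficient, "excluded_insufficient", path))
}

#' Write patient records to a CSV file
#'
#' @param patients a patient-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  require_columns(patients, PATIENT_COLS, "patient table")
  utils::write.csv(patients[PATIENT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
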