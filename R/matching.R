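#' Pair chart and register code events and classify concordance
#'
#' Within each patient, register code occurrences are paired with chart code
#' occurrences for the same surgical occasion. The register keys codes to the
#' hospital admission while the chart records the operation day, so a register
#' event is a candidate partner for a chart event when
#' `0 <= surgery_date - admission_date <= window_days`.
#'
#' Pairing is done in two passes, after canonical sorting by
#' (patient, date, code), so the result never depends on input row order:
#'
#' 1. Exact-code pairs. For each code present in both sources, chart events
#'    are taken in date order and each is paired with the earliest still
#'    unused feasible admission. For window constraints of the form
#'    `delay in [0, w]` this greedy attains the maximum possible number of
#'    exact-code pairs (the feasible admission sets are intervals that shift
#'    right with the surgery date, so an exchange argument applies).
#' 2. Same-occasion pairs with different code text, the candidates for
#'    transfer errors (e.g. a chart `JFB64` registered as `JBF64`). Remaining
#'    chart events are taken in (date, code) order and paired with the
#'    earliest unused feasible admission, ties broken by register code text.
#'
#' Every event ends up in exactly one row of the result: paired rows get
#' verdict `"concordant"` or `"transfer_error"`, leftovers become
#' `"chart_only"` / `"register_only"`. Codes are compared case-insensitively
#' after stripping trailing `-` padding. Duplicate identical codes are paired
#' one-to-one, never one-to-many.
#'
#' @param chart_events,register_events event tables (see [event-tables]).
#' @param window_days non-negative integer; maximum admission-to-surgery delay
#'   for two events to count as the same occasion. Default 7: in the source
#'   validation study 90% of surgeries took place within 7 days of admission.
#' @return A `match_results` data frame with one row per match or unpaired
#'   event: `patient_id`, `hospital_id`, `chart_code`, `register_code`,
#'   `surgery_date`, `admission_date`, `delay_days`, `verdict`, `error_type`,
#'   `error_subtype`.
#' @seealso [classify_error()], [tabulate_matches()]
#' @export
match_events <- function(chart_events, register_events, window_days = 7) {
  if (!is.numeric(window_days) || length(window_days) != 1L ||
      is.na(window_days) || window_days < 0) {
    stop("window_days must be a single non-negative number", call. = FALSE)
  }
  ch <- chart_events
  rg <- register_events
  ch$.code <- normalize_code(ch$code)
  rg$.code <- normalize_code(rg$code)
  # canonical sort: (patient_id, date, code); removes input-order dependence
  ch <- ch[order(ch$patient_id, ch$surgery_date, ch$.code, ch$hospital_id), , drop = FALSE]
  rg <- rg[order(rg$patient_id, rg$admission_date, rg$.code, rg$hospital_id), , drop = FALSE]

  pids <- sort(unique(c(ch$patient_id, rg$patient_id)))
  ch_by <- split(seq_len(nrow(ch)), factor(ch$patient_id, levels = pids))
  rg_by <- split(seq_len(nrow(rg)), factor(rg$patient_id, levels = pids))

  rows <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    rows[[k]] <- match_one_patient(ch, rg, ch_by[[k]], rg_by[[k]], window_days)
  }
  out <- do.call(rbind, c(rows, list(empty_match_results())))
  rownames(out) <- NULL
  out <- classify_error(out)
  class(out) <- c("match_results", "data.frame")
  out
}

empty_match_results <- function() {
  data.frame(patient_id = character(), hospital_id = character(),
             chart_code = character(), register_code = character(),
             surgery_date = as.Date(character()), admission_date = as.Date(character()),
             delay_days = integer(), verdict = character(),
             stringsAsFactors = FALSE)
}

# Greedy pairing for one patient's events; ci/ri are row indices into ch/rg,
# already in canonical (date, code) order.
match_one_patient <- function(ch, rg, ci, ri, w) {
  n_c <- length(ci); n_r <- length(ri)
  c_used <- logical(n_c); r_used <- logical(n_r)
  pair_c <- integer(0); pair_r <- integer(0)

  if (n_c && n_r) {
    sdate <- as.numeric(ch$surgery_date[ci])
    adate <- as.numeric(rg$admission_date[ri])
    ccode <- ch$.code[ci]; rcode <- rg$.code[ri]
    # pass 1: exact codes, earliest feasible admission per chart event
    for (code in sort(intersect(unique(ccode), unique(rcode)))) {
      for (i in which(ccode == code)) {
        cand <- which(!r_used & rcode == code &
                        adate <= sdate[i] & adate >= sdate[i] - w)
        if (length(cand)) {
          j <- cand[which.min(adate[cand])]
          r_used[j] <- TRUE; c_used[i] <- TRUE
          pair_c <- c(pair_c, i); pair_r <- c(pair_r, j)
        }
      }
    }
    # pass 2: same-occasion, different code text (transfer-error candidates)
    for (i in which(!c_used)) {
      cand <- which(!r_used & adate <= sdate[i] & adate >= sdate[i] - w)
      if (length(cand)) {
        o <- cand[order(adate[cand], rcode[cand])]
        j <- o[1L]
        r_used[j] <- TRUE; c_used[i] <- TRUE
        pair_c <- c(pair_c, i); pair_r <- c(pair_r, j)
      }
    }
  }

  res <- list()
  if (length(pair_c)) {
    i <- ci[pair_c]; j <- ri[pair_r]
    res$paired <- data.frame(
      patient_id = ch$patient_id[i], hospital_id = ch$hospital_id[i],
      chart_code = ch$code[i], register_code = rg$code[j],
      surgery_date = ch$surgery_date[i], admission_date = rg$admission_date[j],
      delay_days = as.integer(ch$surgery_date[i] - rg$admission_date[j]),
      verdict = ifelse(ch$.code[i] == rg$.code[j], "concordant", "transfer_error"),
      stringsAsFactors = FALSE)
  }
  lc <- ci[!c_used]
  if (length(lc)) {
    res$chart_only <- data.frame(
      patient_id = ch$patient_id[lc], hospital_id = ch$hospital_id[lc],
      chart_code = ch$code[lc], register_code = NA_character_,
      surgery_date = ch$surgery_date[lc], admission_date = as.Date(NA),
      delay_days = NA_integer_, verdict = "chart_only", stringsAsFactors = FALSE)
  }
  lr <- ri[!r_used]
  if (length(lr)) {
    res$register_only <- data.frame(
      patient_id = rg$patient_id[lr], hospital_id = rg$hospital_id[lr],
      chart_code = NA_character_, register_code = rg$code[lr],
      surgery_date = as.Date(NA), admission_date = rg$admission_date[lr],
      delay_days = NA_integer_, verdict = "register_only", stringsAsFactors = FALSE)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Classify the coding-error type of each match result
#'
#' Adds `error_type` and `error_subtype` columns. A pair with both events
#' present but unequal code text is a transfer error: subtype
#' `"transposition"` when the two strings are equal as character multisets
#' (the pattern produced by swapping characters when hand-copying a code,
#' e.g. `JFB64` vs `JBF64`), otherwise `"substitution"`. Unpaired chart events
#' are `missing_in_register` (register failed to capture a performed
#' procedure); unpaired register events are `missing_in_chart` (a register
#' code with no chart counterpart). Concordant pairs get `"none"`.
#'
#' @param matches a `match_results` data frame from [match_events()].
#' @return `matches` with `error_type` and `error_subtype` columns.
#' @export
classify_error <- function(matches) {
  v <- matches$verdict
  type <- character(length(v))
  type[v == "concordant"]     <- "none"
  type[v == "transfer_error"] <- "transfer_error"
  type[v == "chart_only"]     <- "missing_in_register"
  type[v == "register_only"]  <- "missing_in_chart"
  sub <- rep(NA_character_, length(v))
  te <- which(v == "transfer_error")
  if (length(te)) {
    sub[te] <- ifelse(
      mapply(same_multiset,
             normalize_code(matches$chart_code[te]),
             normalize_code(matches$register_code[te])),
      "transposition", "substitution")
  }
  matches$error_type <- type
  matches$error_subtype <- sub
  matches
}

same_multiset <- function(a, b) {
  identical(sort(strsplit(a, "", fixed = TRUE)[[1L]]),
            sort(strsplit(b, "", fixed = TRUE)[[1L]]))
}

#' Validation count table
#'
#' The cross-tabulation every accuracy estimator is a ratio of. Code-level
#' cells count code occurrences among analysed surgery-positive patients;
#' patient-level cells count chart-negative patients. The constructor checks
#' the margin identities (`n_register = n_both + n_register_only`,
#' `n_chart = n_both + n_chart_only`, `n_concordant <= n_both`,
#' `n_true_negative + n_false_positive_patients = n_patients_negative`).
#'
#' @param n_register register code occurrences.
#' @param n_chart chart code occurrences.
#' @param n_both codes present in both sources (paired).
#' @param n_concordant paired codes with identical code text.
#' @param n_register_only,n_chart_only unpaired occurrences per source.
#' @param n_patients_negative analysed patients whose chart shows no
#'   IBD-related surgery.
#' @param n_true_negative negative patients with no register code.
#' @param n_false_positive_patients negative patients with at least one
#'   register code.
#' @return an object of class `validation_table`.
#' @export
validation_table <- function(n_register = 0, n_chart = 0, n_both = 0,
                             n_concordant = 0, n_register_only = n_register - n_both,
                             n_chart_only = n_chart - n_both,
                             n_patients_negative = 0, n_true_negative = 0,
                             n_false_positive_patients = n_patients_negative - n_true_negative) {
  x <- list(n_register = n_register, n_chart = n_chart, n_both = n_both,
            n_concordant = n_concordant, n_register_only = n_register_only,
            n_chart_only = n_chart_only, n_patients_negative = n_patients_negative,
            n_true_negative = n_true_negative,
            n_false_positive_patients = n_false_positive_patients)
  x <- lapply(x, function(v) as.integer(round(v)))
  if (any(unlist(x) < 0L)) stop("validation_table counts must be non-negative", call. = FALSE)
  with(x, {
    if (n_register != n_both + n_register_only)
      stop("n_register must equal n_both + n_register_only", call. = FALSE)
    if (n_chart != n_both + n_chart_only)
      stop("n_chart must equal n_both + n_chart_only", call. = FALSE)
    if (n_concordant > n_both)
      stop("n_concordant cannot exceed n_both", call. = FALSE)
    if (n_true_negative + n_false_positive_patients != n_patients_negative)
      stop("n_true_negative + n_false_positive_patients must equal n_patients_negative",
           call. = FALSE)
  })
  structure(x, class = "validation_table")
}

#' @export
print.validation_table <- function(x, ...) {
  cat("<validation_table>\n")
  cat(sprintf("  codes: register %d (%d unpaired), chart %d (%d unpaired)\n",
              x$n_register, x$n_register_only, x$n_chart, x$n_chart_only))
  cat(sprintf("  paired %d, concordant %d\n", x$n_both, x$n_concordant))
  cat(sprintf("  negative patients %d (true negative %d, false positive %d)\n",
              x$n_patients_negative, x$n_true_negative, x$n_false_positive_patients))
  invisible(x)
}

#' @export
as.data.frame.validation_table <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

# Per-patient decomposition of the validation table over the analysis set
# (chart available, not excluded). Row sums of the count columns give the
# pooled table; the hospital-clustered bootstrap resamples these rows.
patient_counts <- function(matches, patients) {
  unknown <- setdiff(unique(matches$patient_id), patients$patient_id)
  if (length(unknown)) {
    stop(sprintf("match results reference unknown patient_id(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")), call. = FALSE)
  }
  analysed <- patients[patients$chart_available & !patients$excluded_insufficient, ,
                       drop = FALSE]
  m <- matches[matches$patient_id %in% analysed$patient_id, , drop = FALSE]
  f <- factor(m$patient_id, levels = analysed$patient_id)
  cnt <- function(keep) as.vector(table(f[keep]))
  n_conc  <- cnt(m$verdict == "concordant")
  n_trans <- cnt(m$verdict == "transfer_error")
  n_ronly <- cnt(m$verdict == "register_only")
  n_conly <- cnt(m$verdict == "chart_only")
  n_both  <- n_conc + n_trans
  neg <- as.integer(!analysed$chart_has_ibd_surgery)
  n_register <- n_both + n_ronly
  out <- cbind(n_register = n_register,
               n_chart = n_both + n_conly,
               n_both = n_both,
               n_concordant = n_conc,
               n_negative = neg,
               n_true_negative = as.integer(neg == 1L & n_register == 0L))
  rownames(out) <- analysed$patient_id
  out
}

counts_to_table <- function(counts) {
  s <- colSums(counts)
  validation_table(
    n_register = s[["n_register"]], n_chart = s[["n_chart"]],
    n_both = s[["n_both"]], n_concordant = s[["n_concordant"]],
    n_patients_negative = s[["n_negative"]], n_true_negative = s[["n_true_negative"]])
}

#' Cross-tabulate match results into a validation table
#'
#' Counts are taken over the analysis set: patients with an available chart
#' and not excluded for insufficient surgical notes. Patient-level negatives
#' are analysed patients whose chart shows no IBD-related surgery; those with
#' at least one register code are the false-positive patients.
#'
#' @param matches a `match_results` data frame from [match_events()].
#' @param patients a patient-record table (see [patient_records()]).
#' @return a [validation_table()].
#' @export
tabulate_matches <- function(matches, patients) {
  counts_to_table(patient_counts(matches, patients))
}

#' Summarize admission-to-surgery delays
#'
#' The register records the admission date, not the operation day; the delay
#' between them matters when register codes are used to time outcomes after
#' surgery. Summaries are computed over each patient's first paired surgical
#' occasion by default (`per_patient = TRUE`), or over all paired codes.
#'
#' @param matches a `match_results` data frame.
#' @param per_patient summarize one (first) delay per patient.
#' @return An object of class `delay_summary`: a list with `n`, `median_days`,
#'   `mean_days`, `sd_days`, `iqr_days` and `proportion_within(k)`, the
#'   fraction of delays at most `k` days. With no defined delays all summary
#'   fields are `NA` and `n` is 0 (an explicit empty sentinel).
#' @export
delay_summary <- function(matches, per_patient = TRUE) {
  m <- matches[!is.na(matches$delay_days), , drop = FALSE]
  if (nrow(m) && per_patient) {
    m <- m[order(m$patient_id, m$surgery_date, m$delay_days), , drop = FALSE]
    m <- m[!duplicated(m$patient_id), , drop = FALSE]
  }
  d <- m$delay_days
  out <- if (length(d)) {
    list(n = length(d),
         median_days = stats::median(d),
         mean_days = mean(d),
         sd_days = stats::sd(d),
         iqr_days = stats::IQR(d),
         proportion_within = function(k) mean(d <= k))
  } else {
    list(n = 0L, median_days = NA_real_, mean_days = NA_real_,
         sd_days = NA_real_, iqr_days = NA_real_,
         proportion_within = function(k) NA_real_)
  }
  structure(out, class = "delay_summary")
}

#' @export
print.delay_summary <- function(x, ...) {
  if (x$n == 0L) {
    cat("<delay_summary> no delays defined\n")
  } else {
    cat(sprintf("<delay_summary> n=%d, median %s (IQR %s), mean %.1f (SD %s) days; within 7 days: %.0f%%\n",
                x$n, format(x$median_days), format(x$iqr_days), x$mean_days,
                ifelse(is.na(x$sd_days), "NA", sprintf("%.1f", x$sd_days)),
                100 * x$proportion_within(7)))
  }
  invisible(x)
}
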