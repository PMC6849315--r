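#' Accuracy estimates
#'
#' Container for one named accuracy statistic: a ratio of validation-table
#' counts, optionally with a bootstrap percentile confidence interval. When
#' the denominator is zero the estimate is an explicit undefined sentinel
#' (`defined = FALSE`, `point = NA`) rather than 0 or a silent `NaN` — small
#' strata inside bootstrap replicates hit this case routinely.
#'
#' @param statistic one of `"ppv_true_positive"`, `"ppv_concordant"`,
#'   `"sensitivity"`, `"specificity"`, `"npv"`.
#' @param numerator,denominator the counts the statistic is a ratio of.
#' @param ci_low,ci_high optional bootstrap percentile CI bounds.
#' @param n_resamples,n_degenerate bootstrap metadata: replicates drawn and
#'   replicates dropped as degenerate.
#' @param seed bootstrap seed, if any.
#' @param stratum optional stratum label (e.g. `"abdominal"`, `"pre1997"`).
#' @return an object of class `accuracy_estimate`.
#' @export
accuracy_estimate <- function(statistic, numerator, denominator,
                              ci_low = NA_real_, ci_high = NA_real_,
                              n_resamples = NA_integer_, n_degenerate = NA_integer_,
                              seed = NA_integer_, stratum = NA_character_) {
  statistic <- match.arg(statistic,
                         c("ppv_true_positive", "ppv_concordant", "sensitivity",
                           "specificity", "npv"))
  defined <- denominator > 0
  structure(list(statistic = statistic,
                 point = if (defined) numerator / denominator else NA_real_,
                 numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 defined = defined,
                 ci_low = ci_low, ci_high = ci_high,
                 n_resamples = n_resamples, n_degenerate = n_degenerate,
                 seed = seed, stratum = stratum),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  lab <- if (is.na(x$stratum)) x$statistic else paste0(x$statistic, " [", x$stratum, "]")
  if (!x$defined) {
    cat(sprintf("<accuracy_estimate> %s: undefined (denominator 0)\n", lab))
    return(invisible(x))
  }
  ci <- if (!is.na(x$ci_low)) {
    sprintf(" (95%%CI %s-%s)", format_pct(x$ci_low), format_pct(x$ci_high))
  } else ""
  cat(sprintf("<accuracy_estimate> %s: %s%%%s  %d/%d\n",
              lab, format_pct(x$point), ci, x$numerator, x$denominator))
  invisible(x)
}

# half-up rounding to one decimal, in percent, matching report style
format_pct <- function(p, digits = 1) {
  scale <- 10^digits
  sprintf(paste0("%.", digits, "f"), floor(p * 100 * scale + 0.5) / scale)
}

#' Positive predictive value of validated (true-positive) codes
#'
#' The proportion of register codes that were also found in the chart
#' (and therefore validated) which are concordant with the chart:
#' `n_concordant / n_both`.
#'
#' @param table a [validation_table()].
#' @return an [accuracy_estimate()].
#' @export
ppv_true_positive <- function(table) {
  accuracy_estimate("ppv_true_positive", table$n_concordant, table$n_both)
}

#' Positive predictive value over all register codes
#'
#' The proportion of all register codes (validated or not) that are
#' concordant with the chart: `n_concordant / n_register`. Always less than
#' or equal to [ppv_true_positive()] (same numerator, larger denominator).
#'
#' @param table a [validation_table()].
#' @return an [accuracy_estimate()].
#' @export
ppv_concordant <- function(table) {
  accuracy_estimate("ppv_concordant", table$n_concordant, table$n_register)
}

#' Sensitivity of the register
#'
#' The proportion of gold-standard chart codes captured by the register:
#' `n_both / n_chart`.
#'
#' @param table a [validation_table()].
#' @return an [accuracy_estimate()].
#' @export
sensitivity <- function(table) {
  accuracy_estimate("sensitivity", table$n_both, table$n_chart)
}

#' Specificity of the register (patient level)
#'
#' The proportion of chart-negative patients (no IBD-related surgery in the
#' chart) with no surgical code in the register:
#' `n_true_negative / n_patients_negative`.
#'
#' @param table a [validation_table()].
#' @return an [accuracy_estimate()].
#' @export
specificity <- function(table) {
  accuracy_estimate("specificity", table$n_true_negative, table$n_patients_negative)
}

#' Conditioned negative predictive value
#'
#' NPV computed under an assumed number of false-negative patients:
#' `n_true_negative / (n_true_negative + n_false_negative_patients)`.
#' Register-negative patients were not chart-reviewed for missed surgery in
#' the source design, so the NPV is reported as a sensitivity analysis
#' conditioning on how many of the patients carrying register-missed codes
#' are treated as false negatives.
#'
#' @param table a [validation_table()].
#' @param n_false_negative_patients assumed count of false-negative patients.
#' @return an [accuracy_estimate()].
#' @export
npv_conditioned <- function(table, n_false_negative_patients) {
  if (n_false_negative_patients < 0) {
    stop("n_false_negative_patients must be non-negative", call. = FALSE)
  }
  accuracy_estimate("npv", table$n_true_negative,
                    table$n_true_negative + n_false_negative_patients)
}

#' Scenario bounds for unverifiable codes
#'
#' Patients whose charts mention surgery but lack enough detail to validate
#' contribute codes with an unknown verdict. The scenario bounds bracket a
#' statistic by assuming all `n_unverifiable_codes` such codes are discordant
#' (lower bound) or all concordant (upper bound). For the PPV variants the
#' codes enter the denominator in both scenarios and the numerator only in
#' the upper; for sensitivity the unverifiable chart codes enter the chart
#' denominator in both scenarios and count as captured only in the upper.
#'
#' @param table a [validation_table()].
#' @param n_unverifiable_codes number of unverifiable codes to add.
#' @param statistic `"ppv_true_positive"`, `"ppv_concordant"` or
#'   `"sensitivity"`.
#' @return list with elements `lower` and `upper`, both [accuracy_estimate()].
#' @export
scenario_bounds <- function(table, n_unverifiable_codes,
                            statistic = c("ppv_concordant", "ppv_true_positive",
                                          "sensitivity")) {
  statistic <- match.arg(statistic)
  k <- as.integer(n_unverifiable_codes)
  if (k < 0) stop("n_unverifiable_codes must be non-negative", call. = FALSE)
  base <- switch(statistic,
                 ppv_true_positive = c(table$n_concordant, table$n_both),
                 ppv_concordant    = c(table$n_concordant, table$n_register),
                 sensitivity       = c(table$n_both, table$n_chart))
  list(lower = accuracy_estimate(statistic, base[1L], base[2L] + k),
       upper = accuracy_estimate(statistic, base[1L] + k, base[2L] + k))
}

#' Count unverifiable chart codes
#'
#' Convenience helper: the number of chart code events flagged
#' `verifiable = FALSE`, the `n_unverifiable_codes` input of
#' [scenario_bounds()].
#'
#' @param chart_events a chart event table.
#' @return integer count.
#' @export
n_unverifiable_codes <- function(chart_events) {
  sum(!chart_events$verifiable)
}

#' Stratify match results into per-stratum validation tables
#'
#' Splits the code-level match results by anatomic category or by coding era
#' and tabulates each stratum. The anatomic category of a pair comes from the
#' chart code (the gold standard) resolved against the code list, falling back
#' to the register code for register-only results. The era of a code is the
#' year of its register admission date (`<= 1996` vs `>= 1997`, the year the
#' procedure-code classification changed); chart-only codes, which have no
#' register date, use the surgery year.
#'
#' Patient-level negative counts have no anatomic category or era, so stratum
#' tables carry zeros in the patient-level cells; stratified specificity is
#' not defined. Code-level cells of the strata sum to the pooled table.
#'
#' @param matches a `match_results` data frame.
#' @param patients a patient-record table.
#' @param axis `"anatomic"` or `"era"`.
#' @param codelist a [codelist()]; required for `axis = "anatomic"`.
#' @return named list of [validation_table()], one per stratum level
#'   (`abdominal`/`perianal`/`other` or `pre1997`/`post1997`).
#' @export
stratify_matches <- function(matches, patients, axis = c("anatomic", "era"),
                             codelist = NULL) {
  axis <- match.arg(axis)
  analysed <- patients$patient_id[patients$chart_available &
                                    !patients$excluded_insufficient]
  m <- matches[matches$patient_id %in% analysed, , drop = FALSE]
  stratum <- stratum_of(m, axis, codelist)
  lapply(split(m, stratum), function(s) {
    n_conc  <- sum(s$verdict == "concordant")
    n_both  <- n_conc + sum(s$verdict == "transfer_error")
    validation_table(
      n_register = n_both + sum(s$verdict == "register_only"),
      n_chart = n_both + sum(s$verdict == "chart_only"),
      n_both = n_both, n_concordant = n_conc)
  })
}
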