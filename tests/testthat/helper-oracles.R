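# Shared test helpers: independent oracles and random-case generators.

# Exhaustive maximum-cardinality exact-code matching for one patient:
# recursion over chart events trying every feasible register partner.
# Independent of the greedy implementation; intended for <= 4x4 instances.
max_exact_pairs_oracle <- function(surgery_days, chart_codes,
                                   admission_days, register_codes, window) {
  n <- length(surgery_days)
  rec <- function(i, used) {
    if (i > n) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_along(admission_days)) {
      d <- surgery_days[i] - admission_days[j]
      if (!used[j] && register_codes[j] == chart_codes[i] && d >= 0 && d <= window) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(length(admission_days)))
}

# one-patient event tables on a day grid
day0 <- as.Date("2000-06-01")
mk_chart <- function(days, codes, pid = "P1", hosp = "H1", ...) {
  chart_events(rep_len(pid, length(days)), rep_len(hosp, length(days)),
               day0 + days, codes, ..., study_window = NULL)
}
mk_register <- function(days, codes, pid = "P1", hosp = "H1") {
  register_events(rep_len(pid, length(days)), rep_len(hosp, length(days)),
                  day0 + days, codes, study_window = NULL)
}
mk_patients <- function(pids, hosp = "H1", surgical = TRUE) {
  patient_records(pids, rep_len(hosp, length(pids)),
                  chart_has_ibd_surgery = surgical)
}

rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# random consistent fixture-counts configuration (for fidelity properties)
random_fixture_counts <- function() {
  cells <- expand.grid(category = c("abdominal", "perianal", "other"),
                       era = c("pre1997", "post1997"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n_both <- vapply(seq_len(6L), function(i) rint(0L, 6L), integer(1L))
  cells$n_concordant <- vapply(cells$n_both, function(b) rint(0L, b), integer(1L))
  cells$n_chart_only <- vapply(seq_len(6L), function(i) rint(0L, 3L), integer(1L))
  cells$n_register_only <- vapply(seq_len(6L), function(i) rint(0L, 2L), integer(1L))
  n_ro <- sum(cells$n_register_only)
  n_fp <- if (n_ro > 0L) rint(1L, n_ro) else 0L
  n_tn <- rint(0L, 8L)
  fixture_counts(cells,
                 n_surgical_patients = rint(3L, 10L),
                 n_negative_patients = n_fp + n_tn,
                 n_true_negative = n_tn,
                 n_excluded_patients = rint(0L, 3L),
                 n_hospitals = rint(1L, 5L))
}

# totals implied by a fixture-counts configuration
fixture_totals <- function(counts) {
  cl <- counts$cells
  list(n_register = sum(cl$n_both) + sum(cl$n_register_only),
       n_chart = sum(cl$n_both) + sum(cl$n_chart_only),
       n_both = sum(cl$n_both),
       n_concordant = sum(cl$n_concordant),
       n_patients_negative = counts$n_negative_patients,
       n_true_negative = counts$n_true_negative)
}

paper_pipeline <- function(window_days = 7) {
  fx <- build_fixture()
  m <- match_events(fx$chart_events, fx$register_events, window_days)
  list(fixture = fx, matches = m, table = tabulate_matches(m, fx$patients))
}

pct1 <- function(x) floor(x * 1000 + 0.5) / 10  # half-up percent, 1 decimal
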