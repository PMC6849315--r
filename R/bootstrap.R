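#' Bootstrap configuration
#'
#' Settings for the two-stage hospital-clustered bootstrap.
#'
#' @param n_resamples number of bootstrap replicates (default 10000).
#' @param seed integer seed for the resampling RNG (base R Mersenne-Twister),
#'   or `NULL` to continue from the current RNG state.
#' @param ci_level confidence level for the percentile interval (default 0.95).
#' @param degenerate_policy what to do with replicates on which the statistic
#'   is undefined (zero denominator): `"drop_and_count"` drops them and
#'   records how many were dropped; `"impute_point"` substitutes the full-data
#'   point estimate.
#' @param keep_replicates keep the replicate statistics (as attribute
#'   `"replicates"` of the result) for audit.
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 10000L, seed = NULL, ci_level = 0.95,
                             degenerate_policy = c("drop_and_count", "impute_point"),
                             keep_replicates = FALSE) {
  if (!is.numeric(n_resamples) || n_resamples < 1) {
    stop("n_resamples must be >= 1", call. = FALSE)
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_resamples = as.integer(n_resamples),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ci_level = ci_level,
                 degenerate_policy = match.arg(degenerate_policy),
                 keep_replicates = isTRUE(keep_replicates)),
            class = "bootstrap_config")
}

#' Assign each patient to one hospital cluster
#'
#' The bootstrap resamples hospitals, then patients within hospitals, so
#' every patient must belong to exactly one hospital even if their events
#' span several (in the source study one patient underwent surgery at two
#' hospitals). The rule: the hospital of the patient's earliest event, ties
#' broken by lexicographically smallest hospital id; patients with no events
#' fall back to the `hospital_id` column of the patient table.
#'
#' @param patients a patient-record table (see [patient_records()]).
#' @param chart_events,register_events optional event tables.
#' @return named character vector mapping `patient_id` to `hospital_id`.
#' @export
assign_clusters <- function(patients, chart_events = NULL, register_events = NULL) {
  ev <- list()
  if (!is.null(chart_events) && nrow(chart_events)) {
    ev$chart <- data.frame(patient_id = chart_events$patient_id,
                           hospital_id = chart_events$hospital_id,
                           date = chart_events$surgery_date,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(register_events) && nrow(register_events)) {
    ev$register <- data.frame(patient_id = register_events$patient_id,
                              hospital_id = register_events$hospital_id,
                              date = register_events$admission_date,
                              stringsAsFactors = FALSE)
  }
  out <- patients$hospital_id
  names(out) <- patients$patient_id
  if (length(ev)) {
    ev <- do.call(rbind, ev)
    ev <- ev[order(ev$patient_id, ev$date, ev$hospital_id), , drop = FALSE]
    first <- ev[!duplicated(ev$patient_id), , drop = FALSE]
    hit <- match(first$patient_id, names(out))
    if (anyNA(hit)) {
      stop(sprintf("events reference unknown patient_id(s): %s",
                   paste(utils::head(first$patient_id[is.na(hit)], 5L), collapse = ", ")),
           call. = FALSE)
    }
    out[hit] <- first$hospital_id
  }
  bad <- !nzchar(trimws(out)) | is.na(out)
  if (any(bad)) {
    stop(sprintf("patient(s) with no hospital: %s",
                 paste(utils::head(names(out)[bad], 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

# Draw one two-stage resample: hospitals with replacement, then, within each
# drawn hospital, that hospital's patients with replacement. `cluster_list`
# is a list of integer patient indices per hospital. A hospital drawn c times
# contributes c * n_h patient draws; duplicates are kept, never deduplicated.
# Both two_stage_resample() and the bootstrap fast path consume RNG through
# this one function, so they are replicate-for-replicate identical.
resample_indices <- function(cluster_list) {
  H <- length(cluster_list)
  hs <- sample.int(H, H, replace = TRUE)
  draws <- tabulate(hs, nbins = H)
  idx <- vector("list", H)
  for (h in which(draws > 0L)) {
    members <- cluster_list[[h]]
    n_h <- length(members)
    idx[[h]] <- members[sample.int(n_h, draws[h] * n_h, replace = TRUE)]
  }
  unlist(idx, use.names = FALSE)
}

#' Draw one two-stage clustered resample of a dataset
#'
#' Stage 1 draws H hospitals with replacement from the H observed hospital
#' clusters; stage 2 draws, for each drawn hospital, n_h patients with
#' replacement from that hospital's n_h patients. All code events of a drawn
#' patient travel with it, and repeated draws are duplicated as distinct
#' pseudo-patients (id suffixed `"*2"`, `"*3"`, ...), never deduplicated.
#'
#' @param dataset list with elements `chart_events`, `register_events`,
#'   `patients` (event tables as in [event-tables]).
#' @param clusters optional patient-to-hospital map from [assign_clusters()];
#'   computed from the dataset when missing.
#' @return a list of the same shape with resampled `patients`,
#'   `chart_events`, `register_events`.
#' @export
two_stage_resample <- function(dataset, clusters = NULL) {
  patients <- dataset$patients
  if (is.null(patients) || nrow(patients) == 0L) {
    stop("cannot resample an empty dataset", call. = FALSE)
  }
  if (is.null(clusters)) {
    clusters <- assign_clusters(patients, dataset$chart_events, dataset$register_events)
  }
  cl <- split(seq_len(nrow(patients)), clusters[patients$patient_id])
  idx <- resample_indices(cl)
  new_pat <- patients[idx, , drop = FALSE]
  copy <- stats::ave(seq_along(idx), patients$patient_id[idx], FUN = seq_along)
  new_id <- ifelse(copy == 1L, patients$patient_id[idx],
                   paste0(patients$patient_id[idx], "*", copy))
  take_events <- function(events) {
    if (is.null(events) || nrow(events) == 0L) return(events)
    pieces <- lapply(seq_along(idx), function(k) {
      e <- events[events$patient_id == patients$patient_id[idx[k]], , drop = FALSE]
      if (nrow(e)) e$patient_id <- new_id[k]
      e
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  }
  out <- dataset
  out$patients <- new_pat
  out$patients$patient_id <- new_id
  rownames(out$patients) <- NULL
  out$chart_events <- take_events(dataset$chart_events)
  out$register_events <- take_events(dataset$register_events)
  out
}

# statistic name -> function of the patient_counts column sums
stat_from_sums <- function(statistic) {
  switch(statistic,
         ppv_true_positive = function(s) if (s[[3L]] > 0) s[[4L]] / s[[3L]] else NA_real_,
         ppv_concordant    = function(s) if (s[[1L]] > 0) s[[4L]] / s[[1L]] else NA_real_,
         sensitivity       = function(s) if (s[[2L]] > 0) s[[3L]] / s[[2L]] else NA_real_,
         specificity       = function(s) if (s[[5L]] > 0) s[[6L]] / s[[5L]] else NA_real_,
         stop(sprintf("unsupported bootstrap statistic: %s", statistic), call. = FALSE))
}

point_estimator <- function(statistic) {
  switch(statistic,
         ppv_true_positive = ppv_true_positive,
         ppv_concordant = ppv_concordant,
         sensitivity = sensitivity,
         specificity = specificity)
}

#' Two-stage clustered bootstrap percentile confidence interval
#'
#' Computes an accuracy statistic on the full data, then on `n_resamples`
#' two-stage hospital-clustered resamples, and returns the percentile interval
#' of the replicate values. Because matching is strictly within-patient and a
#' resample carries each drawn patient's events intact, a replicate's
#' validation table is the column sum of the drawn patients' count
#' contributions; the matcher therefore runs once, not per replicate.
#'
#' Replicates on which the statistic is undefined (a resample can have zero
#' register codes, say) are handled per `degenerate_policy`. The result is
#' bit-for-bit reproducible for a fixed `seed`.
#'
#' @param matches a `match_results` data frame from [match_events()].
#' @param patients a patient-record table.
#' @param statistic `"ppv_true_positive"`, `"ppv_concordant"`,
#'   `"sensitivity"` or `"specificity"`.
#' @param config a [bootstrap_config()].
#' @param clusters optional patient-to-hospital map from [assign_clusters()];
#'   derived from the match results (earliest event's hospital, patient-table
#'   fallback) when missing.
#' @return an [accuracy_estimate()] with `ci_low`/`ci_high` and resampling
#'   metadata filled in.
#' @export
bootstrap_ci <- function(matches, patients, statistic, config = bootstrap_config(),
                         clusters = NULL) {
  stopifnot(inherits(config, "bootstrap_config"))
  counts <- patient_counts(matches, patients)
  analysed <- patients[match(rownames(counts), patients$patient_id), , drop = FALSE]
  if (is.null(clusters)) clusters <- clusters_from_matches(matches, analysed)
  clusters <- clusters[rownames(counts)]
  if (anyNA(clusters)) stop("cluster map does not cover all analysed patients", call. = FALSE)
  cl <- split(seq_len(nrow(counts)), clusters)
  if (!length(cl)) stop("cannot bootstrap an empty dataset", call. = FALSE)

  statfun <- stat_from_sums(statistic)
  full <- point_estimator(statistic)(counts_to_table(counts))
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$n_resamples
  reps <- numeric(B)
  for (b in seq_len(B)) {
    idx <- resample_indices(cl)
    reps[b] <- statfun(.colSums(counts[idx, , drop = FALSE], length(idx), ncol(counts)))
  }
  n_degenerate <- sum(is.na(reps))
  if (n_degenerate == B) stop("all bootstrap replicates degenerate", call. = FALSE)
  if (n_degenerate > 0L) {
    if (config$degenerate_policy == "drop_and_count") {
      reps_used <- reps[!is.na(reps)]
    } else {
      reps_used <- ifelse(is.na(reps), full$point, reps)
    }
  } else {
    reps_used <- reps
  }
  alpha <- (1 - config$ci_level) / 2
  ci <- stats::quantile(reps_used, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- accuracy_estimate(statistic, full$numerator, full$denominator,
                           ci_low = ci[1L], ci_high = ci[2L],
                           n_resamples = B, n_degenerate = n_degenerate,
                           seed = if (is.null(config$seed)) NA_integer_ else config$seed,
                           stratum = full$stratum)
  if (config$keep_replicates) attr(out, "replicates") <- reps
  out
}

# Cluster map from match results: earliest event's hospital per patient,
# patient-table hospital_id as fallback for event-less (negative) patients.
clusters_from_matches <- function(matches, patients) {
  matches <- matches[matches$patient_id %in% patients$patient_id, , drop = FALSE]
  date <- matches$surgery_date
  date[is.na(date)] <- matches$admission_date[is.na(date)]
  ev <- data.frame(patient_id = matches$patient_id,
                   hospital_id = matches$hospital_id,
                   surgery_date = date, stringsAsFactors = FALSE)
  assign_clusters(patients, chart_events = ev)
}
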