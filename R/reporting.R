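#' Compute the full set of accuracy estimates for a validated dataset
#'
#' Runs the estimator battery on matched data: the four overall statistics,
#' PPV (concordant) and sensitivity per anatomic and era stratum, conditioned
#' NPVs, and scenario bounds for unverifiable codes. Bootstrap percentile CIs
#' are attached to the overall and stratified statistics when a
#' [bootstrap_config()] is supplied; the conditioned NPVs and scenario bounds
#' are reported as point values.
#'
#' The NPV conditioning counts are taken from the data: `npv_missing_patients`
#' conditions on every patient with at least one register-missed chart code
#' as a false negative; `npv_register_silent` conditions only on those of
#' them with no register code at all.
#'
#' @param matches a `match_results` data frame from [match_events()].
#' @param patients a patient-record table.
#' @param codelist a [codelist()] for anatomic stratification.
#' @param chart_events optional chart event table; enables the
#'   unverifiable-code scenario bounds (codes flagged `verifiable = FALSE`).
#' @param boot a [bootstrap_config()], or `NULL` to skip CIs.
#' @param strata stratification axes to include.
#' @return data frame with columns `statistic`, `stratum_axis`,
#'   `stratum_value`, `numerator`, `denominator`, `point`, `ci_low`,
#'   `ci_high`, `n_resamples`, `seed`.
#' @export
compute_estimates <- function(matches, patients, codelist = NULL,
                              chart_events = NULL, boot = NULL,
                              strata = c("anatomic", "era")) {
  tab <- tabulate_matches(matches, patients)
  clusters <- clusters_from_matches(
    matches, patients[patients$chart_available & !patients$excluded_insufficient, ,
                      drop = FALSE])
  rows <- list()
  add <- function(est, axis = "none", value = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = est$statistic, stratum_axis = axis, stratum_value = value,
      numerator = est$numerator, denominator = est$denominator,
      point = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
      n_resamples = est$n_resamples, seed = est$seed, stringsAsFactors = FALSE)
  }
  est_one <- function(m, statistic) {
    if (is.null(boot)) {
      point_estimator(statistic)(tabulate_matches(m, patients))
    } else {
      bootstrap_ci(m, patients, statistic, boot, clusters = clusters)
    }
  }
  for (s in c("ppv_true_positive", "ppv_concordant", "sensitivity", "specificity")) {
    add(est_one(matches, s))
  }
  for (axis in strata) {
    if (axis == "anatomic" && is.null(codelist)) next
    stratum <- stratum_of(matches, axis, codelist)
    for (lev in levels(stratum)) {
      sub <- matches[!is.na(stratum) & stratum == lev, , drop = FALSE]
      for (s in c("ppv_concordant", "sensitivity")) {
        add(est_one(sub, s), axis = axis, value = lev)
      }
    }
  }
  k_all <- npv_missing_patients(matches, patients)
  k_strict <- npv_register_silent(matches, patients)
  add(npv_conditioned(tab, k_all), axis = "npv_condition", value = "all_missing")
  add(npv_conditioned(tab, k_strict), axis = "npv_condition", value = "register_silent")
  if (!is.null(chart_events)) {
    k <- n_unverifiable_codes(chart_events)
    for (s in c("ppv_true_positive", "ppv_concordant", "sensitivity")) {
      b <- scenario_bounds(tab, k, s)
      add(b$lower, axis = "scenario", value = "lower")
      add(b$upper, axis = "scenario", value = "upper")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# stratum assignment per match row (factor; shared by stratify_matches and
# the stratified bootstrap)
stratum_of <- function(matches, axis, codelist = NULL) {
  if (axis == "anatomic") {
    if (is.null(codelist)) stop("anatomic stratification needs a codelist", call. = FALSE)
    code <- ifelse(is.na(matches$chart_code), matches$register_code,
                   matches$chart_code)
    res <- lookup_code(code, codelist)
    if (anyNA(res$category)) {
      bad <- unique(res$code[is.na(res$category)])
      stop(sprintf("anatomic category unresolvable for code(s): %s",
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    factor(res$category, levels = c("abdominal", "perianal", "other"))
  } else {
    date <- matches$admission_date
    date[is.na(date)] <- matches$surgery_date[is.na(date)]
    year <- as.integer(format(date, "%Y"))
    factor(ifelse(year <= 1996L, "pre1997", "post1997"),
           levels = c("pre1997", "post1997"))
  }
}

# analysed patients with >= 1 register-missed chart code
npv_missing_patients <- function(matches, patients) {
  analysed <- patients$patient_id[patients$chart_available &
                                    !patients$excluded_insufficient]
  m <- matches[matches$patient_id %in% analysed, , drop = FALSE]
  length(unique(m$patient_id[m$verdict == "chart_only"]))
}

# of those, patients with no register code at all
npv_register_silent <- function(matches, patients) {
  analysed <- patients$patient_id[patients$chart_available &
                                    !patients$excluded_insufficient]
  m <- matches[matches$patient_id %in% analysed, , drop = FALSE]
  missing_pat <- unique(m$patient_id[m$verdict == "chart_only"])
  has_reg <- unique(m$patient_id[m$verdict %in%
                                   c("concordant", "transfer_error", "register_only")])
  length(setdiff(missing_pat, has_reg))
}

fmt_est <- function(row) {
  if (is.na(row$point)) return("undefined")
  ci <- if (!is.na(row$ci_low)) {
    sprintf(" (%s-%s)", format_pct(row$ci_low), format_pct(row$ci_high))
  } else ""
  sprintf("%s%s %d/%d", format_pct(row$point), ci, row$numerator, row$denominator)
}

pick_est <- function(est, statistic, axis = "none", value = NA_character_) {
  sel <- est$statistic == statistic & est$stratum_axis == axis &
    (if (is.na(value)) TRUE else est$stratum_value == value)
  est[which(sel)[1L], , drop = FALSE]
}

#' Render the overall validation table
#'
#' A text rendering in the layout of a validation-study cross-tabulation:
#' code counts by source, patient-level negatives, and the four overall
#' accuracy statistics formatted `point (ci_low-ci_high) num/den`. Every
#' number comes from the supplied validation table and estimates frame;
#' nothing is recomputed.
#'
#' @param table a [validation_table()].
#' @param estimates the frame from [compute_estimates()].
#' @param n_register_silent count for the "patients with no register code"
#'   line (see [compute_estimates()]).
#' @return character vector of report lines.
#' @export
render_table2 <- function(table, estimates, n_register_silent = NA_integer_) {
  c("Register vs chart review, IBD-related surgical procedure codes",
    "",
    sprintf("  Chart positive: code in both sources (concordant)  %d (%d)",
            table$n_both, table$n_concordant),
    sprintf("  Chart positive: code missing in register           %d",
            table$n_chart_only),
    sprintf("  Chart positive: patients with no register code     %s",
            ifelse(is.na(n_register_silent), "-", n_register_silent)),
    sprintf("  Chart negative: register code present              %d",
            table$n_register_only),
    sprintf("  Chart negative: no register code                   %d",
            table$n_true_negative),
    "",
    sprintf("  PPV (true positives)   %s",
            fmt_est(pick_est(estimates, "ppv_true_positive"))),
    sprintf("  PPV (concordant codes) %s",
            fmt_est(pick_est(estimates, "ppv_concordant"))),
    sprintf("  Sensitivity            %s",
            fmt_est(pick_est(estimates, "sensitivity"))),
    sprintf("  Specificity            %s",
            fmt_est(pick_est(estimates, "specificity"))))
}

#' Render the stratified validation table
#'
#' Code counts and PPV/sensitivity per anatomic category and coding era,
#' one column per stratum plus the pooled total, in the layout of the
#' source study's stratified table.
#'
#' @param matches a `match_results` data frame.
#' @param patients a patient-record table.
#' @param codelist a [codelist()].
#' @param estimates the frame from [compute_estimates()].
#' @return a data frame, one column per stratum.
#' @export
render_table3 <- function(matches, patients, codelist, estimates) {
  strat <- c(stratify_matches(matches, patients, "anatomic", codelist),
             stratify_matches(matches, patients, "era"))
  total <- tabulate_matches(matches, patients)
  cols <- c(names(strat), "total")
  tabs <- c(strat, list(total = total))
  axis_of <- c(abdominal = "anatomic", perianal = "anatomic", other = "anatomic",
               pre1997 = "era", post1997 = "era")
  cell <- function(f) vapply(tabs, f, character(1L))
  stat_row <- function(statistic) {
    vapply(cols, function(v) {
      if (v == "total") return(fmt_est(pick_est(estimates, statistic)))
      fmt_est(pick_est(estimates, statistic, axis_of[[v]], v))
    }, character(1L))
  }
  out <- rbind(
    code_in_chart              = cell(function(t) as.character(t$n_chart)),
    chart_only                 = cell(function(t) as.character(t$n_chart_only)),
    code_in_register           = cell(function(t) as.character(t$n_register)),
    register_only              = cell(function(t) as.character(t$n_register_only)),
    code_in_both               = cell(function(t) as.character(t$n_both)),
    concordant                 = cell(function(t) as.character(t$n_concordant)),
    discordant                 = cell(function(t) as.character(t$n_both - t$n_concordant)),
    ppv_concordant             = stat_row("ppv_concordant"),
    sensitivity                = stat_row("sensitivity"))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Export match results to CSV
#'
#' @param matches a `match_results` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  cols <- c("patient_id", "hospital_id", "chart_code", "register_code",
            "surgery_date", "admission_date", "verdict", "error_type",
            "error_subtype", "delay_days")
  utils::write.csv(matches[intersect(cols, names(matches))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, command, config, inputs = character(),
                           seed = NA_integer_) {
  digests <- if (length(inputs)) {
    as.list(unname(tools::md5sum(inputs)))
  } else list()
  names(digests) <- basename(inputs)
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("regval")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   config = config,
                   input_md5 = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Run the full validation pipeline on event files
#'
#' Reads register events, chart events, patient records and a code list,
#' matches and tabulates them, computes all accuracy estimates (with
#' two-stage hospital-clustered bootstrap CIs unless `bootstrap = FALSE`),
#' and writes to `out_dir`: `matches.csv`, `estimates.csv`, rendered
#' `table_overall.txt` and `table_stratified.txt`, and a `manifest.json`
#' capturing the configuration, seed, package version and input file digests.
#'
#' @param register_path,chart_path,patients_path CSV inputs (see
#'   [event-tables]).
#' @param codelist_path code-list TSV (see [load_codelist()]), or `NULL` for
#'   [default_codelist()].
#' @param out_dir output directory, created if needed.
#' @param window_days matching window in days.
#' @param bootstrap compute bootstrap CIs.
#' @param n_resamples,seed,ci_level bootstrap settings.
#' @param strata stratification axes.
#' @param quiet suppress progress messages (written to `stderr`).
#' @return invisibly, a list with `table`, `estimates`, `matches`,
#'   `delay` (a [delay_summary()]) and the output paths.
#' @export
run_validation <- function(register_path, chart_path, patients_path,
                           codelist_path = NULL, out_dir = ".",
                           window_days = 7, bootstrap = TRUE,
                           n_resamples = 10000L, seed = 1L, ci_level = 0.95,
                           strata = c("anatomic", "era"), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  register <- read_events(register_path, "register")
  chart <- read_events(chart_path, "chart")
  patients <- read_patients(patients_path)
  cl <- if (is.null(codelist_path)) default_codelist() else load_codelist(codelist_path)
  say(sprintf("read %d register codes, %d chart codes, %d patients",
              nrow(register), nrow(chart), nrow(patients)))

  matches <- match_events(chart, register, window_days)
  tab <- tabulate_matches(matches, patients)
  boot <- if (bootstrap) {
    bootstrap_config(n_resamples = n_resamples, seed = seed)
  } else NULL
  say(sprintf("matched: %d paired (%d concordant), %d chart-only, %d register-only",
              tab$n_both, tab$n_concordant, tab$n_chart_only, tab$n_register_only))
  est <- compute_estimates(matches, patients, codelist = cl, chart_events = chart,
                           boot = boot, strata = strata)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(matches = file.path(out_dir, "matches.csv"),
                estimates = file.path(out_dir, "estimates.csv"),
                table_overall = file.path(out_dir, "table_overall.txt"),
                table_stratified = file.path(out_dir, "table_stratified.txt"))
  write_matches(matches, paths$matches)
  utils::write.csv(est, paths$estimates, row.names = FALSE, quote = FALSE)
  writeLines(render_table2(tab, est, npv_register_silent(matches, patients)),
             paths$table_overall)
  t3 <- render_table3(matches, patients, cl, est)
  writeLines(c(paste(c("", colnames(t3)), collapse = "\t"),
               paste(rownames(t3), apply(t3, 1L, paste, collapse = "\t"),
                     sep = "\t")),
             paths$table_stratified)
  write_manifest(out_dir, "validate",
                 config = list(window_days = window_days, bootstrap = bootstrap,
                               n_resamples = if (bootstrap) n_resamples else 0L,
                               ci_level = ci_level, strata = strata),
                 inputs = c(register_path, chart_path, patients_path,
                            if (!is.null(codelist_path)) codelist_path),
                 seed = seed)
  say(sprintf("wrote results to %s", out_dir))
  invisible(list(table = tab, estimates = est, matches = matches,
                 delay = delay_summary(matches), paths = paths))
}

#' Simulate a dataset and write it as event files
#'
#' Writes `register.csv`, `chart.csv`, `patients.csv`, `codelist.tsv`,
#' ground-truth sidecars `ground_truth_chart.csv` /
#' `ground_truth_register.csv`, and a `manifest.json` recording the
#' configuration and seed, all conforming to the schemas read by
#' [run_validation()].
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, the simulated dataset (see [simulate_dataset()]) plus
#'   output paths.
#' @export
run_simulation <- function(config, out_dir = ".", quiet = FALSE) {
  ds <- simulate_dataset(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(register = file.path(out_dir, "register.csv"),
                chart = file.path(out_dir, "chart.csv"),
                patients = file.path(out_dir, "patients.csv"),
                codelist = file.path(out_dir, "codelist.tsv"),
                gt_chart = file.path(out_dir, "ground_truth_chart.csv"),
                gt_register = file.path(out_dir, "ground_truth_register.csv"))
  write_events(ds$register_events, paths$register)
  write_events(ds$chart_events, paths$chart)
  write_patients(ds$patients, paths$patients)
  write_codelist(ds$codelist, paths$codelist)
  utils::write.csv(ds$ground_truth$register, paths$gt_register, row.names = FALSE)
  utils::write.csv(ds$ground_truth$chart, paths$gt_chart, row.names = FALSE)
  write_manifest(out_dir, "simulate",
                 config = unclass(config)[setdiff(names(unclass(config)), "seed")],
                 seed = config$seed)
  if (!quiet) {
    message(sprintf("simulated %d patients (%d surgical), %d chart / %d register codes -> %s",
                    nrow(ds$patients), sum(ds$patients$chart_has_ibd_surgery),
                    nrow(ds$chart_events), nrow(ds$register_events), out_dir))
  }
  invisible(c(ds, list(paths = paths)))
}
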