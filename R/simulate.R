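#' Simulation configuration
#'
#' Parameters of the synthetic register/chart generator. Defaults emulate the
#' source validation study's published structure: 258 analysed patients in 27
#' hospitals, a 20% surgery prevalence, a zero-truncated (shifted negative
#' binomial) number of codes per surgical patient with mean 3.1 / SD 4.5,
#' anatomic category weights 67:40:57 (abdominal:perianal:other), a pre-1997
#' coding-era share of 85/164, a geometric admission-to-surgery delay with
#' median 1 and mean 2.1 days, and per-code error rates echoing the observed
#' error counts: omission 9/164, transposition transfer 2/155, spurious
#' register codes 3/258 per patient.
#'
#' @param n_patients number of patients (>= 1).
#' @param n_hospitals number of hospital clusters.
#' @param surgery_prevalence probability a patient's chart documents IBD
#'   surgery.
#' @param codes_mean,codes_sd target mean and SD of chart codes per surgical
#'   patient, matched exactly by a shifted negative binomial
#'   (`1 + NB`; requires `codes_sd^2 > codes_mean - 1`).
#' @param category_weights unnormalized weights over abdominal, perianal,
#'   other.
#' @param p_miss probability a chart code is omitted from the register.
#' @param p_transfer probability a chart code is registered with two adjacent
#'   characters transposed. `p_miss + p_transfer` must not exceed 1; the
#'   remaining mass is copied exactly.
#' @param p_spurious expected number (Poisson mean) of register codes with no
#'   chart counterpart, per patient.
#' @param delay_mean mean of the geometric admission-to-surgery delay in days
#'   (median 1 at the default 2.1).
#' @param delay_cap optional hard cap on the delay, in days; `NULL` leaves the
#'   geometric tail uncapped (the study condition). A finite cap at or below
#'   the matching window makes pipeline verdicts agree exactly with ground
#'   truth and is used by recovery tests.
#' @param era_split probability a surgical session falls in the pre-1997
#'   coding era.
#' @param session_split probability an additional code opens a new surgical
#'   session; the default 0.43 targets the published mean of 1.9 sessions per
#'   surgical patient given 3.1 codes.
#' @param hospital_dispersion gamma shape for hospital-size weights; values
#'   below 1 give the strong skew the published per-hospital SD implies.
#' @param vocab_size synthetic procedure codes per (era, category).
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 258L, n_hospitals = 27L,
                              surgery_prevalence = 0.20,
                              codes_mean = 3.1, codes_sd = 4.5,
                              category_weights = c(abdominal = 67, perianal = 40,
                                                   other = 57),
                              p_miss = 9 / 164, p_transfer = 2 / 155,
                              p_spurious = 3 / 258,
                              delay_mean = 2.1, delay_cap = NULL,
                              era_split = 85 / 164, session_split = 0.43,
                              hospital_dispersion = 0.5,
                              vocab_size = 12L, seed = 1L) {
  probs <- c(surgery_prevalence, p_miss, p_transfer, era_split, session_split)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_miss + p_transfer > 1) {
    stop("p_miss + p_transfer must not exceed 1 (mutually exclusive code fates)",
         call. = FALSE)
  }
  if (p_spurious < 0) stop("p_spurious must be non-negative", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (n_hospitals < 1) stop("n_hospitals must be >= 1", call. = FALSE)
  if (codes_mean <= 1 || codes_sd <= 0) {
    stop("codes_mean must exceed 1 and codes_sd must be positive", call. = FALSE)
  }
  shifted_nb_params(codes_mean, codes_sd)  # validates moment feasibility
  if (delay_mean <= 0) stop("delay_mean must be positive", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_hospitals = as.integer(n_hospitals),
                 surgery_prevalence = surgery_prevalence,
                 codes_mean = codes_mean, codes_sd = codes_sd,
                 category_weights = category_weights / sum(category_weights),
                 p_miss = p_miss, p_transfer = p_transfer,
                 p_spurious = p_spurious,
                 delay_mean = delay_mean, delay_cap = delay_cap,
                 era_split = era_split, session_split = session_split,
                 hospital_dispersion = hospital_dispersion,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Codes per surgical patient: 1 + NB(size, mu), a zero-truncated count family
# that hits mean/SD targets exactly. (A zero-truncated NB cannot: at mean 3.1
# its SD is bounded near 3.5 by the logarithmic-series limit, below the
# published 4.5.) Moment match: mu = mean - 1, size = mu^2 / (sd^2 - mu).
shifted_nb_params <- function(mean_target, sd_target) {
  mu <- mean_target - 1
  v <- sd_target^2
  if (v <= mu) {
    stop("codes_sd too small: need sd^2 > codes_mean - 1 for the shifted NB",
         call. = FALSE)
  }
  list(size = mu^2 / (v - mu), mu = mu)
}

rcodes_per_patient <- function(n, size, mu) {
  if (n == 0L) return(integer())
  pmin(1L + stats::rnbinom(n, size = size, mu = mu), 100L)
}

# synthetic vocabularies; built so an adjacent transposition of characters
# 2 and 3 never reproduces a vocabulary code (3rd character avoids the
# category characters and differs from the 2nd)
make_vocab <- function(vocab_size) {
  pre_d3 <- c(0L, 1L, 2L, 3L, 4L, 5L, 8L)
  pre <- function(p2) sprintf("4%d%d%d", p2,
                              pre_d3[((seq_len(vocab_size) - 1L) %% 7L) + 1L],
                              (seq_len(vocab_size) - 1L) %/% 7L)
  post_l3 <- setdiff(LETTERS, c("F", "G", "H", "J"))
  post <- function(l2) sprintf("J%s%s%02d", l2,
                               post_l3[((seq_len(vocab_size) - 1L) %% length(post_l3)) + 1L],
                               seq_len(vocab_size))
  list(pre1997  = list(abdominal = pre(6L), perianal = pre(9L), other = pre(7L)),
       post1997 = list(abdominal = post("F"), perianal = post("H"),
                       other = post("G")))
}

vocab_codelist <- function(vocab) {
  pats <- character(); cats <- character()
  for (era in names(vocab)) {
    for (cat in names(vocab[[era]])) {
      pats <- c(pats, vocab[[era]][[cat]])
      cats <- c(cats, rep(cat, length(vocab[[era]][[cat]])))
    }
  }
  keep <- !duplicated(pats)
  codelist(pats[keep], cats[keep])
}

era_grid <- function(era) {
  if (era == "pre1997") {
    seq(as.Date("1970-01-15"), as.Date("1996-06-30"), by = 60L)
  } else {
    seq(as.Date("1997-02-15"), as.Date("2014-10-31"), by = 60L)
  }
}

#' Simulate a register/chart dataset with injected coding errors
#'
#' Generates patients clustered in hospitals, surgical sessions with chart
#' codes, and the register's rendering of them: each chart code is
#' independently omitted (probability `p_miss`), transposed (two adjacent
#' characters swapped, `p_transfer`) or copied exactly; spurious register
#' codes with no chart counterpart are added per patient at Poisson rate
#' `p_spurious`. Codes of one surgical session share a surgery date and a
#' register admission date `delay` days earlier; sessions of one patient are
#' at least 60 days apart so a 7-day matching window never couples distinct
#' sessions. Ground-truth labels are retained for every event.
#'
#' @param config a [simulation_config()].
#' @param seed optional seed overriding `config$seed` (used by replicate
#'   harnesses).
#' @return list with `chart_events`, `register_events`, `patients`,
#'   `codelist`, `ground_truth` (list of `chart` and `register` label tables)
#'   and `config`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_patients
  H <- config$n_hospitals
  vocab <- make_vocab(config$vocab_size)

  hosp_w <- stats::rgamma(H, shape = config$hospital_dispersion) + 1e-9
  hospital <- sprintf("H%03d", sample.int(H, n, replace = TRUE,
                                          prob = hosp_w / sum(hosp_w)))
  pid <- sprintf("P%05d", seq_len(n))
  surgical <- stats::runif(n) < config$surgery_prevalence

  idx_s <- which(surgical)
  zt <- shifted_nb_params(config$codes_mean, config$codes_sd)
  n_codes <- rcodes_per_patient(length(idx_s), zt$size, zt$mu)

  chart <- chart_events(study_window = NULL)
  register <- register_events(study_window = NULL)
  gt_chart <- data.frame(event_id = integer(), patient_id = character(),
                         code = character(), fate = character(),
                         stringsAsFactors = FALSE)
  gt_register <- data.frame(event_id = integer(), patient_id = character(),
                            code = character(), fate = character(),
                            stringsAsFactors = FALSE)

  if (length(idx_s)) {
    n_sessions <- 1L + stats::rbinom(length(idx_s), pmax(n_codes - 1L, 0L),
                                     config$session_split)
    # one surgical session = one admission; codes beyond the first n_sessions
    # are spread uniformly over the patient's sessions
    total_codes <- sum(n_codes)
    code_pat <- rep(seq_along(idx_s), n_codes)           # surgical-patient index
    within <- sequence(n_codes)
    extra_sess <- floor(stats::runif(total_codes) * rep(n_sessions, n_codes)) + 1L
    code_sess <- ifelse(within <= rep(n_sessions, n_codes), within, extra_sess)

    total_sess <- sum(n_sessions)
    sess_pat <- rep(seq_along(idx_s), n_sessions)
    sess_gid_offset <- cumsum(n_sessions) - n_sessions
    code_gid <- sess_gid_offset[code_pat] + code_sess

    sess_era <- ifelse(stats::runif(total_sess) < config$era_split,
                       "pre1997", "post1997")
    # non-overlapping session slots: consecutive grid slots per (patient, era)
    # starting at a random per-group offset
    grp <- paste(sess_pat, sess_era)
    rank_in_grp <- stats::ave(seq_len(total_sess), grp, FUN = seq_along)
    size_of_grp <- stats::ave(seq_len(total_sess), grp, FUN = length)
    grids <- list(pre1997 = era_grid("pre1997"), post1997 = era_grid("post1997"))
    g_len <- vapply(grids, length, integer(1L))[sess_era]
    off_draw <- floor(stats::runif(total_sess) * (g_len - size_of_grp)) + 1L
    first <- rank_in_grp == 1L
    offset <- off_draw[first][match(grp, grp[first])]
    slot <- offset + rank_in_grp - 1L
    sess_date <- as.Date(ifelse(sess_era == "pre1997",
                                as.character(grids$pre1997[slot]),
                                as.character(grids$post1997[slot])))
    p_geom <- 1 / (config$delay_mean + 1)
    sess_delay <- stats::rgeom(total_sess, p_geom)
    if (!is.null(config$delay_cap)) sess_delay <- pmin(sess_delay, config$delay_cap)

    code_cat <- c("abdominal", "perianal", "other")[
      sample.int(3L, total_codes, replace = TRUE, prob = config$category_weights)]
    code_era <- sess_era[code_gid]
    code_text <- character(total_codes)
    for (era in c("pre1997", "post1997")) {
      for (cat in c("abdominal", "perianal", "other")) {
        g <- which(code_era == era & code_cat == cat)
        if (length(g)) {
          code_text[g] <- vocab[[era]][[cat]][
            sample.int(config$vocab_size, length(g), replace = TRUE)]
        }
      }
    }

    u <- stats::runif(total_codes)
    fate <- ifelse(u < config$p_miss, "missed",
                   ifelse(u < config$p_miss + config$p_transfer,
                          "transfer", "exact"))
    code_pid <- pid[idx_s][code_pat]
    code_hosp <- hospital[idx_s][code_pat]
    code_date <- sess_date[code_gid]
    code_adm <- code_date - sess_delay[code_gid]

    chart <- chart_events(code_pid, code_hosp, code_date, code_text,
                          note_source = "surgical_note", verifiable = TRUE,
                          study_window = NULL)
    gt_chart <- data.frame(event_id = seq_len(total_codes), patient_id = code_pid,
                           code = code_text,
                           fate = ifelse(fate == "missed", "missed", "captured"),
                           stringsAsFactors = FALSE)

    keep <- fate != "missed"
    reg_text <- ifelse(fate == "transfer", swap23(code_text), code_text)[keep]
    register <- register_events(code_pid[keep], code_hosp[keep],
                                code_adm[keep], reg_text, study_window = NULL)
    gt_register <- data.frame(
      event_id = seq_len(sum(keep)), patient_id = code_pid[keep],
      code = reg_text,
      fate = ifelse(fate[keep] == "transfer", "transfer", "true_concordant"),
      stringsAsFactors = FALSE)
  }

  # spurious register codes: no chart counterpart, any patient
  n_spur <- stats::rpois(n, config$p_spurious)
  if (sum(n_spur)) {
    sp_pat <- rep(seq_len(n), n_spur)
    m <- length(sp_pat)
    sp_era <- ifelse(stats::runif(m) < config$era_split, "pre1997", "post1997")
    sp_cat <- c("abdominal", "perianal", "other")[
      sample.int(3L, m, replace = TRUE, prob = config$category_weights)]
    sp_code <- character(m)
    for (era in c("pre1997", "post1997")) {
      for (cat in c("abdominal", "perianal", "other")) {
        g <- which(sp_era == era & sp_cat == cat)
        if (length(g)) {
          sp_code[g] <- vocab[[era]][[cat]][
            sample.int(config$vocab_size, length(g), replace = TRUE)]
        }
      }
    }
    grids <- list(pre1997 = era_grid("pre1997"), post1997 = era_grid("post1997"))
    sp_slot <- floor(stats::runif(m) * vapply(grids, length, integer(1L))[sp_era]) + 1L
    sp_date <- as.Date(ifelse(sp_era == "pre1997",
                              as.character(grids$pre1997[sp_slot]),
                              as.character(grids$post1997[sp_slot])))
    sp_reg <- register_events(pid[sp_pat], hospital[sp_pat], sp_date, sp_code,
                              study_window = NULL)
    first_id <- nrow(register)
    register <- rbind(register, sp_reg)
    gt_register <- rbind(gt_register,
                         data.frame(event_id = first_id + seq_len(m),
                                    patient_id = pid[sp_pat], code = sp_code,
                                    fate = "spurious", stringsAsFactors = FALSE))
  }

  patients <- patient_records(pid, hospital, chart_available = TRUE,
                              chart_has_ibd_surgery = surgical,
                              excluded_insufficient = FALSE)
  list(chart_events = chart, register_events = register, patients = patients,
       codelist = vocab_codelist(vocab),
       ground_truth = list(chart = gt_chart, register = gt_register),
       config = config)
}

#' Descriptive structure of a dataset
#'
#' Cohort-level descriptives in the style of a validation-study "basic
#' characteristics" table: patients, hospitals, surgical patients, codes per
#' source, paired (validated) codes, codes per surgical patient and per
#' hospital, surgical sessions per surgical patient.
#'
#' @param dataset list with `chart_events`, `register_events`, `patients`
#'   (from [simulate_dataset()] or [build_fixture()]).
#' @param window_days matching window used to count paired codes.
#' @return one-row data frame of descriptives.
#' @export
summarize_structure <- function(dataset, window_days = 7) {
  ch <- dataset$chart_events; rg <- dataset$register_events
  pats <- dataset$patients
  n_pat <- nrow(pats)
  if (n_pat == 0L && nrow(ch) == 0L && nrow(rg) == 0L) {
    return(data.frame(n_patients = 0L, n_hospitals = 0L, n_surgical_patients = 0L,
                      n_chart_codes = 0L, n_register_codes = 0L, n_codes_validated = 0L,
                      mean_codes_per_patient = 0, sd_codes_per_patient = 0,
                      mean_codes_per_hospital = 0, sd_codes_per_hospital = 0,
                      mean_sessions_per_patient = 0))
  }
  surg <- pats$patient_id[pats$chart_has_ibd_surgery & !pats$excluded_insufficient]
  cpp <- as.vector(table(factor(ch$patient_id, levels = surg)))
  hosp_levels <- sort(unique(c(pats$hospital_id, ch$hospital_id, rg$hospital_id)))
  cph <- as.vector(table(factor(ch$hospital_id, levels = hosp_levels)))
  sess <- if (nrow(ch)) {
    tapply(ch$surgery_date, factor(ch$patient_id, levels = surg),
           function(d) length(unique(d)))
  } else numeric()
  sess[is.na(sess)] <- 0
  n_both <- if (nrow(ch) && nrow(rg)) {
    m <- match_events(ch, rg, window_days)
    tabulate_matches(m, pats)$n_both
  } else 0L
  data.frame(n_patients = n_pat,
             n_hospitals = length(hosp_levels),
             n_surgical_patients = length(surg),
             n_chart_codes = nrow(ch),
             n_register_codes = nrow(rg),
             n_codes_validated = n_both,
             mean_codes_per_patient = if (length(cpp)) mean(cpp) else 0,
             sd_codes_per_patient = if (length(cpp) > 1L) stats::sd(cpp) else 0,
             mean_codes_per_hospital = if (length(cph)) mean(cph) else 0,
             sd_codes_per_hospital = if (length(cph) > 1L) stats::sd(cph) else 0,
             mean_sessions_per_patient = if (length(sess)) mean(sess) else 0)
}

# analytic statistic values implied by the error rates (used by recovery_report)
true_statistic_values <- function(config) {
  sens <- 1 - config$p_miss
  ppv_tp <- (1 - config$p_miss - config$p_transfer) / (1 - config$p_miss)
  spec <- exp(-config$p_spurious)
  mu_codes <- config$surgery_prevalence * config$codes_mean
  ppv_conc <- (mu_codes * (1 - config$p_miss - config$p_transfer)) /
    (mu_codes * (1 - config$p_miss) + config$p_spurious)
  c(ppv_true_positive = ppv_tp, ppv_concordant = ppv_conc,
    sensitivity = sens, specificity = spec)
}

#' Estimator-recovery report over simulated replicates
#'
#' Runs the full pipeline (simulate, match, tabulate, estimate, bootstrap)
#' on `n_reps` independent replicates of a configuration and compares the
#' estimates with the analytic values the configured error rates imply:
#' sensitivity `1 - p_miss`, PPV of validated codes
#' `(1 - p_miss - p_transfer) / (1 - p_miss)`, patient-level specificity
#' `exp(-p_spurious)`, and the ratio-of-expectations PPV over all register
#' codes. Coverage is the fraction of replicate CIs containing the true value.
#'
#' Delays beyond the matching window register as misses, so recovery against
#' the analytic values is exact only when `config$delay_cap` is at or below
#' `window_days`; otherwise the geometric tail contributes a small calibrated
#' downward bias to sensitivity.
#'
#' @param config a [simulation_config()]; replicate r runs with seed
#'   `config$seed + r`.
#' @param n_reps number of replicates (>= 2).
#' @param window_days matching window passed to [match_events()].
#' @param n_resamples bootstrap replicates per CI; 0 skips CIs (coverage `NA`).
#' @param ci_level bootstrap confidence level.
#' @return data frame with one row per statistic: `statistic`, `true_value`,
#'   `mean_estimate`, `bias`, `rmse`, `ci_coverage`.
#' @export
recovery_report <- function(config, n_reps, window_days = 7,
                            n_resamples = 500L, ci_level = 0.95) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  stats_names <- c("ppv_true_positive", "ppv_concordant", "sensitivity",
                   "specificity")
  truth <- true_statistic_values(config)
  est <- matrix(NA_real_, n_reps, length(stats_names),
                dimnames = list(NULL, stats_names))
  cover <- matrix(NA, n_reps, length(stats_names),
                  dimnames = list(NULL, stats_names))
  for (r in seq_len(n_reps)) {
    ds <- simulate_dataset(config, seed = config$seed + r)
    m <- match_events(ds$chart_events, ds$register_events, window_days)
    tab <- tabulate_matches(m, ds$patients)
    for (s in stats_names) {
      if (n_resamples > 0L) {
        e <- bootstrap_ci(m, ds$patients, s,
                          bootstrap_config(n_resamples = n_resamples,
                                           seed = config$seed + r,
                                           ci_level = ci_level))
        cover[r, s] <- !is.na(e$ci_low) &&
          e$ci_low <= truth[[s]] && truth[[s]] <= e$ci_high
      } else {
        e <- point_estimator(s)(tab)
      }
      est[r, s] <- e$point
    }
  }
  data.frame(statistic = stats_names,
             true_value = unname(truth[stats_names]),
             mean_estimate = colMeans(est, na.rm = TRUE),
             bias = colMeans(est, na.rm = TRUE) - unname(truth[stats_names]),
             rmse = sqrt(colMeans((est - rep(truth[stats_names],
                                             each = n_reps))^2, na.rm = TRUE)),
             ci_coverage = if (n_resamples > 0L) colMeans(cover, na.rm = TRUE)
                           else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}
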