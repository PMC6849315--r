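#' Counts configuration for the reconstructed validation fixture
#'
#' The source validation study published its full cross-tabulation (overall
#' and stratified by anatomic category and coding era) but not the raw data.
#' A counts configuration specifies, per (category, era) cell, how many code
#' occurrences were present in both sources (`n_both`), concordant among those
#' (`n_concordant`), chart-only (`n_chart_only`) and register-only
#' (`n_register_only`), plus the patient-level structure. [build_fixture()]
#' turns it into an exact synthetic dataset whose tabulation reproduces every
#' configured cell.
#'
#' The default is the published study: 53 surgical patients with 164 chart /
#' 158 register codes (155 paired, 153 concordant), 205 chart-negative
#' patients of whom 3 carry one spurious register code each, 4 patients
#' excluded for insufficient surgical notes (one unverifiable code each),
#' 27 hospitals. The joint (category, era) allocation satisfies all printed
#' row and column marginals.
#'
#' @param cells data frame with columns `category`, `era`, `n_both`,
#'   `n_concordant`, `n_chart_only`, `n_register_only`.
#' @param n_surgical_patients patients whose charts document IBD surgery and
#'   were validated.
#' @param n_negative_patients chart-negative patients.
#' @param n_true_negative chart-negative patients with no register code; the
#'   remainder each carry at least one register-only code.
#' @param n_excluded_patients patients excluded for insufficient notes; each
#'   contributes one unverifiable code present in both sources.
#' @param n_missing_patients surgical patients carrying the chart-only
#'   (register-missed) codes; clamped to the number of chart-only codes.
#' @param n_all_missing_patients how many of those carry no register code at
#'   all (both false negative and register-silent); the rest also receive
#'   paired codes.
#' @param n_hospitals hospitals to spread patients over (round-robin).
#' @return an object of class `fixture_counts`.
#' @export
fixture_counts <- function(cells = default_fixture_cells(),
                           n_surgical_patients = 53L,
                           n_negative_patients = 205L,
                           n_true_negative = 202L,
                           n_excluded_patients = 4L,
                           n_missing_patients = 4L,
                           n_all_missing_patients = 2L,
                           n_hospitals = 27L) {
  n_chart_only <- sum(cells$n_chart_only)
  n_missing_patients <- min(as.integer(n_missing_patients), n_chart_only,
                            as.integer(n_surgical_patients))
  n_all_missing_patients <- min(as.integer(n_all_missing_patients),
                                n_missing_patients)
  x <- structure(list(cells = cells,
                      n_surgical_patients = as.integer(n_surgical_patients),
                      n_negative_patients = as.integer(n_negative_patients),
                      n_true_negative = as.integer(n_true_negative),
                      n_excluded_patients = as.integer(n_excluded_patients),
                      n_missing_patients = n_missing_patients,
                      n_all_missing_patients = n_all_missing_patients,
                      n_hospitals = as.integer(n_hospitals)),
                 class = "fixture_counts")
  validate_fixture_counts(x)
  x
}

# Joint (category, era) cell allocation consistent with every printed
# marginal: category totals both 65/36/54 and concordant 64/36/53;
# era totals both 77/78 and concordant 76/77; chart-only 2/4/3 by category
# and 8/1 by era; register-only 3/0/0 by category and 1/2 by era.
default_fixture_cells <- function() {
  data.frame(
    category        = rep(c("abdominal", "perianal", "other"), each = 2L),
    era             = rep(c("pre1997", "post1997"), times = 3L),
    n_both          = c(30L, 35L, 20L, 16L, 27L, 27L),
    n_concordant    = c(30L, 34L, 20L, 16L, 26L, 27L),
    n_chart_only    = c(2L, 0L, 4L, 0L, 2L, 1L),
    n_register_only = c(1L, 2L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

validate_fixture_counts <- function(x) {
  cells <- x$cells
  need <- c("category", "era", "n_both", "n_concordant", "n_chart_only",
            "n_register_only")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop(sprintf("fixture cells missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  num <- as.matrix(cells[c("n_both", "n_concordant", "n_chart_only", "n_register_only")])
  if (any(num < 0)) stop("fixture cell counts must be non-negative", call. = FALSE)
  if (any(cells$n_concordant > cells$n_both)) {
    stop("inconsistent marginals: n_concordant exceeds n_both in some cell",
         call. = FALSE)
  }
  if (!all(cells$category %in% c("abdominal", "perianal", "other")) ||
      !all(cells$era %in% c("pre1997", "post1997"))) {
    stop("fixture cells have unknown category or era levels", call. = FALSE)
  }
  if (x$n_true_negative > x$n_negative_patients) {
    stop("n_true_negative cannot exceed n_negative_patients", call. = FALSE)
  }
  n_fp <- x$n_negative_patients - x$n_true_negative
  n_ro <- sum(cells$n_register_only)
  if (n_fp > n_ro) {
    stop("inconsistent marginals: more false-positive patients than register-only codes",
         call. = FALSE)
  }
  if (n_ro > 0L && n_fp == 0L) {
    stop("register-only codes configured but no false-positive patients to carry them",
         call. = FALSE)
  }
  if (sum(cells$n_chart_only) > 0L && x$n_missing_patients < 1L) {
    stop("chart-only codes configured but n_missing_patients is 0", call. = FALSE)
  }
  n_chart_codes <- sum(cells$n_both) + sum(cells$n_chart_only)
  if (n_chart_codes > 0L && x$n_surgical_patients < 1L) {
    stop("chart codes configured but no surgical patients to carry them", call. = FALSE)
  }
  if (sum(cells$n_both) > 0L &&
      x$n_surgical_patients - x$n_all_missing_patients < 1L) {
    stop("paired codes configured but every surgical patient is all-missing",
         call. = FALSE)
  }
  n_pat <- x$n_surgical_patients + x$n_negative_patients + x$n_excluded_patients
  if (n_pat > 0L && x$n_hospitals < 1L) {
    stop("patients configured but n_hospitals < 1", call. = FALSE)
  }
  if (x$n_surgical_patients > 0L &&
      ceiling(n_chart_codes / x$n_surgical_patients) > 80L) {
    stop("too many codes per patient to fit inside one coding era", call. = FALSE)
  }
  invisible(x)
}

# synthetic code vocabularies: 4-digit tokens for the pre-1997 numeric system,
# letter-letter-letter-digit-digit NOMESCO-style tokens for 1997+
fixture_pools <- function() {
  list(
    concordant = list(
      pre1997  = list(abdominal = c("4601", "4612", "4621", "4633", "4644",
                                    "4655", "4666", "4677"),
                      perianal  = c("4901", "4912", "4923", "4934", "4945", "4956"),
                      other     = c("4701", "4712", "4723", "4734", "4745",
                                    "4756", "4767")),
      post1997 = list(abdominal = c("JFB10", "JFB21", "JFB32", "JFB43", "JFB54",
                                    "JFH20", "JFG10", "JFC20"),
                      perianal  = c("JHA10", "JHA21", "JHA32", "JHA43", "JHB10",
                                    "JHB21"),
                      other     = c("JGB10", "JGB21", "JGB32", "JGB43", "JGC10",
                                    "JGC21"))),
    chart_only = list(
      pre1997  = list(abdominal = c("4642", "4611", "4690"),
                      perianal  = c("4999", "4958", "4967", "4976"),
                      other     = c("4781", "4792", "4770")),
      post1997 = list(abdominal = c("JFK10", "JFK21"),
                      perianal  = c("JHC10", "JHC21"),
                      other     = c("JGB99", "JGD10", "JGD21"))),
    transfer = list(
      pre1997  = list(abdominal = c("4685", "4657"),
                      perianal  = c("4958", "4967"),
                      other     = c("4705", "4716")),
      post1997 = list(abdominal = c("JFB20", "JFC31"),
                      perianal  = c("JHA20", "JHB31"),
                      other     = c("JGB20", "JGC31"))))
}

# adjacent transposition of characters 2 and 3, the hand-copy slip the
# source study observed (JFB-- registered as JBF--)
swap23 <- function(code) {
  s <- strsplit(code, "", fixed = TRUE)
  vapply(s, function(ch) paste(c(ch[1L], ch[3L], ch[2L], ch[-(1:3)]), collapse = ""),
         character(1L))
}

cycle <- function(pool, n) if (n == 0L) character() else pool[((seq_len(n) - 1L) %% length(pool)) + 1L]

era_base <- function(era) {
  as.Date(ifelse(era == "pre1997", "1988-01-10", "2005-03-05"))
}

#' Build the reconstructed validation dataset from a counts configuration
#'
#' Emits a synthetic-but-exact dataset — chart events, register events,
#' patient records and a matching code list — whose matched tabulation
#' reproduces every configured cell of the counts configuration. Code
#' occurrences are packed round-robin onto the configured surgical patients,
#' occasions within a patient are spaced 40 days apart (so a 7-day matching
#' window never couples distinct occasions), paired register admissions
#' precede surgery by one day, and patients are spread round-robin over the
#' configured hospitals. One surgical patient's later occasions are placed at
#' a second hospital, mirroring the one patient of the source study operated
#' at two hospitals. The builder is deterministic; `shuffle_seed` only
#' permutes output row order (the tabulation is order-invariant).
#'
#' @param counts a [fixture_counts()] configuration.
#' @param shuffle_seed optional integer; permute event row order reproducibly.
#' @return list with `chart_events`, `register_events`, `patients`,
#'   `codelist`.
#' @export
build_fixture <- function(counts = fixture_counts(), shuffle_seed = NULL) {
  validate_fixture_counts(counts)
  pools <- fixture_pools()
  n_s <- counts$n_surgical_patients
  n_n <- counts$n_negative_patients
  n_x <- counts$n_excluded_patients
  n_fp <- n_n - counts$n_true_negative
  n_pat <- n_s + n_n + n_x

  hospitals <- sprintf("H%03d", seq_len(max(counts$n_hospitals, 1L)))
  pid <- c(if (n_s) sprintf("S%03d", seq_len(n_s)),
           if (n_n) sprintf("N%03d", seq_len(n_n)),
           if (n_x) sprintf("X%03d", seq_len(n_x)))
  phosp <- cycle(hospitals, n_pat)
  patients <- patient_records(
    patient_id = pid, hospital_id = phosp,
    chart_available = TRUE,
    chart_has_ibd_surgery = c(rep(TRUE, n_s), rep(FALSE, n_n), rep(TRUE, n_x)),
    excluded_insufficient = c(rep(FALSE, n_s + n_n), rep(TRUE, n_x)))

  # expand the cells into one row per chart-bearing code occurrence
  occ <- do.call(rbind, lapply(seq_len(nrow(counts$cells)), function(i) {
    cl <- counts$cells[i, ]
    n_tr <- cl$n_both - cl$n_concordant
    kind <- c(rep("concordant", cl$n_concordant), rep("transfer", n_tr),
              rep("chart_only", cl$n_chart_only))
    if (!length(kind)) return(NULL)
    data.frame(category = cl$category, era = cl$era, kind = kind,
               stringsAsFactors = FALSE)
  }))
  chart <- chart_events(study_window = NULL)
  register <- register_events(study_window = NULL)
  used_codes <- character()

  if (!is.null(occ) && nrow(occ)) {
    # per-(category, era, kind) code assignment from the pools
    occ$code <- NA_character_
    for (g in split(seq_len(nrow(occ)), occ[c("kind", "era", "category")], drop = TRUE)) {
      o <- occ[g[1L], ]
      pool <- pools[[o$kind]][[o$era]][[o$category]]
      occ$code[g] <- cycle(pool, length(g))
    }
    # packing: paired codes round-robin over the surgical patients that have
    # register codes; chart-only (register-missed) codes onto the designated
    # missing-code patients, the last n_all_missing of whom get nothing else
    occ$patient_id <- NA_character_
    paired_idx <- which(occ$kind != "chart_only")
    co_idx <- which(occ$kind == "chart_only")
    n_paired_pat <- n_s - counts$n_all_missing_patients
    if (length(paired_idx)) {
      occ$patient_id[paired_idx] <-
        pid[((seq_along(paired_idx) - 1L) %% n_paired_pat) + 1L]
    }
    if (length(co_idx)) {
      n_miss <- counts$n_missing_patients
      miss_ids <- pid[n_s - n_miss + seq_len(n_miss)]
      occ$patient_id[co_idx] <- miss_ids[((seq_along(co_idx) - 1L) %% n_miss) + 1L]
    }
    key <- paste(occ$patient_id, occ$era)
    slot <- stats::ave(rep(1L, nrow(occ)), key, FUN = seq_along)
    occ$surgery_date <- era_base(occ$era) + 40L * (slot - 1L)
    occ$hospital_id <- phosp[match(occ$patient_id, pid)]
    # one patient operated at two hospitals: later occasions move next door
    two <- occ$patient_id == pid[1L] & slot > 1L
    if (any(two) && length(hospitals) > 1L) occ$hospital_id[two] <- hospitals[2L]

    chart <- chart_events(occ$patient_id, occ$hospital_id, occ$surgery_date,
                          occ$code, note_source = "surgical_note",
                          verifiable = TRUE, study_window = NULL)
    paired <- occ[occ$kind != "chart_only", , drop = FALSE]
    if (nrow(paired)) {
      reg_code <- ifelse(paired$kind == "transfer", swap23(paired$code), paired$code)
      register <- register_events(paired$patient_id, paired$hospital_id,
                                  paired$surgery_date - 1L, reg_code,
                                  study_window = NULL)
    }
    used_codes <- unique(occ$code)
  }

  # register-only (spurious) codes on the false-positive negative patients
  ro <- counts$cells[counts$cells$n_register_only > 0L, , drop = FALSE]
  if (nrow(ro)) {
    rocc <- do.call(rbind, lapply(seq_len(nrow(ro)), function(i) {
      data.frame(category = ro$category[i], era = ro$era[i],
                 seq = seq_len(ro$n_register_only[i]), stringsAsFactors = FALSE)
    }))
    fp_ids <- pid[n_s + seq_len(n_fp)]
    rocc$patient_id <- fp_ids[((seq_len(nrow(rocc)) - 1L) %% n_fp) + 1L]
    rocc$code <- NA_character_
    for (g in split(seq_len(nrow(rocc)), rocc[c("era", "category")], drop = TRUE)) {
      o <- rocc[g[1L], ]
      # draw spurious codes from the concordant pools, cycled from the tail
      pool <- rev(pools$concordant[[o$era]][[o$category]])
      rocc$code[g] <- cycle(pool, length(g))
    }
    key <- paste(rocc$patient_id, rocc$era)
    slot <- stats::ave(rep(1L, nrow(rocc)), key, FUN = seq_along)
    ro_reg <- register_events(rocc$patient_id,
                              phosp[match(rocc$patient_id, pid)],
                              era_base(rocc$era) + 40L * (slot - 1L),
                              rocc$code, study_window = NULL)
    register <- rbind(register, ro_reg)
    used_codes <- unique(c(used_codes, rocc$code))
  }

  # excluded patients: one unverifiable code each, present in both sources
  if (n_x > 0L) {
    x_ids <- pid[n_s + n_n + seq_len(n_x)]
    x_code <- cycle(pools$chart_only$post1997$abdominal, n_x)
    x_date <- as.Date("2006-06-01") + 40L * (seq_len(n_x) - 1L)
    x_hosp <- phosp[match(x_ids, pid)]
    chart <- rbind(chart,
                   chart_events(x_ids, x_hosp, x_date, x_code,
                                note_source = "other_note", verifiable = FALSE,
                                study_window = NULL))
    register <- rbind(register,
                      register_events(x_ids, x_hosp, x_date - 1L, x_code,
                                      study_window = NULL))
    used_codes <- unique(c(used_codes, x_code))
  }

  # code list covering every chart-side and register-only code
  cl_entries <- do.call(rbind, lapply(c("concordant", "chart_only", "transfer"),
    function(kind) {
      do.call(rbind, lapply(c("pre1997", "post1997"), function(era) {
        p <- pools[[kind]][[era]]
        data.frame(pattern = unlist(p[c("abdominal", "perianal", "other")],
                                    use.names = FALSE),
                   category = rep(c("abdominal", "perianal", "other"),
                                  times = lengths(p[c("abdominal", "perianal", "other")])),
                   stringsAsFactors = FALSE)
      }))
    }))
  cl_entries <- cl_entries[!duplicated(cl_entries$pattern), , drop = FALSE]
  cl <- codelist(cl_entries$pattern, cl_entries$category)

  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    chart <- chart[sample.int(nrow(chart)), , drop = FALSE]
    register <- register[sample.int(nrow(register)), , drop = FALSE]
    rownames(chart) <- rownames(register) <- NULL
  }
  list(chart_events = chart, register_events = register,
       patients = patients, codelist = cl)
}
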