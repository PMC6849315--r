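test_that("patients are clustered at their earliest event's hospital", {
  pats <- patient_records(c("P1", "P2", "P3"), c("HZ", "HZ", "H3"))
  ch <- chart_events(c("P1", "P1"), c("H2", "H1"),
                     as.Date(c("1995-06-01", "1990-06-01")), c("A1", "B2"),
                     study_window = NULL)
  rg <- register_events("P2", "H5", as.Date("1992-01-01"), "C3",
                        study_window = NULL)
  cl <- assign_clusters(pats, ch, rg)
  expect_identical(cl[["P1"]], "H1")  # earliest event wins
  expect_identical(cl[["P2"]], "H5")
  expect_identical(cl[["P3"]], "H3")  # no events: patient-table fallback
  # same-date tie at two hospitals: lexicographically smallest
  ch2 <- chart_events(c("P1", "P1"), c("H9", "H2"),
                      as.Date(c("1990-06-01", "1990-06-01")), c("A1", "B2"),
                      study_window = NULL)
  expect_identical(assign_clusters(pats, ch2)[["P1"]], "H2")
  # permuting event rows never changes the assignment
  expect_identical(assign_clusters(pats, ch2[2:1, ])[["P1"]], "H2")
  expect_error(assign_clusters(patient_records("P4", "")), "no hospital")
})

test_that("a single-hospital single-patient dataset resamples to itself", {
  ds <- list(chart_events = mk_chart(c(1, 5), c("A1", "B2")),
             register_events = mk_register(c(0, 4), c("A1", "B2")),
             patients = mk_patients("P1"))
  set.seed(1)
  rs <- two_stage_resample(ds)
  expect_equal(rs$patients, ds$patients)
  expect_equal(rs$chart_events, ds$chart_events)
  expect_equal(rs$register_events, ds$register_events)
  expect_error(two_stage_resample(list(patients = mk_patients(character()))),
               "empty")
})

test_that("stage-1 hospital multisets are equiprobable (2 hospitals x 1 patient)", {
  ds <- list(chart_events = rbind(mk_chart(1, "A1", pid = "PA", hosp = "HA"),
                                  mk_chart(1, "B2", pid = "PB", hosp = "HB")),
             register_events = mk_register(numeric(), character())[0, ],
             patients = patient_records(c("PA", "PB"), c("HA", "HB"),
                                        chart_has_ibd_surgery = TRUE))
  clusters <- assign_clusters(ds$patients, ds$chart_events)
  set.seed(42)
  B <- 4000L
  kinds <- vapply(seq_len(B), function(b) {
    rs <- two_stage_resample(ds, clusters)
    a <- sum(startsWith(rs$patients$patient_id, "PA"))
    sprintf("%dA%dB", a, 2L - a)
  }, character(1L))
  freq <- table(factor(kinds, levels = c("2A0B", "1A1B", "0A2B"))) / B
  # enumeration oracle: {AA}, {AB}, {BA}, {BB} equiprobable at stage 1,
  # so P(2A) = P(2B) = 1/4 and P(1A1B) = 1/2; 4000 draws, ~3.5 SE tolerance
  expect_equal(unname(freq[["2A0B"]]), 0.25, tolerance = 0.10)
  expect_equal(unname(freq[["0A2B"]]), 0.25, tolerance = 0.10)
  expect_equal(unname(freq[["1A1B"]]), 0.50, tolerance = 0.06)
})

test_that("each drawn hospital contributes exactly its patient count", {
  set.seed(9)
  n_h <- c(HA = 2L, HB = 3L, HC = 1L)
  pats <- patient_records(sprintf("P%d", 1:6),
                          rep(names(n_h), times = n_h))
  ds <- list(chart_events = mk_chart(numeric(), character())[0, ],
             register_events = mk_register(numeric(), character())[0, ],
             patients = pats)
  for (i in 1:20) {
    rs <- two_stage_resample(ds)
    orig <- sub("[*].*$", "", rs$patients$patient_id)
    drawn_per_hosp <- table(pats$hospital_id[match(orig, pats$patient_id)])
    for (h in names(drawn_per_hosp)) {
      # c_h draws of hospital h contribute c_h * n_h patients
      expect_equal(unname(drawn_per_hosp[[h]]) %% n_h[[h]], 0)
    }
    expect_equal(nrow(rs$patients),
                 sum(vapply(names(drawn_per_hosp),
                            function(h) drawn_per_hosp[[h]], integer(1L))))
  }
})

test_that("the count fast path reproduces the materialized resample", {
  fx <- build_fixture()
  m <- match_events(fx$chart_events, fx$register_events, 7)
  counts <- regval:::patient_counts(m, fx$patients)
  analysed <- fx$patients[fx$patients$chart_available &
                            !fx$patients$excluded_insufficient, ]
  clusters <- regval:::clusters_from_matches(m, analysed)
  ds <- list(chart_events = fx$chart_events[
               fx$chart_events$patient_id %in% analysed$patient_id, ],
             register_events = fx$register_events[
               fx$register_events$patient_id %in% analysed$patient_id, ],
             patients = analysed)
  for (seed in c(11, 23)) {
    set.seed(seed)
    rs <- two_stage_resample(ds, clusters)
    tab_material <- tabulate_matches(
      match_events(rs$chart_events, rs$register_events, 7), rs$patients)
    set.seed(seed)
    idx <- regval:::resample_indices(
      split(seq_len(nrow(counts)), clusters[rownames(counts)]))
    tab_fast <- regval:::counts_to_table(counts[idx, , drop = FALSE])
    expect_identical(unclass(tab_fast), unclass(tab_material))
  }
})

test_that("bootstrap CIs are bit-identical under a fixed seed", {
  pp <- paper_pipeline()
  cfg <- bootstrap_config(n_resamples = 2000, seed = 7)
  e1 <- bootstrap_ci(pp$matches, pp$fixture$patients, "sensitivity", cfg)
  e2 <- bootstrap_ci(pp$matches, pp$fixture$patients, "sensitivity", cfg)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(e1$ci_low <= e1$point && e1$point <= e1$ci_high)
  expect_true(e1$ci_low >= 0 && e1$ci_high <= 1)
  # a different seed gives a different interval
  e3 <- bootstrap_ci(pp$matches, pp$fixture$patients, "sensitivity",
                     bootstrap_config(n_resamples = 2000, seed = 8))
  expect_false(identical(c(e1$ci_low, e1$ci_high), c(e3$ci_low, e3$ci_high)))
})

test_that("an all-concordant stratum yields the degenerate interval [1, 1]", {
  ch <- mk_chart(c(1, 30, 61), c("A1", "B2", "C3"))
  rg <- mk_register(c(0, 29, 60), c("A1", "B2", "C3"))
  m <- match_events(ch, rg, 7)
  e <- bootstrap_ci(m, mk_patients("P1"), "ppv_true_positive",
                    bootstrap_config(n_resamples = 500, seed = 3))
  expect_equal(e$point, 1)
  expect_equal(e$ci_low, 1)
  expect_equal(e$ci_high, 1)
})

test_that("degenerate replicates follow the configured policy", {
  # hospital HA: one concordant pair; hospital HB: a chart-only patient.
  # the {HB, HB} resample has zero register codes -> ppv_concordant undefined
  ch <- rbind(mk_chart(1, "A1", pid = "PA", hosp = "HA"),
              mk_chart(1, "B2", pid = "PB", hosp = "HB"))
  rg <- mk_register(0, "A1", pid = "PA", hosp = "HA")
  m <- match_events(ch, rg, 7)
  pats <- patient_records(c("PA", "PB"), c("HA", "HB"),
                          chart_has_ibd_surgery = TRUE)
  e_drop <- bootstrap_ci(m, pats, "ppv_concordant",
                         bootstrap_config(n_resamples = 400, seed = 5,
                                          degenerate_policy = "drop_and_count"))
  expect_gt(e_drop$n_degenerate, 0L)
  expect_lt(e_drop$n_degenerate, 400L)
  e_imp <- bootstrap_ci(m, pats, "ppv_concordant",
                        bootstrap_config(n_resamples = 400, seed = 5,
                                         degenerate_policy = "impute_point"))
  expect_equal(e_imp$n_degenerate, e_drop$n_degenerate)
  # all replicates degenerate -> estimation error
  m_only <- match_events(mk_chart(1, "B2"), mk_register(numeric(), character()))
  expect_error(bootstrap_ci(m_only, mk_patients("P1"), "ppv_concordant",
                            bootstrap_config(n_resamples = 50, seed = 1)),
               "degenerate")
})

test_that("CI width shrinks in expectation as hospitals grow", {
  widths <- vapply(c(5L, 30L, 100L), function(H) {
    cfg <- simulation_config(n_patients = H * 10L, n_hospitals = H,
                             delay_cap = 7, seed = 60 + H)
    ds <- simulate_dataset(cfg)
    m <- match_events(ds$chart_events, ds$register_events, 7)
    e <- bootstrap_ci(m, ds$patients, "sensitivity",
                      bootstrap_config(n_resamples = 500, seed = 2))
    e$ci_high - e$ci_low
  }, numeric(1L))
  expect_gt(widths[1L], widths[2L])
  expect_gt(widths[2L], widths[3L])
})
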