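test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(p_miss = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(p_miss = 0.6, p_transfer = 0.6),
               "mutually exclusive")
  expect_error(simulation_config(codes_mean = 0.5), "codes_mean")
  expect_error(simulation_config(codes_mean = 3.1, codes_sd = 1.2), "codes_sd")
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  cfg <- simulation_config(n_patients = 120, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$chart_events, d2$chart_events)
  expect_identical(d1$register_events, d2$register_events)
  expect_identical(d1$patients, d2$patients)
  d3 <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(d1$chart_events, d3$chart_events))
})

test_that("a zero-error configuration gives all statistics exactly 1", {
  cfg <- simulation_config(p_miss = 0, p_transfer = 0, p_spurious = 0,
                           delay_cap = 7, seed = 13)
  ds <- simulate_dataset(cfg)
  m <- match_events(ds$chart_events, ds$register_events, 7)
  tab <- tabulate_matches(m, ds$patients)
  expect_equal(ppv_true_positive(tab)$point, 1)
  expect_equal(ppv_concordant(tab)$point, 1)
  expect_equal(sensitivity(tab)$point, 1)
  expect_equal(specificity(tab)$point, 1)
})

test_that("pipeline verdicts agree with ground truth when delays fit the window", {
  cfg <- simulation_config(n_patients = 800, p_spurious = 0, delay_cap = 7,
                           seed = 17)
  ds <- simulate_dataset(cfg)
  m <- match_events(ds$chart_events, ds$register_events, 7)
  tab <- tabulate_matches(m, ds$patients)
  gt <- ds$ground_truth
  expect_equal(tab$n_chart, nrow(gt$chart))
  expect_equal(tab$n_chart_only, sum(gt$chart$fate == "missed"))
  expect_equal(tab$n_both, sum(gt$chart$fate == "captured"))
  expect_equal(tab$n_concordant, sum(gt$register$fate == "true_concordant"))
  expect_equal(tab$n_both - tab$n_concordant,
               sum(gt$register$fate == "transfer"))
  expect_equal(tab$n_register_only, sum(gt$register$fate == "spurious"))
})

test_that("transposed register codes are adjacent-swap transfer errors", {
  cfg <- simulation_config(n_patients = 2000, p_miss = 0, p_transfer = 0.3,
                           p_spurious = 0, delay_cap = 7, seed = 23)
  ds <- simulate_dataset(cfg)
  m <- match_events(ds$chart_events, ds$register_events, 7)
  te <- m[m$verdict == "transfer_error", ]
  expect_gt(nrow(te), 100L)
  # every injected transfer code is an adjacent swap of a listed chart code
  gt_transfer <- ds$ground_truth$register$code[
    ds$ground_truth$register$fate == "transfer"]
  back <- regval:::swap23(gt_transfer)
  expect_true(all(lookup_code(back, ds$codelist)$ibd_related))
  expect_false(any(lookup_code(gt_transfer, ds$codelist)$ibd_related))
  # pairing recovers the injected transfers one-for-one; the rare session
  # with two transfers may cross-pair them, so most but not necessarily all
  # pairs are flagged as pure transpositions
  expect_equal(nrow(te), length(gt_transfer))
  expect_gt(mean(te$error_subtype == "transposition"), 0.9)
})

test_that("injected error rates are recovered from ground-truth labels", {
  cfg <- simulation_config(n_patients = 12000, seed = 29)
  ds <- simulate_dataset(cfg)
  gt <- ds$ground_truth
  n_chart <- nrow(gt$chart)
  miss_hat <- mean(gt$chart$fate == "missed")
  se <- sqrt(cfg$p_miss * (1 - cfg$p_miss) / n_chart)
  expect_lt(abs(miss_hat - cfg$p_miss), 3 * se)
  trans_hat <- sum(gt$register$fate == "transfer") / n_chart
  se_t <- sqrt(cfg$p_transfer * (1 - cfg$p_transfer) / n_chart)
  expect_lt(abs(trans_hat - cfg$p_transfer), 3 * se_t)
  spur_hat <- sum(gt$register$fate == "spurious") / nrow(ds$patients)
  se_s <- sqrt(cfg$p_spurious / nrow(ds$patients))
  expect_lt(abs(spur_hat - cfg$p_spurious), 3 * se_s)
})

test_that("the generator reproduces the published cohort structure", {
  cfg <- simulation_config(n_patients = 8000, seed = 37)
  ds <- simulate_dataset(cfg)
  s <- summarize_structure(ds, window_days = 60)
  n_surg <- s$n_surgical_patients
  expect_lt(abs(n_surg / s$n_patients - 0.20), 3 * sqrt(0.2 * 0.8 / 8000))
  expect_lt(abs(s$mean_codes_per_patient - 3.1), 3 * 4.5 / sqrt(n_surg))
  expect_equal(s$sd_codes_per_patient, 4.5, tolerance = 0.1)
  expect_lt(abs(s$mean_sessions_per_patient - 1.9), 0.15)
  # pre-1997 era share of chart codes
  pre <- mean(format(ds$chart_events$surgery_date, "%Y") <= "1996")
  expect_equal(pre, 85 / 164, tolerance = 0.08)
})

test_that("the default study-sized configuration looks like the study", {
  ds <- simulate_dataset(simulation_config(seed = 41))
  s <- summarize_structure(ds)
  expect_equal(s$n_patients, 258L)
  expect_lte(s$n_hospitals, 27L)
  expect_gt(s$n_hospitals, 10L)
  expect_gt(s$n_surgical_patients, 20L)
  expect_lt(s$n_surgical_patients, 90L)
})

test_that("an empty dataset summarizes to all zeros", {
  empty <- list(chart_events = mk_chart(numeric(), character()),
                register_events = mk_register(numeric(), character()),
                patients = mk_patients(character()))
  s <- summarize_structure(empty)
  expect_true(all(unlist(s) == 0))
})

test_that("recovery_report is exact under a zero-error configuration", {
  cfg <- simulation_config(n_patients = 150, p_miss = 0, p_transfer = 0,
                           p_spurious = 0, delay_cap = 7, seed = 43)
  rep <- recovery_report(cfg, n_reps = 3, window_days = 7, n_resamples = 80)
  expect_equal(rep$true_value, rep(1, 4))
  expect_equal(rep$bias, rep(0, 4))
  expect_equal(rep$rmse, rep(0, 4))
  expect_equal(rep$ci_coverage, rep(1, 4))
  expect_error(recovery_report(cfg, n_reps = 1), "n_reps")
})

test_that("written simulation files re-enter the pipeline unchanged", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(n_patients = 80, delay_cap = 7, seed = 47)
  ds <- run_simulation(cfg, out, quiet = TRUE)
  reg <- read_events(file.path(out, "register.csv"), "register")
  ch <- read_events(file.path(out, "chart.csv"), "chart")
  pats <- read_patients(file.path(out, "patients.csv"))
  expect_equal(reg, ds$register_events)
  expect_equal(ch, ds$chart_events)
  expect_equal(pats, ds$patients)
  expect_true(file.exists(file.path(out, "manifest.json")))
  gt <- utils::read.csv(file.path(out, "ground_truth_register.csv"))
  expect_equal(nrow(gt), nrow(reg))
})
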