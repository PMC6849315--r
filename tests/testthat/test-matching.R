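test_that("an exact code within the window pairs as concordant with its delay", {
  m <- match_events(mk_chart(3, "JFH20"), mk_register(2, "JFH20"))
  expect_equal(nrow(m), 1L)
  expect_identical(m$verdict, "concordant")
  expect_identical(m$error_type, "none")
  expect_equal(m$delay_days, 1L)
})

test_that("same-occasion different codes pair as a transfer error", {
  m <- match_events(mk_chart(1, "JFB00"), mk_register(1, "JBF00"))
  expect_identical(m$verdict, "transfer_error")
  expect_identical(m$error_type, "transfer_error")
  expect_identical(m$error_subtype, "transposition")
  expect_equal(m$delay_days, 0L)
})

test_that("unpaired events become chart_only / register_only", {
  m <- match_events(mk_chart(0, "4999"), mk_register(numeric(), character()))
  expect_identical(m$verdict, "chart_only")
  expect_identical(m$error_type, "missing_in_register")
  m2 <- match_events(mk_chart(numeric(), character()), mk_register(0, "4999"))
  expect_identical(m2$verdict, "register_only")
  expect_identical(m2$error_type, "missing_in_chart")
  # out-of-window register event (admission after surgery, or > window before)
  m3 <- match_events(mk_chart(0, "4999"), mk_register(1, "4999"))
  expect_setequal(m3$verdict, c("chart_only", "register_only"))
  m4 <- match_events(mk_chart(10, "4999"), mk_register(0, "4999"))
  expect_setequal(m4$verdict, c("chart_only", "register_only"))
})

test_that("code comparison ignores case and trailing padding", {
  m <- match_events(mk_chart(1, "jfb--"), mk_register(0, "JFB"))
  expect_identical(m$verdict, "concordant")
})

test_that("negative window is an argument error", {
  expect_error(match_events(mk_chart(1, "A"), mk_register(1, "A"), -1), "non-negative")
})

test_that("greedy matching attains the exhaustive maximum on small instances", {
  set.seed(202)
  codes <- c("JFH20", "4642", "JFB10")
  for (case in 1:300) {
    nc <- rint(0L, 4L); nr <- rint(0L, 4L)
    sdays <- sort(sample.int(12L, nc, replace = TRUE))
    adays <- sort(sample.int(12L, nr, replace = TRUE))
    ccode <- sample(codes, nc, replace = TRUE)
    rcode <- sample(codes, nr, replace = TRUE)
    w <- rint(0L, 8L)
    m <- match_events(mk_chart(sdays, ccode), mk_register(adays, rcode), w)
    got <- sum(m$verdict == "concordant")
    want <- max_exact_pairs_oracle(sdays, ccode, adays, rcode, w)
    expect_identical(got, want,
                     info = sprintf("case %d: s=%s c=%s a=%s r=%s w=%d",
                                    case, toString(sdays), toString(ccode),
                                    toString(adays), toString(rcode), w))
  }
})

test_that("every event lands in exactly one match result (conservation)", {
  set.seed(77)
  for (case in 1:25) {
    nc <- rint(0L, 10L); nr <- rint(0L, 10L)
    ch <- mk_chart(sample.int(20L, nc, TRUE),
                   sample(c("A1", "B2", "C3"), nc, TRUE),
                   pid = sample(c("P1", "P2"), nc, TRUE))
    rg <- mk_register(sample.int(20L, nr, TRUE),
                      sample(c("A1", "B2", "C3"), nr, TRUE),
                      pid = sample(c("P1", "P2"), nr, TRUE))
    m <- match_events(ch, rg, 7)
    paired <- sum(m$verdict %in% c("concordant", "transfer_error"))
    expect_equal(paired + sum(m$verdict == "chart_only"), nc)
    expect_equal(paired + sum(m$verdict == "register_only"), nr)
    tab <- tabulate_matches(m, mk_patients(c("P1", "P2")))
    expect_equal(tab$n_register, nr)
    expect_equal(tab$n_chart, nc)
  }
})

test_that("permuting input row order never changes the tabulation", {
  set.seed(99)
  fx <- build_fixture()
  base <- tabulate_matches(match_events(fx$chart_events, fx$register_events, 7),
                           fx$patients)
  for (s in 1:3) {
    sh <- build_fixture(shuffle_seed = s)
    tab <- tabulate_matches(match_events(sh$chart_events, sh$register_events, 7),
                            sh$patients)
    expect_identical(unclass(tab), unclass(base))
  }
})

test_that("duplicate identical codes pair one-to-one, never one-to-many", {
  m <- match_events(mk_chart(c(1, 1), c("4642", "4642")), mk_register(1, "4642"))
  expect_equal(sum(m$verdict == "concordant"), 1L)
  expect_equal(sum(m$verdict == "chart_only"), 1L)
})

test_that("transfer subtypes agree with a character-multiset oracle", {
  set.seed(5)
  pool <- c("JFB64", "JBF64", "4642", "4611", "4624", "JFH20", "JHF20")
  for (i in 1:60) {
    a <- sample(pool, 1L); b <- sample(setdiff(pool, a), 1L)
    m <- match_events(mk_chart(1, a), mk_register(1, b))
    multiset_equal <- identical(sort(strsplit(a, "")[[1L]]),
                                sort(strsplit(b, "")[[1L]]))
    expect_identical(m$error_subtype,
                     if (multiset_equal) "transposition" else "substitution")
  }
  # the named example pair: same digits, different codes -> substitution
  m <- match_events(mk_chart(1, "4642"), mk_register(1, "4611"))
  expect_identical(m$error_type, "transfer_error")
  expect_identical(m$error_subtype, "substitution")
})

test_that("delay summaries match hand computation and flag the empty case", {
  mk_delays <- function(d) {
    data.frame(patient_id = sprintf("P%d", seq_along(d)),
               surgery_date = day0 + seq_along(d),
               delay_days = d)
  }
  s <- delay_summary(mk_delays(c(1L, 1L, 1L)))
  expect_equal(s$median_days, 1)
  expect_equal(s$mean_days, 1)
  expect_equal(s$sd_days, 0)

  s2 <- delay_summary(mk_delays(c(0L, 1L, 1L, 2L, 7L)))
  expect_equal(s2$median_days, 1)
  expect_equal(s2$mean_days, 2.2)
  expect_equal(s2$proportion_within(7), 1.0)
  expect_lt(s2$proportion_within(1), 1.0)

  empty <- delay_summary(mk_delays(integer())[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median_days))
  expect_true(is.na(empty$proportion_within(7)))
})

test_that("per-patient summaries use each patient's first occasion", {
  m <- data.frame(patient_id = c("P1", "P1", "P2"),
                  surgery_date = day0 + c(5, 1, 3),
                  delay_days = c(6L, 2L, 4L))
  s <- delay_summary(m, per_patient = TRUE)
  expect_equal(s$n, 2L)
  expect_equal(s$mean_days, 3)  # first occasions: P1 day 1 (delay 2), P2 (4)
})

test_that("simulated geometric delays keep their median through the pipeline", {
  cfg <- simulation_config(n_patients = 4000, p_miss = 0, p_transfer = 0,
                           p_spurious = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  m <- match_events(ds$chart_events, ds$register_events, window_days = 60)
  s <- delay_summary(m, per_patient = FALSE)
  expect_gte(s$n, 1000L)
  expect_equal(s$median_days, 1)
  expect_equal(s$mean_days, 2.1, tolerance = 0.1)
})
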