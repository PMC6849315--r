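write_fixture_files <- function(dir, fx = build_fixture()) {
  paths <- list(register = file.path(dir, "register.csv"),
                chart = file.path(dir, "chart.csv"),
                patients = file.path(dir, "patients.csv"),
                codelist = file.path(dir, "codelist.tsv"))
  write_events(fx$register_events, paths$register)
  write_events(fx$chart_events, paths$chart)
  write_patients(fx$patients, paths$patients)
  write_codelist(fx$codelist, paths$codelist)
  paths
}

test_that("run_validation writes a complete, correct report set", {
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  out <- file.path(dir, "results")
  res <- run_validation(p$register, p$chart, p$patients, p$codelist,
                        out_dir = out, n_resamples = 300, seed = 2,
                        quiet = TRUE)
  expect_true(all(file.exists(unlist(res$paths))))
  expect_true(file.exists(file.path(out, "manifest.json")))

  overall <- readLines(res$paths$table_overall)
  expect_true(any(grepl("155 (153)", overall, fixed = TRUE)))
  expect_true(any(grepl("96.8", overall, fixed = TRUE)))

  est <- utils::read.csv(res$paths$estimates)
  pc <- est[est$statistic == "ppv_concordant" & est$stratum_axis == "none", ]
  expect_equal(pc$numerator, 153L)
  expect_equal(pc$denominator, 158L)
  expect_false(is.na(pc$ci_low))

  matches <- utils::read.csv(res$paths$matches)
  expect_equal(nrow(matches), nrow(res$matches))

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 2L)
  expect_equal(length(manifest$input_md5), 4L)
})

test_that("rendered table cells equal the estimates CSV after display rounding", {
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  res <- run_validation(p$register, p$chart, p$patients, p$codelist,
                        out_dir = file.path(dir, "r"), n_resamples = 200,
                        seed = 9, quiet = TRUE)
  est <- utils::read.csv(res$paths$estimates, stringsAsFactors = FALSE)
  t3 <- utils::read.delim(res$paths$table_stratified, check.names = FALSE,
                          row.names = 1)
  for (v in c("abdominal", "perianal", "other", "pre1997", "post1997")) {
    axis <- if (v %in% c("pre1997", "post1997")) "era" else "anatomic"
    row <- est[est$statistic == "ppv_concordant" & est$stratum_axis == axis &
                 est$stratum_value == v, ]
    want <- sprintf("%s (%s-%s) %d/%d",
                    regval:::format_pct(row$point),
                    regval:::format_pct(row$ci_low),
                    regval:::format_pct(row$ci_high),
                    row$numerator, row$denominator)
    expect_identical(t3["ppv_concordant", v], want)
  }
})

test_that("two runs with the same seed and inputs are byte-identical", {
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  r1 <- run_validation(p$register, p$chart, p$patients, p$codelist,
                       out_dir = file.path(dir, "a"), n_resamples = 200,
                       seed = 4, quiet = TRUE)
  r2 <- run_validation(p$register, p$chart, p$patients, p$codelist,
                       out_dir = file.path(dir, "b"), n_resamples = 200,
                       seed = 4, quiet = TRUE)
  for (f in c("estimates", "matches", "table_overall", "table_stratified")) {
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
  }
})

test_that("disabling the bootstrap leaves CI columns empty", {
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  res <- run_validation(p$register, p$chart, p$patients, p$codelist,
                        out_dir = file.path(dir, "nb"), bootstrap = FALSE,
                        quiet = TRUE)
  est <- utils::read.csv(res$paths$estimates)
  expect_true(all(is.na(est$ci_low)))
  expect_true(all(is.na(est$ci_high)))
  # point estimates are unaffected
  pc <- est[est$statistic == "sensitivity" & est$stratum_axis == "none", ]
  expect_equal(pc$point, 155 / 164)
})

test_that("the command-line front end runs the pipeline end to end", {
  script <- system.file("cli", "regval.R", package = "regval")
  skip_if(script == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  p <- write_fixture_files(dir)
  out <- file.path(dir, "cli_out")
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript,
                    c(script, "validate",
                      "--register", p$register, "--chart", p$chart,
                      "--patients", p$patients, "--codelist", p$codelist,
                      "--out", out, "--bootstrap-reps", "100", "--seed", "3",
                      "--quiet"),
                    stdout = FALSE, stderr = FALSE,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  skip_if(status == 127L, "Rscript not runnable here")
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "estimates.csv")))
  # invalid input exits non-zero
  status_bad <- system2(rscript, c(script, "validate", "--register", "nope.csv",
                                   "--chart", p$chart, "--patients", p$patients),
                        stdout = FALSE, stderr = FALSE,
                        env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_false(status_bad == 0L)
})
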