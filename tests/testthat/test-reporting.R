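expected_tests <- c("surrogate_dimensions", "motion_amplitude",
                    "hu_value_consistency", "projection_dimensions",
                    "spatial_resolution", "low_contrast_cnr", "noise",
                    "uniformity", "geometric_distortion", "hu_constancy",
                    "low_contrast")

qa_report_small <- function() {
  memo("qa_report_small", {
    run_qa(small_sim(), small_geometry(), trace = sinusoid_trace(10, 6))
  })
}

test_that("run_qa produces a complete report with passing spatial tests", {
  rep <- qa_report_small()
  expect_s3_class(rep, "qa_report")
  expect_setequal(rep$tests$test, expected_tests)
  expect_false(anyDuplicated(rep$tests$test) > 0)
  expect_true(all(rep$tests$status %in% c("pass", "fail", "error",
                                          "skipped")))
  spatial <- c("surrogate_dimensions", "motion_amplitude",
               "hu_value_consistency", "projection_dimensions")
  st <- rep$tests$status[match(spatial, rep$tests$test)]
  expect_equal(st, rep("pass", 4))
  expect_lte(rep$tests$value[rep$tests$test == "surrogate_dimensions"], 1)
  expect_lte(rep$tests$value[rep$tests$test == "hu_value_consistency"], 2)
  expect_equal(rep$n_bins, 10)
  expect_equal(rep$binning_mode, "phase")
})

test_that("reports serialize to JSON and CSV", {
  rep <- qa_report_small()
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json)
  report_csv(rep, csv)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(sort(parsed$tests$test), sort(rep$tests$test))
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), nrow(rep$tests))
})

test_that("a stationary-only input runs IQ tests and skips motion tests", {
  rep <- run_qa(list(stationary = small_sim()$stationary),
                small_geometry())
  motion <- c("surrogate_dimensions", "motion_amplitude",
              "hu_value_consistency", "projection_dimensions")
  expect_true(all(rep$tests$status[rep$tests$test %in% motion] == "skipped"))
  expect_true(all(rep$tests$status[rep$tests$test == "noise"] == "pass"))
  expect_setequal(rep$tests$test, expected_tests)
})

test_that("a trace-less 4D input skips amplitude and projection expectations", {
  sim <- small_sim()
  rep <- run_qa(list(stationary = sim$stationary, series = sim$series),
                small_geometry(), trace = NULL, include_iq = FALSE)
  st <- rep$tests$status
  names(st) <- rep$tests$test
  expect_equal(unname(st["motion_amplitude"]), "skipped")
  expect_equal(unname(st["projection_dimensions"]), "skipped")
  expect_equal(unname(st["surrogate_dimensions"]), "pass")
})

test_that("a corrupt bin degrades gracefully and is reported", {
  sim <- small_sim()
  bad <- sim$series$volumes
  bad[[3]]$voxels <- array(-1000, dim = dim(bad[[3]]$voxels))
  series <- phase4d_series(bad, mode = "phase")
  rep <- run_qa(list(stationary = sim$stationary, series = series),
                small_geometry(), trace = sinusoid_trace(10, 6),
                include_iq = FALSE)
  expect_equal(names(rep$bin_errors), "bin_02")
  # remaining bins still yield passing spatial tests
  expect_equal(rep$tests$status[rep$tests$test == "surrogate_dimensions"],
               "pass")
  # a stationary scan is mandatory
  expect_error(run_qa(list(series = series), small_geometry()),
               class = "qa4dct_configuration_error")
})

test_that("rerunning on identical inputs yields identical tests", {
  sim <- small_sim()
  r1 <- run_qa(sim, small_geometry(), trace = sinusoid_trace(10, 6),
               include_iq = FALSE)
  r2 <- run_qa(sim, small_geometry(), trace = sinusoid_trace(10, 6),
               include_iq = FALSE)
  expect_identical(r1$tests, r2$tests)
})

test_that("compare_to_baseline flags deltas against tolerances", {
  rep <- qa_report_small()
  self <- compare_to_baseline(rep, rep)
  expect_true(all(self$delta[!is.na(self$delta)] == 0))
  expect_true(all(self$status %in% c("pass", "skipped")))

  base <- rep
  base$tests$value[base$tests$test == "noise"] <-
    base$tests$value[base$tests$test == "noise"] - 3
  cmp <- compare_to_baseline(rep, base, tolerances = list(noise = 2))
  expect_equal(cmp$status[cmp$test == "noise"], "fail")

  base2 <- rep
  base2$tests$value[base2$tests$test == "uniformity"] <- NA
  cmp2 <- compare_to_baseline(rep, base2)
  expect_equal(cmp2$status[cmp2$test == "uniformity"], "skipped")

  base3 <- rep
  base3$tests <- base3$tests[base3$tests$test != "noise", ]
  expect_error(compare_to_baseline(rep, base3),
               class = "qa4dct_comparability_error")
})

test_that("the CLI front door validates its arguments", {
  expect_equal(qa4dct_cli(character()), 2L)
  expect_equal(suppressMessages(qa4dct_cli("frobnicate")), 2L)
  tr <- qa4dct:::parse_trace_arg("sinusoid:15:6")
  expect_equal(tr$peak_to_peak_mm, c(0, 0, 15))
  expect_equal(tr$period_s, 6)
  expect_s3_class(qa4dct:::parse_trace_arg("patient"), "motion_trace")
  expect_null(qa4dct:::parse_trace_arg("none"))
  expect_error(qa4dct:::parse_trace_arg("wobble:3"), "cannot parse")
})
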