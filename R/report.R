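#' QA tolerances
#'
#' Default tolerances seed the spatial tests at 1 mm and HU consistency at
#' 2 HU — initial values reflecting what a well-commissioned scanner
#' achieves; sites are expected to derive their own action limits from
#' longitudinal data. Optional entries in `iq_delta` bound the absolute
#' difference between the 4DCT bin-mean and the stationary value of an
#' image-quality metric; metrics without a bound are reported
#' informationally and always pass.
#'
#' @param dimension_delta_mm Bound on the mean-over-bins minus stationary
#'   plug dimension delta.
#' @param amplitude_delta_mm Bound on measured-minus-input motion amplitude.
#' @param projection_delta_mm Bound on the MIP/MinIP dimension delta.
#' @param hu_consistency_hu Bound on the per-plug bin-mean minus stationary
#'   HU delta.
#' @param iq_delta Named list of bounds for image-quality metric deltas
#'   (names from `c("geometric_distortion_mm", "mtf10_lp_per_cm",
#'   "contrast_detectability_mm", "hu_constancy_hu", "uniformity_hu",
#'   "noise_hu", "cnr_low_contrast")`).
#' @return A `tolerance_set`.
#' @export
tolerance_set <- function(dimension_delta_mm = 1.0, amplitude_delta_mm = 1.0,
                          projection_delta_mm = 1.0, hu_consistency_hu = 2.0,
                          iq_delta = list()) {
  for (v in c(dimension_delta_mm, amplitude_delta_mm, projection_delta_mm,
              hu_consistency_hu, unlist(iq_delta))) {
    check_number(v, "tolerance", min = 1e-12)
  }
  structure(list(dimension_delta_mm = dimension_delta_mm,
                 amplitude_delta_mm = amplitude_delta_mm,
                 projection_delta_mm = projection_delta_mm,
                 hu_consistency_hu = hu_consistency_hu,
                 iq_delta = iq_delta),
            class = "tolerance_set")
}

log_stage <- function(fmt, ...) {
  message(sprintf("[qa4dct %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full 4DCT QA analysis
#'
#' Orchestrates the end-to-end analysis: phantom localization on every
#' volume, surrogate plug dimension and centroid measurements per bin,
#' spatial-integrity tests against the stationary baseline, derived volumes
#' (average CT, MIP, MinIP) with the projection dimension checks, per-plug
#' HU consistency, and the image-quality suite on the stationary scan, each
#' bin, and the average CT. Individual test failures degrade to per-test
#' `"error"` status; tests whose inputs are absent (no 4D series, no trace)
#' are `"skipped"`. A stationary series is required as the baseline.
#'
#' @param input Either a directory readable by [read_series_tree()] or a
#'   list with elements `stationary` ([ct_volume()]) and optionally `series`
#'   ([phase4d_series()]), e.g. a [simulate_4dct()] result.
#' @param geom The [phantom_geometry()].
#' @param trace The input motion trace (needed for amplitude and projection
#'   expectations); `NULL` skips those tests.
#' @param tolerances A [tolerance_set()].
#' @param include_iq Run the image-quality suite (default TRUE; skipping it
#'   saves time when only spatial integrity is of interest).
#' @return A `qa_report` (see [write_report()]); component `tests` is the
#'   per-test data frame with columns `test`, `value`, `tolerance`,
#'   `status`.
#' @export
run_qa <- function(input, geom, trace = NULL, tolerances = tolerance_set(),
                   include_iq = TRUE) {
  if (is.character(input)) input <- read_series_tree(input)
  stationary <- input$stationary
  series <- input$series
  if (is.null(stationary)) {
    stopf("no stationary series found: a stationary baseline is required",
          class = "qa4dct_configuration_error")
  }
  tests <- list()
  add_test <- function(name, value, tolerance, status) {
    tests[[name]] <<- data.frame(test = name,
                                 value = as.numeric(value %||% NA),
                                 tolerance = as.numeric(tolerance %||% NA),
                                 status = status)
  }
  guard <- function(name, tolerance, expr) {
    tryCatch(expr, error = function(e) {
      add_test(name, NA, tolerance, "error")
      log_stage("%s: error: %s", name, conditionMessage(e))
      NULL
    })
  }
  report <- list(version = as.character(utils::packageVersion("qa4dct")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 model = geom$model,
                 binning_mode = if (!is.null(series)) series$mode else NA,
                 n_bins = if (!is.null(series)) series$n_bins else 0L,
                 tolerances = unclass(tolerances))

  log_stage("locating phantom in stationary volume")
  pose_stat <- locate_phantom(stationary, geom)
  surrogates <- find_plug(geom, role = "motion_surrogate")
  sens_plugs <- geometry_module(geom, "sensitometry")$plugs
  sens_plugs <- lapply(sens_plugs, function(p) find_plug(geom, p$id))

  stat_dims <- lapply(surrogates, function(p) {
    measure_plug_dimensions(stationary, pose_stat, p, geom)
  })
  names(stat_dims) <- vapply(surrogates, `[[`, "", "id")
  stat_hu <- lapply(sens_plugs, function(p) {
    detect_plug(stationary, pose_stat, p, geom)
  })
  names(stat_hu) <- vapply(sens_plugs, `[[`, "", "id")

  if (is.null(series)) {
    for (t in c("surrogate_dimensions", "motion_amplitude",
                "hu_value_consistency", "projection_dimensions")) {
      add_test(t, NA, NA, "skipped")
    }
    report$spatial <- list()
  } else {
    log_stage("measuring %d bins", series$n_bins)
    bin_dims <- lapply(names(stat_dims), function(id) list())
    names(bin_dims) <- names(stat_dims)
    bin_hu <- lapply(names(stat_hu), function(id) list())
    names(bin_hu) <- names(stat_hu)
    bin_errors <- list()
    for (v in series$volumes) {
      lab <- v$meta$bin_label %||% "?"
      tryCatch({
        pose_k <- locate_phantom(v, geom)
        for (p in surrogates) {
          bin_dims[[p$id]] <- c(bin_dims[[p$id]],
                                list(measure_plug_dimensions(v, pose_k, p,
                                                             geom)))
        }
        for (p in sens_plugs) {
          bin_hu[[p$id]] <- c(bin_hu[[p$id]],
                              list(detect_plug(v, pose_k, p, geom)))
        }
      }, error = function(e) {
        bin_errors[[lab]] <<- conditionMessage(e)
        log_stage("bin %s: error: %s", lab, conditionMessage(e))
      })
    }
    report$bin_errors <- bin_errors
    if (length(bin_errors) == series$n_bins) {
      stopf("every bin failed measurement: %s",
            paste(unlist(bin_errors), collapse = "; "),
            class = "qa4dct_detection_error")
    }

    dim_tables <- guard("surrogate_dimensions",
                        tolerances$dimension_delta_mm, {
      tabs <- lapply(names(stat_dims), function(id) {
        dimension_consistency(bin_dims[[id]], stat_dims[[id]])
      })
      tab <- do.call(rbind, tabs)
      add_test("surrogate_dimensions", max(abs(tab$delta_mm)),
               tolerances$dimension_delta_mm,
               if (max(abs(tab$delta_mm)) <= tolerances$dimension_delta_mm)
                 "pass" else "fail")
      tab
    })

    amp_tables <- if (is.null(trace)) {
      add_test("motion_amplitude", NA, tolerances$amplitude_delta_mm,
               "skipped")
      NULL
    } else {
      guard("motion_amplitude", tolerances$amplitude_delta_mm, {
        tabs <- lapply(names(bin_dims), function(id) {
          motion_amplitude(bin_dims[[id]], trace)
        })
        tab <- do.call(rbind, tabs)
        add_test("motion_amplitude", max(abs(tab$delta_mm)),
                 tolerances$amplitude_delta_mm,
                 if (max(abs(tab$delta_mm)) <= tolerances$amplitude_delta_mm)
                   "pass" else "fail")
        tab
      })
    }

    hu_tab <- guard("hu_value_consistency", tolerances$hu_consistency_hu, {
      tab <- hu_consistency(bin_hu, stat_hu)
      add_test("hu_value_consistency", max(abs(tab$delta_hu)),
               tolerances$hu_consistency_hu,
               if (max(abs(tab$delta_hu)) <= tolerances$hu_consistency_hu)
                 "pass" else "fail")
      tab
    })

    log_stage("deriving average / MIP / MinIP")
    avg <- average_ct(series)
    mip <- intensity_projection(series, "MIP")
    minip <- intensity_projection(series, "MinIP")

    proj_tab <- if (is.null(trace)) {
      add_test("projection_dimensions", NA, tolerances$projection_delta_mm,
               "skipped")
      NULL
    } else {
      guard("projection_dimensions", tolerances$projection_delta_mm, {
        pairs <- list()
        for (p in surrogates) {
          plug_hu_v <- material_hu(geom, p$material)
          bghu <- material_hu(geom, p$module_material %||% geom$background)
          proj <- if (plug_hu_v > bghu) mip else minip
          pairs <- c(pairs, list(
            projection_dimension_check(proj, stat_dims[[p$id]], trace, p,
                                       geom)))
        }
        tab <- do.call(rbind, pairs)
        add_test("projection_dimensions", max(abs(tab$delta_mm)),
                 tolerances$projection_delta_mm,
                 if (max(abs(tab$delta_mm)) <= tolerances$projection_delta_mm)
                   "pass" else "fail")
        tab
      })
    }

    report$spatial <- list(dimension = dim_tables, amplitude = amp_tables,
                           projections = proj_tab)
    report$hu_consistency <- hu_tab
    report$derived_available <- c("average", "MIP", "MinIP")
    if (include_iq) {
      log_stage("image-quality suite (stationary, %d bins, average CT)",
                series$n_bins)
      iq_stat <- as.data.frame(iq_suite(stationary, geom, pose_stat))
      iq_bins <- iq_suite_series(series, geom)
      iq_avg <- as.data.frame(iq_suite(avg, geom))
      report$iq <- list(stationary = iq_stat, bins = iq_bins$per_bin,
                        bins_summary = iq_bins$summary, average = iq_avg)
      for (metric in iq_metric_names) {
        name <- switch(metric,
                       mtf10_lp_per_cm = "spatial_resolution",
                       cnr_low_contrast = "low_contrast_cnr",
                       noise_hu = "noise",
                       uniformity_hu = "uniformity",
                       geometric_distortion_mm = "geometric_distortion",
                       hu_constancy_hu = "hu_constancy",
                       contrast_detectability_mm = "low_contrast")
        mean_4d <- iq_bins$summary$mean[iq_bins$summary$metric == metric]
        delta <- mean_4d - iq_stat[[metric]]
        bound <- tolerances$iq_delta[[metric]]
        status <- if (is.na(delta)) {
          "error"
        } else if (is.null(bound)) {
          "pass"
        } else if (abs(delta) <= bound) "pass" else "fail"
        add_test(name, delta, bound %||% NA, status)
      }
    } else {
      for (t in c("spatial_resolution", "low_contrast_cnr", "noise",
                  "uniformity", "geometric_distortion", "hu_constancy",
                  "low_contrast")) {
        add_test(t, NA, NA, "skipped")
      }
    }
  }
  if (is.null(series)) {
    if (include_iq) {
      # stationary-only input: IQ tests run on the baseline alone
      iq_stat <- as.data.frame(iq_suite(stationary, geom, pose_stat))
      report$iq <- list(stationary = iq_stat)
    }
    for (metric in iq_metric_names) {
      name <- switch(metric,
                     mtf10_lp_per_cm = "spatial_resolution",
                     cnr_low_contrast = "low_contrast_cnr",
                     noise_hu = "noise",
                     uniformity_hu = "uniformity",
                     geometric_distortion_mm = "geometric_distortion",
                     hu_constancy_hu = "hu_constancy",
                     contrast_detectability_mm = "low_contrast")
      if (include_iq) {
        v <- iq_stat[[metric]]
        add_test(name, v, NA, if (is.na(v)) "error" else "pass")
      } else {
        add_test(name, NA, NA, "skipped")
      }
    }
  }
  report$tests <- do.call(rbind, unname(tests))
  class(report) <- "qa_report"
  report
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> model %s, %d bin(s), %s binning\n",
              x$model, x$n_bins, x$binning_mode))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write a QA report as JSON (canonical) or flat CSV
#'
#' @param report A `qa_report` from [run_qa()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$spatial <- lapply(out$spatial, function(tab) {
    if (is.null(tab)) NULL else as.data.frame(tab)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
report_csv <- function(report, path) {
  utils::write.csv(report$tests, path, row.names = FALSE)
  invisible(path)
}

as_report <- function(x) {
  if (inherits(x, "qa_report")) return(x)
  if (is.character(x) && file.exists(x)) {
    r <- jsonlite::read_json(x, simplifyVector = TRUE)
    r$tests <- as.data.frame(r$tests)
    class(r) <- "qa_report"
    return(r)
  }
  stopf("not a qa_report or report file: %s", x, class = "qa4dct_input_error")
}

#' Compare a QA report against a baseline report
#'
#' Longitudinal constancy check: per-test current-minus-baseline deltas with
#' optional tolerance flags. The two reports must carry the same test list;
#' a test whose value is missing in either report is marked `"skipped"`.
#'
#' @param current,baseline `qa_report` objects or paths to report JSON
#'   files.
#' @param tolerances Named list of per-test delta bounds (names matching
#'   `tests$test`); tests without a bound are informational and pass.
#' @return Data frame: `test`, `current`, `baseline`, `delta`, `tolerance`,
#'   `status`.
#' @export
compare_to_baseline <- function(current, baseline, tolerances = list()) {
  cur <- as_report(current)
  base <- as_report(baseline)
  if (!setequal(cur$tests$test, base$tests$test)) {
    stopf("test lists differ between reports: %s vs %s",
          paste(setdiff(cur$tests$test, base$tests$test), collapse = ","),
          paste(setdiff(base$tests$test, cur$tests$test), collapse = ","),
          class = "qa4dct_comparability_error")
  }
  rows <- lapply(cur$tests$test, function(tn) {
    cv <- cur$tests$value[cur$tests$test == tn]
    bv <- base$tests$value[base$tests$test == tn]
    delta <- cv - bv
    bound <- tolerances[[tn]]
    status <- if (is.na(delta)) {
      "skipped"
    } else if (is.null(bound)) {
      "pass"
    } else if (abs(delta) <= bound) "pass" else "fail"
    data.frame(test = tn, current = cv, baseline = bv, delta = delta,
               tolerance = bound %||% NA_real_, status = status)
  })
  do.call(rbind, rows)
}
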