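#' Spatial-integrity analysis
#'
#' Phase-resolved spatial-integrity tests: plug-dimension consistency of the
#' 4DCT bins against the stationary reference, motion-amplitude recovery from
#' per-bin plug centroids, derived volumes (average CT, MIP, MinIP) and the
#' projection dimension check against the expected motion envelope.
#'
#' @name spatial_integrity
NULL

check_same_plug <- function(meas_list, stationary) {
  ids <- vapply(meas_list, function(m) m$plug_id, character(1))
  if (length(unique(c(ids, stationary$plug_id))) != 1L) {
    stopf("mismatched plug ids: %s vs %s",
          paste(unique(ids), collapse = ","), stationary$plug_id,
          class = "qa4dct_input_error")
  }
}

#' Plug-dimension consistency across bins
#'
#' For each axis, the mean FWHM dimension over all bins is compared with the
#' stationary FWHM; the delta (mean over bins minus stationary) is the
#' spatial-integrity dimension metric. All bins enter the mean; no outlier
#' rejection.
#'
#' @param bin_measurements List of `plug_measurement` (one per bin, with
#'   `fwhm_mm` filled) for one plug.
#' @param stationary_measurement The matching stationary `plug_measurement`.
#' @return A data frame with one row per axis: `plug_id`, `axis`,
#'   `mean_fwhm_mm`, `stationary_fwhm_mm`, `delta_mm`; the per-bin FWHM
#'   matrix (bins x 3) is attached as attribute `per_bin`.
#' @export
dimension_consistency <- function(bin_measurements, stationary_measurement) {
  if (!length(bin_measurements)) {
    stopf("need at least one bin measurement", class = "qa4dct_input_error")
  }
  check_same_plug(bin_measurements, stationary_measurement)
  per_bin <- t(vapply(bin_measurements, function(m) m$fwhm_mm, numeric(3)))
  colnames(per_bin) <- c("X", "Y", "Z")
  means <- colMeans(per_bin)
  stat <- stationary_measurement$fwhm_mm
  out <- data.frame(plug_id = stationary_measurement$plug_id,
                    axis = c("X", "Y", "Z"),
                    mean_fwhm_mm = as.numeric(means),
                    stationary_fwhm_mm = as.numeric(stat),
                    delta_mm = as.numeric(means - stat))
  attr(out, "per_bin") <- per_bin
  out
}

#' Motion amplitude from per-bin centroids
#'
#' The measured amplitude per axis is the extent (max minus min) of the plug
#' centroid positions across bins, compared against the trace peak-to-peak
#' amplitude.
#'
#' @param bin_measurements List of `plug_measurement`, one per bin.
#' @param trace The input [sinusoid_trace()] / [sampled_trace()] driving the
#'   motion platform.
#' @return Data frame with one row per axis: `plug_id`, `axis`,
#'   `measured_extent_mm`, `expected_p2p_mm`, `delta_mm`; per-bin centroids
#'   attached as attribute `centroids` (bins x 3).
#' @export
motion_amplitude <- function(bin_measurements, trace) {
  if (length(bin_measurements) < 2L) {
    stopf("motion amplitude needs at least 2 bins",
          class = "qa4dct_insufficient_bins_error")
  }
  cen <- t(vapply(bin_measurements, function(m) m$centroid_mm, numeric(3)))
  colnames(cen) <- c("X", "Y", "Z")
  extent <- apply(cen, 2, function(v) max(v) - min(v))
  expected <- trace_peak_to_peak(trace)
  out <- data.frame(plug_id = bin_measurements[[1]]$plug_id,
                    axis = c("X", "Y", "Z"),
                    measured_extent_mm = as.numeric(extent),
                    expected_p2p_mm = as.numeric(expected),
                    delta_mm = as.numeric(extent - expected))
  attr(out, "centroids") <- cen
  out
}

fold_series <- function(series, f, label, finalize = identity) {
  if (!inherits(series, "phase4d_series") || !length(series$volumes)) {
    stopf("nonempty phase4d_series required", class = "qa4dct_input_error")
  }
  acc <- series$volumes[[1]]$voxels
  for (v in series$volumes[-1]) {
    if (!same_grid(series$volumes[[1]], v)) {
      stopf("series grids are not aligned", class = "qa4dct_input_error")
    }
    acc <- f(acc, v$voxels)
  }
  ct_volume(finalize(acc), series$volumes[[1]]$spacing_mm,
            series$volumes[[1]]$origin_mm,
            meta = list(bin_label = label, series_id = label))
}

#' Average CT of a 4D series
#'
#' Voxelwise arithmetic mean over the bins, labeled `"average"`; the clinical
#' dose-calculation volume derived from 4DCT.
#'
#' @param series A [phase4d_series()].
#' @return A [ct_volume()].
#' @export
average_ct <- function(series) {
  fold_series(series, `+`, "average",
              finalize = function(acc) acc / series$n_bins)
}

#' Intensity projections across a 4D series
#'
#' Voxelwise maximum (MIP) or minimum (MinIP) across the bins; the motion
#' envelope of high- or low-density objects.
#'
#' @param series A [phase4d_series()].
#' @param kind `"MIP"` or `"MinIP"`.
#' @return A [ct_volume()] labeled with `kind`.
#' @export
intensity_projection <- function(series, kind = c("MIP", "MinIP")) {
  kind <- match.arg(kind)
  fold_series(series, if (kind == "MIP") pmax else pmin, kind)
}

#' Projection dimension check
#'
#' Measures a surrogate plug's z-dimension in a MIP or MinIP volume and
#' compares it with the expected motion envelope: the stationary z-FWHM plus
#' the input platform peak-to-peak amplitude along Z. The Teflon plug pairs
#' with the MIP and the Air plug with the MinIP.
#'
#' @param projection A MIP or MinIP [ct_volume()] (from
#'   [intensity_projection()]).
#' @param stationary_measurement The plug's stationary `plug_measurement`.
#' @param trace The input motion trace.
#' @param plug The `plug_spec` (from [find_plug()]).
#' @param geom The [phantom_geometry()].
#' @param pose Optional pre-computed pose of the projection volume.
#' @return One-row data frame: `plug_id`, `projection`, `measured_z_mm`,
#'   `expected_z_mm`, `delta_mm`.
#' @export
projection_dimension_check <- function(projection, stationary_measurement,
                                       trace, plug, geom, pose = NULL) {
  kind <- projection$meta$bin_label %||% "projection"
  if (is.null(pose)) pose <- locate_phantom(projection, geom)
  p2p_z <- trace_peak_to_peak(trace)[3]
  meas <- measure_plug_dimensions(projection, pose, plug, geom,
                                  z_margin = 8 + p2p_z / 2)
  expected <- stationary_measurement$fwhm_mm[3] + p2p_z
  data.frame(plug_id = plug$id, projection = kind,
             measured_z_mm = meas$fwhm_mm[3],
             expected_z_mm = expected,
             delta_mm = meas$fwhm_mm[3] - expected)
}
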