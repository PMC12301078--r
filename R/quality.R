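#' CT image-quality metric suite
#'
#' The metrics computed identically for the stationary scan, each 4DCT bin,
#' and the average CT: geometric distortion from the distance markers,
#' spatial resolution as the 10%-MTF frequency from the bead point-spread
#' function, low-contrast detectability, HU constancy of the air/LDPE/acrylic
#' inserts, uniformity, noise, and the low-contrast CNR of the
#' polystyrene/LDPE pair.
#'
#' @name image_quality
NULL

# values of voxels inside an in-plane disc within an axial band
disc_roi_values <- function(vol, center_mm, radius_mm, z_half_mm,
                            inner_radius_mm = 0) {
  xs <- axis_coords(vol, 1)
  ys <- axis_coords(vol, 2)
  zs <- axis_coords(vol, 3)
  ix <- which(abs(xs - center_mm[1]) <= radius_mm)
  iy <- which(abs(ys - center_mm[2]) <= radius_mm)
  iz <- which(abs(zs - center_mm[3]) <= z_half_mm)
  if (!length(ix) || !length(iy) || !length(iz)) {
    stopf("ROI outside volume", class = "qa4dct_configuration_error")
  }
  d2 <- outer((xs[ix] - center_mm[1])^2, (ys[iy] - center_mm[2])^2, "+")
  keep <- d2 <= radius_mm^2 & d2 >= inner_radius_mm^2
  sub <- vol$voxels[ix, iy, iz, drop = FALSE]
  sub[rep(keep, length(iz))]
}

module_region_center <- function(pose, mod) {
  pose_transform(pose, c(0, 0, mod$z_mm))
}

#' Geometric distortion from distance markers
#'
#' Localizes each distance marker by thresholded centroid and measures all
#' marker pairs whose nominal separation equals the configured spacing; the
#' metric is the absolute difference between the mean measured distance and
#' the nominal distance.
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @return Distortion in mm; measured pair distances attached as attribute
#'   `pair_distances_mm`.
#' @export
geometric_distortion <- function(vol, pose, geom) {
  mod <- geometry_module(geom, "sensitometry")
  mk <- mod$markers
  if (is.null(mk) || length(mk$positions) < 2L) {
    stopf("geometry has no distance markers",
          class = "qa4dct_configuration_error")
  }
  nominal <- lapply(mk$positions, function(p) {
    c(p$x_mm, p$y_mm, mod$z_mm + p$z_mm)
  })
  cents <- lapply(nominal, function(p) marker_centroid(vol, pose, geom, p, mk))
  spacing <- mk$nominal_spacing_mm
  measured <- numeric(0)
  np <- length(nominal)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      nom_d <- sqrt(sum((nominal[[i]] - nominal[[j]])^2))
      if (abs(nom_d - spacing) <= 0.5) {
        measured <- c(measured,
                      sqrt(sum((cents[[i]] - cents[[j]])^2)))
      }
    }
  }
  if (!length(measured)) {
    stopf("no marker pair at the nominal spacing %.1f mm", spacing,
          class = "qa4dct_configuration_error")
  }
  out <- abs(mean(measured) - spacing)
  attr(out, "pair_distances_mm") <- measured
  out
}

# first-order Bessel-type transform of a uniform sphere of diameter d:
# normalized 3D FT evaluated at in-plane radial frequency f (cycles/mm)
sphere_aperture_mtf <- function(f, diameter_mm) {
  x <- pi * diameter_mm * f
  out <- rep(1, length(x))
  nz <- x > 1e-8
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

fft_freqs <- function(n, spacing) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * spacing)
  k
}

#' Modulation transfer function from the bead
#'
#' Extracts a cubic ROI around the bead, subtracts the background (median of
#' the ROI in-plane shell), sums the bead signal along Z to obtain the
#' in-plane PSF sample, takes the 2D FFT magnitude radially averaged over
#' in-plane frequency, normalizes to 1 at zero frequency, and divides out the
#' analytic transform of the bead's finite diameter (sphere-aperture
#' correction, capped at 80% of Nyquist to avoid noise blow-up). The
#' spatial-resolution figure is the lowest frequency where the modulation
#' crosses 0.10, linearly interpolated, in line pairs per cm. When the
#' modulation never reaches 0.10 below the cap, the cap frequency is
#' reported with `saturated = TRUE`.
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @param roi_half_mm ROI half-width in mm (default 6).
#' @param cap_frac Fraction of in-plane Nyquist beyond which the curve is
#'   truncated (default 0.8).
#' @return List with `mtf10_lp_cm`, `curve` (data frame `freq_lp_cm`,
#'   `modulation`), and `saturated`.
#' @export
mtf_from_bead <- function(vol, pose, geom, roi_half_mm = 6, cap_frac = 0.8) {
  mod <- geometry_module(geom, "spatial_resolution")
  if (is.null(mod$bead)) {
    stopf("geometry has no bead", class = "qa4dct_configuration_error")
  }
  b <- mod$bead
  center <- pose_transform(pose, c(b$x_mm, b$y_mm, mod$z_mm + b$z_mm))
  half <- rep(roi_half_mm, 3)
  bi <- box_indices(vol, center, half)
  sub <- vol$voxels[bi[[1]], bi[[2]], bi[[3]], drop = FALSE]
  d <- dim(sub)
  # background: median over the 2-pixel in-plane shell of the ROI
  rim <- array(FALSE, dim = d)
  w <- min(2L, d[1], d[2])
  rim[c(seq_len(w), d[1] - seq_len(w) + 1L), , ] <- TRUE
  rim[, c(seq_len(w), d[2] - seq_len(w) + 1L), ] <- TRUE
  bg <- stats::median(sub[rim])
  psf2d <- apply(sub - bg, c(1, 2), sum)
  total <- sum(psf2d)
  if (total <= 0) {
    stopf("bead signal not above background", class = "qa4dct_detection_error")
  }
  sp <- vol$spacing_mm
  n <- 2^ceiling(log2(4 * max(d[1], d[2])))
  pad <- matrix(0, n, n)
  pad[seq_len(d[1]), seq_len(d[2])] <- psf2d
  mag <- Mod(stats::fft(pad))
  fx <- fft_freqs(n, sp[1])
  fy <- fft_freqs(n, sp[2])
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  nyq <- 0.5 / max(sp[1], sp[2])
  df <- 1 / (n * max(sp[1], sp[2]))
  cap <- cap_frac * nyq
  nb <- floor(cap / df)
  freq <- (0:nb) * df
  modn <- vapply(0:nb, function(j) {
    sel <- fr >= (j - 0.5) * df & fr < (j + 0.5) * df
    mean(mag[sel])
  }, numeric(1))
  modn <- modn / modn[1]
  corr <- sphere_aperture_mtf(freq, b$diameter_mm)
  ok <- corr > 0.05
  modn[ok] <- modn[ok] / corr[ok]
  modn <- modn[ok]
  freq <- freq[ok]
  modn[1] <- 1
  below <- which(modn < 0.10)
  if (length(below)) {
    j <- min(below)
    t <- (modn[j - 1] - 0.10) / (modn[j - 1] - modn[j])
    f10 <- freq[j - 1] + t * (freq[j] - freq[j - 1])
    saturated <- FALSE
  } else {
    f10 <- freq[length(freq)]
    saturated <- TRUE
  }
  list(mtf10_lp_cm = 10 * f10,
       curve = data.frame(freq_lp_cm = 10 * freq, modulation = modn),
       saturated = saturated)
}

#' Low-contrast detectability
#'
#' For each low-contrast target at the requested nominal contrast, in
#' descending diameter, compares the mean HU of a disc ROI at the expected
#' target position against a surrounding background annulus; the target is
#' detectable when the ROI contrast divided by the annulus standard
#' deviation reaches the decision threshold. Returns the smallest detectable
#' diameter (NA when none is detectable).
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @param contrast_pct Nominal contrast level of the target set (default 1).
#' @param decision_threshold ROI-contrast-to-noise threshold (default 2).
#' @return List with `smallest_detectable_mm` (NA if none) and `table`
#'   (per-target diameter, ROI contrast, annulus sd, CNR, detectable flag).
#' @export
low_contrast_detectability <- function(vol, pose, geom, contrast_pct = 1.0,
                                       decision_threshold = 2.0) {
  mod <- geometry_module(geom, "low_contrast")
  targets <- Filter(function(t) isTRUE(all.equal(t$contrast_pct, contrast_pct)),
                    mod$low_contrast_targets %||% list())
  if (!length(targets)) {
    stopf("no low-contrast targets at %.1f%% contrast", contrast_pct,
          class = "qa4dct_configuration_error")
  }
  dias <- vapply(targets, function(t) t$diameter_mm, numeric(1))
  targets <- targets[order(-dias)]
  z_half <- mod$length_mm * 0.25
  rows <- lapply(targets, function(tg) {
    th <- tg$theta_deg * pi / 180
    center <- pose_transform(pose, c(tg$r_mm * cos(th), tg$r_mm * sin(th),
                                     mod$z_mm))
    r <- tg$diameter_mm / 2
    disc <- disc_roi_values(vol, center, max(r - 1, r / 2), z_half)
    annulus <- disc_roi_values(vol, center, r + 5, z_half,
                               inner_radius_mm = r + 2)
    contrast <- abs(mean(disc) - mean(annulus))
    noise <- stats::sd(annulus)
    cnr <- if (noise > 0) contrast / noise else Inf
    data.frame(diameter_mm = tg$diameter_mm, contrast_hu = contrast,
               annulus_sd_hu = noise, cnr = cnr,
               detectable = cnr >= decision_threshold)
  })
  tab <- do.call(rbind, rows)
  det <- tab$diameter_mm[tab$detectable]
  list(smallest_detectable_mm = if (length(det)) min(det) else NA_real_,
       largest_tested_mm = max(tab$diameter_mm),
       table = tab)
}

#' HU constancy
#'
#' Maximum absolute difference between measured plug mean HU and the
#' expected CT numbers of the air (-1000 HU), LDPE (-100 HU) and acrylic
#' (120 HU) inserts.
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @param expected Named numeric of expected HU per plug id.
#' @return Max abs deviation in HU; per-plug table attached as attribute
#'   `per_plug`.
#' @export
hu_constancy <- function(vol, pose, geom,
                         expected = c(air = -1000, ldpe = -100,
                                      acrylic = 120)) {
  rows <- lapply(names(expected), function(id) {
    m <- detect_plug(vol, pose, find_plug(geom, id), geom)
    data.frame(plug_id = id, mean_hu = m$mean_hu,
               expected_hu = expected[[id]],
               deviation_hu = m$mean_hu - expected[[id]])
  })
  tab <- do.call(rbind, rows)
  out <- max(abs(tab$deviation_hu))
  attr(out, "per_plug") <- tab
  out
}

#' Per-plug HU consistency versus stationary
#'
#' For each sensitometry plug, the mean over bins of the plug mean HU minus
#' the stationary plug mean HU.
#'
#' @param bin_measurements Named list (by plug id) of lists of
#'   `plug_measurement`, one inner list per plug across bins.
#' @param stationary_measurements Named list (by plug id) of stationary
#'   `plug_measurement`.
#' @return Data frame: `plug_id`, `mean_bin_hu`, `stationary_hu`,
#'   `delta_hu`.
#' @export
hu_consistency <- function(bin_measurements, stationary_measurements) {
  ids <- names(bin_measurements)
  if (!setequal(ids, names(stationary_measurements))) {
    stopf("plug sets differ between bins and stationary",
          class = "qa4dct_input_error")
  }
  rows <- lapply(ids, function(id) {
    bins <- vapply(bin_measurements[[id]], function(m) m$mean_hu, numeric(1))
    stat <- stationary_measurements[[id]]$mean_hu
    data.frame(plug_id = id, mean_bin_hu = mean(bins), stationary_hu = stat,
               delta_hu = mean(bins) - stat)
  })
  do.call(rbind, rows)
}

uniformity_module_geometry <- function(geom) {
  mod <- geometry_module(geom, "uniformity")
  diam <- if (is.na(mod$diameter_mm)) geom$outer_diameter_mm else mod$diameter_mm
  list(mod = mod, diameter_mm = diam)
}

#' Uniformity
#'
#' Maximum absolute difference between the mean HU of four peripheral ROIs
#' (12/3/6/9 o'clock at 80% of the module radius) and the central ROI of the
#' uniformity module. ROI diameters default to 10% of the module diameter.
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @param roi_diameter_frac Peripheral/central ROI diameter as a fraction of
#'   the module diameter (default 0.1).
#' @param radius_frac Radial position of the peripheral ROIs as a fraction
#'   of the module radius (default 0.8).
#' @param band_mm Axial half-extent of the ROIs (default 5).
#' @return Uniformity in HU (max abs peripheral minus center difference);
#'   ROI means attached as attribute `roi_means_hu`.
#' @export
uniformity <- function(vol, pose, geom, roi_diameter_frac = 0.1,
                       radius_frac = 0.8, band_mm = 5) {
  um <- uniformity_module_geometry(geom)
  center <- module_region_center(pose, um$mod)
  roi_r <- um$diameter_mm * roi_diameter_frac / 2
  ring <- um$diameter_mm / 2 * radius_frac
  center_mean <- mean(disc_roi_values(vol, center, roi_r, band_mm))
  periph <- vapply(c(90, 0, 270, 180), function(ang) {
    th <- (ang + pose$rotation_deg) * pi / 180
    mean(disc_roi_values(vol, center + c(ring * cos(th), ring * sin(th), 0),
                         roi_r, band_mm))
  }, numeric(1))
  out <- max(abs(periph - center_mean))
  attr(out, "roi_means_hu") <- c(center = center_mean,
                                 N = periph[1], E = periph[2],
                                 S = periph[3], W = periph[4])
  out
}

#' Noise
#'
#' Sample standard deviation of HU in the central disc ROI of the uniformity
#' module, with ROI diameter 40% of the module diameter, over the module's
#' central slice band.
#'
#' @inheritParams uniformity
#' @return Noise in HU.
#' @export
image_noise <- function(vol, pose, geom, band_mm = 5) {
  um <- uniformity_module_geometry(geom)
  center <- module_region_center(pose, um$mod)
  vals <- disc_roi_values(vol, center, 0.2 * um$diameter_mm, band_mm)
  stats::sd(vals)
}

#' Low-contrast CNR
#'
#' Contrast-to-noise ratio of the polystyrene/LDPE sensitometry pair: the
#' difference of the plug mean HU divided by the quadrature sum of the two
#' plug HU standard deviations (an arithmetic-sum denominator is available
#' via `denominator = "sum"`).
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param geom The [phantom_geometry()].
#' @param denominator `"quadrature"` (default) or `"sum"`.
#' @return Signed CNR (dimensionless); `Inf` with attribute
#'   `undefined = TRUE` when both plug standard deviations are zero.
#' @export
cnr_low_contrast <- function(vol, pose, geom,
                             denominator = c("quadrature", "sum")) {
  denominator <- match.arg(denominator)
  pair <- find_plug(geom, role = "cnr_pair_member")
  if (length(pair) != 2L) {
    stopf("expected exactly 2 cnr_pair_member plugs, found %d", length(pair),
          class = "qa4dct_configuration_error")
  }
  hu <- vapply(pair, function(p) material_hu(geom, p$material), numeric(1))
  pair <- pair[order(-hu)]  # higher-HU plug first (polystyrene - LDPE)
  m1 <- detect_plug(vol, pose, pair[[1]], geom)
  m2 <- detect_plug(vol, pose, pair[[2]], geom)
  den <- if (denominator == "quadrature") {
    sqrt(m1$sd_hu^2 + m2$sd_hu^2)
  } else {
    m1$sd_hu + m2$sd_hu
  }
  if (den == 0) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (m1$mean_hu - m2$mean_hu) / den
}

#' Run the full image-quality suite on one volume
#'
#' Computes every metric whose supporting module is present in the geometry;
#' individual metric failures are captured per metric and the suite
#' continues.
#'
#' @param vol A [ct_volume()].
#' @param geom The [phantom_geometry()].
#' @param pose Optional pre-computed pose (located automatically otherwise).
#' @return An `iq_metrics` list: `bin_label`, numeric metrics
#'   (`geometric_distortion_mm`, `mtf10_lp_per_cm`,
#'   `contrast_detectability_mm`, `hu_constancy_hu`, `uniformity_hu`,
#'   `noise_hu`, `cnr_low_contrast`), and `errors` (named list of failure
#'   messages).
#' @export
iq_suite <- function(vol, geom, pose = NULL) {
  if (is.null(pose)) pose <- locate_phantom(vol, geom)
  errors <- list()
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  out <- list(
    bin_label = vol$meta$bin_label %||% NA_character_,
    geometric_distortion_mm = run("geometric_distortion",
                                  as.numeric(geometric_distortion(vol, pose, geom))),
    mtf10_lp_per_cm = run("mtf", mtf_from_bead(vol, pose, geom)$mtf10_lp_cm),
    contrast_detectability_mm =
      run("low_contrast",
          low_contrast_detectability(vol, pose, geom)$smallest_detectable_mm),
    hu_constancy_hu = run("hu_constancy",
                          as.numeric(hu_constancy(vol, pose, geom))),
    uniformity_hu = run("uniformity", as.numeric(uniformity(vol, pose, geom))),
    noise_hu = run("noise", image_noise(vol, pose, geom)),
    cnr_low_contrast = run("cnr", as.numeric(cnr_low_contrast(vol, pose, geom)))
  )
  out$errors <- errors
  class(out) <- "iq_metrics"
  out
}

iq_metric_names <- c("geometric_distortion_mm", "mtf10_lp_per_cm",
                     "contrast_detectability_mm", "hu_constancy_hu",
                     "uniformity_hu", "noise_hu", "cnr_low_contrast")

#' @export
as.data.frame.iq_metrics <- function(x, ...) {
  data.frame(bin_label = x$bin_label,
             as.list(unlist(x[iq_metric_names])))
}

#' Image-quality suite across a 4D series
#'
#' Runs [iq_suite()] on each bin and summarizes every metric as the
#' unweighted mean and sample standard deviation across bins.
#'
#' @param series A [phase4d_series()].
#' @param geom The [phantom_geometry()].
#' @return List with `per_bin` (data frame, one row per bin) and `summary`
#'   (data frame of metric mean and sd across bins).
#' @export
iq_suite_series <- function(series, geom) {
  per_bin <- do.call(rbind, lapply(series$volumes, function(v) {
    as.data.frame(iq_suite(v, geom))
  }))
  vals <- per_bin[, iq_metric_names, drop = FALSE]
  summary <- data.frame(metric = iq_metric_names,
                        mean = vapply(vals, mean, numeric(1)),
                        sd = vapply(vals, stats::sd, numeric(1)),
                        row.names = NULL)
  list(per_bin = per_bin, summary = summary)
}
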