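#' Motion traces
#'
#' A `motion_trace` describes the rigid displacement of the whole phantom
#' over time. Two kinds are supported: an analytic sinusoid (the standard
#' motion-platform QA trace) and a sampled time series (e.g. a patient-like
#' breathing trace). The sinusoid is parameterized per axis by its
#' peak-to-peak amplitude; phase fraction 0 is anchored at peak displacement
#' (peak-inhale analog) so that displacement(p) = (p2p/2) * cos(2*pi*(p +
#' phase_offset)).
#'
#' @param peak_to_peak_mm Peak-to-peak amplitude; a scalar means motion along
#'   Z only, a length-3 vector gives per-axis amplitudes.
#' @param period_s Breathing period in seconds.
#' @param phase_offset_fraction Phase anchor shift in \[0, 1).
#' @return A `motion_trace`.
#' @export
sinusoid_trace <- function(peak_to_peak_mm, period_s,
                           phase_offset_fraction = 0) {
  if (length(peak_to_peak_mm) == 1L) peak_to_peak_mm <- c(0, 0, peak_to_peak_mm)
  check_number(peak_to_peak_mm, "peak_to_peak_mm", min = 0, len = 3L)
  check_number(period_s, "period_s", min = 1e-9)
  check_number(phase_offset_fraction, "phase_offset_fraction", min = 0, max = 1 - 1e-12)
  structure(list(kind = "sinusoid",
                 peak_to_peak_mm = as.numeric(peak_to_peak_mm),
                 period_s = as.numeric(period_s),
                 phase_offset_fraction = as.numeric(phase_offset_fraction)),
            class = "motion_trace")
}

#' @rdname sinusoid_trace
#' @param t_s Strictly increasing sample times in seconds.
#' @param dx_mm,dy_mm,dz_mm Displacement samples per axis in mm.
#' @param period_s For sampled traces, the nominal breathing period used to
#'   assign phase fractions for phase binning.
#' @export
sampled_trace <- function(t_s, dx_mm, dy_mm, dz_mm, period_s) {
  n <- length(t_s)
  stopifnot(length(dx_mm) == n, length(dy_mm) == n, length(dz_mm) == n)
  if (n < 2L || any(diff(t_s) <= 0)) {
    stopf("sampled trace times must be strictly increasing (n >= 2)",
          class = "qa4dct_validation_error")
  }
  check_number(period_s, "period_s", min = 1e-9)
  structure(list(kind = "sampled",
                 t_s = as.numeric(t_s),
                 disp = cbind(dx = as.numeric(dx_mm), dy = as.numeric(dy_mm),
                              dz = as.numeric(dz_mm)),
                 period_s = as.numeric(period_s)),
            class = "motion_trace")
}

#' Synthetic patient-like 3D breathing trace
#'
#' A deterministic quasi-periodic 3D trace: the dominant axis (Z) is a sum of
#' two incommensurate sinusoids plus a slow drift, with smaller correlated
#' X/Y components, emulating the irregular amplitude of a real breathing
#' record. Ten nominal cycles of 4.2 s are sampled at 20 Hz.
#'
#' @param scale Overall amplitude scale factor (default 1 gives ~15 mm
#'   peak-to-peak along Z).
#' @return A sampled [motion_trace] with `period_s = 4.2`.
#' @export
patient_like_trace <- function(scale = 1) {
  t <- seq(0, 42, by = 0.05)
  z <- 6.0 * cos(2 * pi * t / 4.2) +
    1.5 * cos(2 * pi * t / 1.9 + 1.1) +
    0.8 * sin(2 * pi * t / 21)
  x <- 1.2 * cos(2 * pi * t / 4.2 + 0.4)
  y <- 0.8 * cos(2 * pi * t / 4.2 + 2.0) + 0.3 * cos(2 * pi * t / 2.3)
  sampled_trace(t, scale * x, scale * y, scale * z, period_s = 4.2)
}

# Displacement (n x 3 matrix) at given phase fractions of a sinusoid.
sinusoid_displacement <- function(trace, phase) {
  amp <- trace$peak_to_peak_mm / 2
  c_ <- cos(2 * pi * (phase + trace$phase_offset_fraction))
  cbind(dx = amp[1] * c_, dy = amp[2] * c_, dz = amp[3] * c_)
}

#' Per-axis peak-to-peak displacement of a trace
#' @param trace A `motion_trace`.
#' @return Length-3 numeric (x, y, z) in mm.
#' @export
trace_peak_to_peak <- function(trace) {
  if (trace$kind == "sinusoid") return(trace$peak_to_peak_mm)
  apply(trace$disp, 2, function(v) max(v) - min(v))
}

#' Acquisition parameters for synthetic rendering
#'
#' @param voxel_spacing_mm Voxel spacing (x, y, z); default `c(1, 1, 2)`,
#'   i.e. 1 mm in-plane with 2 mm slices as in a typical lung 4DCT protocol.
#' @param psf_sigma_mm Isotropic Gaussian point-spread width applied after
#'   partial-volume rendering; default 0.5 mm, giving an in-plane resolution
#'   of about 6.8 lp/cm at 10% MTF, typical of a clinical body kernel.
#' @param noise_sigma_hu Additive Gaussian noise scale in HU (default 10).
#' @param supersampling In-plane subdivision per axis used for
#'   partial-volume coverage of boundary voxels (axial partial volume is
#'   computed analytically for cylinders); default 4.
#' @param seed Integer seed controlling all simulator randomness.
#' @param grid An optional explicit grid `list(shape, origin_mm)`; by default
#'   the grid is derived from the phantom geometry with margins wide enough
#'   for the rendered displacement.
#' @return An `acquisition_spec`.
#' @export
acquisition_spec <- function(voxel_spacing_mm = c(1, 1, 2),
                             psf_sigma_mm = 0.5, noise_sigma_hu = 10,
                             supersampling = 4L, seed = 1L, grid = NULL) {
  check_number(voxel_spacing_mm, "voxel_spacing_mm", min = 1e-9, len = 3L)
  check_number(psf_sigma_mm, "psf_sigma_mm", min = 0)
  check_number(noise_sigma_hu, "noise_sigma_hu", min = 0)
  check_number(supersampling, "supersampling", min = 1)
  structure(list(voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 psf_sigma_mm = as.numeric(psf_sigma_mm),
                 noise_sigma_hu = as.numeric(noise_sigma_hu),
                 supersampling = as.integer(supersampling),
                 seed = as.integer(seed), grid = grid),
            class = "acquisition_spec")
}

#' Retrospective binning parameters
#'
#' @param mode `"phase"` (bins are equal fractions of the breathing cycle)
#'   or `"amplitude"` (bins are equal-width intervals of the principal-axis
#'   displacement range).
#' @param n_bins Number of respiratory bins (default 10).
#' @param intra_bin_samples Number of sub-displacements rendered and averaged
#'   per bin to model intra-bin motion blur (default 3). With 1 sample per
#'   bin, phase bins are sampled at the bin start so that a sinusoid anchored
#'   at peak displacement hits both extremes exactly.
#' @return A `binning_spec`.
#' @export
binning_spec <- function(mode = "phase", n_bins = 10L,
                         intra_bin_samples = 3L) {
  mode <- match.arg(mode, c("phase", "amplitude"))
  check_number(n_bins, "n_bins", min = 1)
  check_number(intra_bin_samples, "intra_bin_samples", min = 1)
  structure(list(mode = mode, n_bins = as.integer(n_bins),
                 intra_bin_samples = as.integer(intra_bin_samples)),
            class = "binning_spec")
}

# Pick m representative rows from a sample matrix, spread evenly across the
# distribution of the principal-axis coordinate (deterministic).
representative_rows <- function(disp, m, principal) {
  n <- nrow(disp)
  if (n <= m) return(disp[rep(seq_len(n), length.out = m), , drop = FALSE])
  ord <- order(disp[, principal])
  pick <- ord[round(seq(1, n, length.out = m))]
  disp[pick, , drop = FALSE]
}

#' Sample per-bin sub-displacements from a trace
#'
#' Phase mode: bin k covers cycle fraction \[k/n, (k+1)/n); for an analytic
#' sinusoid the bin is sampled on a left-anchored uniform grid of
#' `intra_bin_samples` phases (so bin starts include the trace extremes when
#' the anchor is at peak displacement). Amplitude mode: the principal-axis
#' displacement range is split into n equal-width intervals; each bin keeps
#' the trace samples falling in its interval, reduced to `intra_bin_samples`
#' evenly spread representatives.
#'
#' @param trace A [sinusoid_trace()] / [sampled_trace()].
#' @param binning A [binning_spec()].
#' @return List of `n_bins` matrices (`intra_bin_samples` x 3) of
#'   displacements in mm, ordered by bin index.
#' @export
sample_trace_bins <- function(trace, binning) {
  n <- binning$n_bins
  m <- binning$intra_bin_samples
  if (binning$mode == "phase" && trace$kind == "sinusoid") {
    return(lapply(seq_len(n) - 1L, function(k) {
      phases <- (k + (seq_len(m) - 1L) / m) / n
      sinusoid_displacement(trace, phases)
    }))
  }
  # Sample-based path: densify sinusoids, use the recorded samples otherwise.
  if (trace$kind == "sinusoid") {
    phases <- seq(0, 1 - 1 / 2000, by = 1 / 2000)
    disp <- sinusoid_displacement(trace, phases)
  } else {
    disp <- trace$disp
    phases <- ((trace$t_s - trace$t_s[1]) / trace$period_s) %% 1
  }
  p2p <- apply(disp, 2, function(v) max(v) - min(v))
  principal <- which.max(p2p)
  if (binning$mode == "amplitude") {
    if (p2p[principal] <= 1e-9) {
      stopf("amplitude binning of a zero-amplitude trace is degenerate",
            class = "qa4dct_degenerate_trace_error")
    }
    lo <- min(disp[, principal])
    width <- p2p[principal] / n
    idx <- pmin(floor((disp[, principal] - lo) / width), n - 1L)
    lapply(seq_len(n) - 1L, function(k) {
      rows <- disp[idx == k, , drop = FALSE]
      if (!nrow(rows)) {
        # empty interval (possible for gappy sampled traces): fall back to
        # the sample nearest the interval center
        center <- lo + (k + 0.5) * width
        rows <- disp[which.min(abs(disp[, principal] - center)), ,
                     drop = FALSE]
      }
      representative_rows(rows, m, principal)
    })
  } else {
    idx <- pmin(floor(phases * n), n - 1L)
    lapply(seq_len(n) - 1L, function(k) {
      rows <- disp[idx == k, , drop = FALSE]
      if (!nrow(rows)) {
        stopf("phase bin %d contains no trace samples", k,
              class = "qa4dct_degenerate_trace_error")
      }
      representative_rows(rows, m, principal)
    })
  }
}

## ---- rendering ------------------------------------------------------------

# Grid derived from the geometry: centered in-plane, covering the body plus
# fixed margins and any extra motion margin.
acq_grid <- function(geom, acq, extra_margin = c(0, 0, 0)) {
  if (!is.null(acq$grid)) return(acq$grid)
  extra_margin <- unname(extra_margin)
  sp <- acq$voxel_spacing_mm
  margin_xy <- 14 + max(extra_margin[1:2])
  margin_z <- 12 + extra_margin[3]
  half_xy <- geom$outer_diameter_mm / 2 + margin_xy
  nx <- 2L * ceiling(half_xy / sp[1]) + 1L
  ny <- 2L * ceiling(half_xy / sp[2]) + 1L
  zmin <- geom$body_z_mm[1] - margin_z
  zmax <- geom$body_z_mm[2] + margin_z
  nz <- ceiling((zmax - zmin) / sp[3]) + 1L
  origin <- c(-(nx - 1) / 2 * sp[1], -(ny - 1) / 2 * sp[2], zmin)
  list(shape = unname(c(nx, ny, nz)), origin_mm = unname(origin))
}

# Fractional in-plane coverage of a disc over a pixel grid; exact 0/1
# classification away from the rim, ss x ss subsampling on rim pixels.
disc_coverage <- function(xs, ys, cx, cy, radius, dx, dy, ss) {
  h <- 0.5 * sqrt(dx^2 + dy^2)
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  cov <- (d2 <= (radius - h)^2) * 1
  rim <- which(d2 > (radius - h)^2 & d2 < (radius + h)^2)
  if (length(rim)) {
    ri <- arrayInd(rim, dim(d2))
    px <- xs[ri[, 1]]
    py <- ys[ri[, 2]]
    acc <- numeric(length(rim))
    off <- (seq_len(ss) - 0.5) / ss - 0.5
    for (ox in off) {
      for (oy in off) {
        acc <- acc + (((px + ox * dx - cx)^2 + (py + oy * dy - cy)^2) <= radius^2)
      }
    }
    cov[rim] <- acc / (ss * ss)
  }
  cov
}

# Fraction of each voxel z-extent covered by [z0, z1] (analytic).
interval_coverage <- function(zs, dz, z0, z1) {
  pmax(0, (pmin(zs + dz / 2, z1) - pmax(zs - dz / 2, z0))) / dz
}

paint_cylinder <- function(vol, grid_x, grid_y, grid_z, sp, cx, cy, z0, z1,
                           radius, hu, ss, cache = NULL) {
  h <- 0.5 * sqrt(sp[1]^2 + sp[2]^2)
  ix <- which(abs(grid_x - cx) <= radius + h)
  iy <- which(abs(grid_y - cy) <= radius + h)
  iz <- which(grid_z + sp[3] / 2 > z0 & grid_z - sp[3] / 2 < z1)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  key <- sprintf("c|%.4f|%.4f|%.4f", cx, cy, radius)
  inplane <- if (!is.null(cache)) cache[[key]] else NULL
  if (is.null(inplane)) {
    inplane <- disc_coverage(grid_x[ix], grid_y[iy], cx, cy, radius,
                             sp[1], sp[2], ss)
    if (!is.null(cache)) cache[[key]] <- inplane
  }
  zfrac <- interval_coverage(grid_z[iz], sp[3], z0, z1)
  occ <- outer(inplane, zfrac)
  sub <- vol[ix, iy, iz, drop = FALSE]
  vol[ix, iy, iz] <- sub + occ * (hu - sub)
  vol
}

paint_sphere <- function(vol, grid_x, grid_y, grid_z, sp, center, radius,
                         hu, ss) {
  ss <- max(ss, 4L)
  ix <- which(abs(grid_x - center[1]) <= radius + sp[1])
  iy <- which(abs(grid_y - center[2]) <= radius + sp[2])
  iz <- which(abs(grid_z - center[3]) <= radius + sp[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  occ <- array(0, dim = c(nx, ny, nz))
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  gx <- grid_x[ix] - center[1]
  gy <- grid_y[iy] - center[2]
  gz <- grid_z[iz] - center[3]
  for (ox in off) {
    d2x <- (gx + ox * sp[1])^2
    for (oy in off) {
      d2xy <- outer(d2x, (gy + oy * sp[2])^2, "+")
      for (oz in off) {
        d2 <- outer(d2xy, (gz + oz * sp[3])^2, "+")
        occ <- occ + (d2 <= radius^2)
      }
    }
  }
  occ <- occ / ss^3
  sub <- vol[ix, iy, iz, drop = FALSE]
  vol[ix, iy, iz] <- sub + occ * (hu - sub)
  vol
}

# Separable Gaussian blur; kernels sampled at the voxel pitch and
# renormalized, edges padded by replication. Near-delta kernels are skipped.
# Implemented as shifted-array accumulation, which beats stats::filter on
# multi-million-voxel grids.
gaussian_blur3 <- function(vox, sigma_mm, spacing) {
  d <- dim(vox)
  for (axis in 1:3) {
    s <- sigma_mm / spacing[axis]
    r <- ceiling(4 * s)
    if (r < 1) next
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    if (max(k) > 0.9999) next
    n <- d[axis]
    padsel <- c(rep(1L, r), seq_len(n), rep(n, r))
    pad <- switch(axis,
                  `1` = vox[padsel, , , drop = FALSE],
                  `2` = vox[, padsel, , drop = FALSE],
                  `3` = vox[, , padsel, drop = FALSE])
    acc <- NULL
    for (j in seq_along(k)) {
      sel <- (j - 1L) + seq_len(n)
      term <- switch(axis,
                     `1` = pad[sel, , , drop = FALSE],
                     `2` = pad[, sel, , drop = FALSE],
                     `3` = pad[, , sel, drop = FALSE])
      acc <- if (is.null(acc)) k[j] * term else acc + k[j] * term
    }
    vox <- acc
  }
  vox
}

#' Render the phantom at a rigid displacement
#'
#' Produces a noiseless HU volume: every geometry primitive (body cylinder,
#' module fills, sensitometry plugs, distance rods, low-contrast targets,
#' bead) is rasterized with partial-volume coverage — analytic along Z for
#' z-aligned cylinders, `supersampling^2` in-plane subsamples on rim voxels,
#' `supersampling^3` for the bead sphere — then convolved with the Gaussian
#' PSF. Deterministic; noise is added by [simulate_4dct()] only.
#'
#' @param geom A [phantom_geometry()].
#' @param displacement Length-3 rigid displacement in mm.
#' @param acq An [acquisition_spec()].
#' @param cache Internal in-plane coverage cache (an environment) reused
#'   across renderings that differ only axially.
#' @return A [ct_volume()].
#' @export
render_phantom <- function(geom, displacement = c(0, 0, 0),
                           acq = acquisition_spec(), cache = NULL) {
  check_number(displacement, "displacement", len = 3L)
  grid <- acq_grid(geom, acq)
  sp <- acq$voxel_spacing_mm
  shape <- grid$shape
  grid_x <- grid$origin_mm[1] + (seq_len(shape[1]) - 1) * sp[1]
  grid_y <- grid$origin_mm[2] + (seq_len(shape[2]) - 1) * sp[2]
  grid_z <- grid$origin_mm[3] + (seq_len(shape[3]) - 1) * sp[3]
  R <- geom$outer_diameter_mm / 2
  if (abs(displacement[1]) + R > max(abs(range(grid_x))) ||
      abs(displacement[2]) + R > max(abs(range(grid_y))) ||
      geom$body_z_mm[1] + displacement[3] < grid_z[1] - sp[3] / 2 ||
      geom$body_z_mm[2] + displacement[3] > grid_z[length(grid_z)] + sp[3] / 2) {
    stopf("displaced phantom exceeds the acquisition grid",
          class = "qa4dct_geometry_error")
  }
  ss <- acq$supersampling
  d <- displacement
  vol <- array(-1000, dim = shape)
  bg_hu <- material_hu(geom, geom$background)
  vol <- paint_cylinder(vol, grid_x, grid_y, grid_z, sp,
                        d[1], d[2], geom$body_z_mm[1] + d[3],
                        geom$body_z_mm[2] + d[3], R, bg_hu, ss, cache)
  for (mod in geom$modules) {
    mod_lo <- mod$z_mm - mod$length_mm / 2 + d[3]
    mod_hi <- mod$z_mm + mod$length_mm / 2 + d[3]
    mod_bg <- bg_hu
    if (!is.null(mod$material)) {
      mod_bg <- material_hu(geom, mod$material)
      mod_r <- if (is.na(mod$diameter_mm)) R else mod$diameter_mm / 2
      vol <- paint_cylinder(vol, grid_x, grid_y, grid_z, sp, d[1], d[2],
                            mod_lo, mod_hi, mod_r, mod_bg, ss, cache)
    }
    for (tg in mod$low_contrast_targets %||% list()) {
      th <- tg$theta_deg * pi / 180
      vol <- paint_cylinder(vol, grid_x, grid_y, grid_z, sp,
                            tg$r_mm * cos(th) + d[1],
                            tg$r_mm * sin(th) + d[2],
                            mod_lo, mod_hi, tg$diameter_mm / 2,
                            mod_bg + 10 * tg$contrast_pct, ss, cache)
    }
    for (p in mod$plugs) {
      th <- p$theta_deg * pi / 180
      pz <- mod$z_mm + p$z_mm + d[3]
      vol <- paint_cylinder(vol, grid_x, grid_y, grid_z, sp,
                            p$r_mm * cos(th) + d[1],
                            p$r_mm * sin(th) + d[2],
                            pz - p$length_mm / 2, pz + p$length_mm / 2,
                            p$diameter_mm / 2, material_hu(geom, p$material),
                            ss, cache)
    }
    if (!is.null(mod$markers)) {
      mk <- mod$markers
      for (pos in mk$positions) {
        mz <- mod$z_mm + pos$z_mm + d[3]
        vol <- paint_cylinder(vol, grid_x, grid_y, grid_z, sp,
                              pos$x_mm + d[1], pos$y_mm + d[2],
                              mz - mk$length_mm / 2, mz + mk$length_mm / 2,
                              mk$diameter_mm / 2,
                              material_hu(geom, mk$material), ss, cache)
      }
    }
    if (!is.null(mod$bead)) {
      b <- mod$bead
      vol <- paint_sphere(vol, grid_x, grid_y, grid_z, sp,
                          c(b$x_mm + d[1], b$y_mm + d[2],
                            mod$z_mm + b$z_mm + d[3]),
                          b$diameter_mm / 2, material_hu(geom, b$material), ss)
    }
  }
  if (acq$psf_sigma_mm > 0) {
    vol <- gaussian_blur3(vol, acq$psf_sigma_mm, sp)
  }
  ct_volume(vol, sp, grid$origin_mm,
            meta = list(bin_label = "stationary"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

add_noise <- function(vol, sigma, seed) {
  if (sigma <= 0) return(vol)
  n <- length(vol$voxels)
  vol$voxels <- clamp(vol$voxels +
                        with_seed(seed, stats::rnorm(n, 0, sigma)),
                      HU_MIN, HU_MAX)
  vol
}

#' Simulate a stationary reference scan and a binned 4DCT
#'
#' Renders the stationary volume at zero displacement, then each respiratory
#' bin as the mean of noiseless renderings at the bin's sub-displacements
#' (intra-bin motion blur), and finally adds independent seeded Gaussian
#' noise per volume. Ground truth (per-plug nominal dimensions, per-bin mean
#' displacement, achievable peak-to-peak amplitude) is returned alongside.
#' Bit-reproducible for a fixed `acq$seed`.
#'
#' @param geom A [phantom_geometry()].
#' @param trace A [sinusoid_trace()] / [sampled_trace()].
#' @param binning A [binning_spec()].
#' @param acq An [acquisition_spec()].
#' @return A list of class `qa4dct_simulation`: `stationary` ([ct_volume()]),
#'   `series` ([phase4d_series()]), `ground_truth`, plus the input specs.
#' @export
simulate_4dct <- function(geom, trace, binning = binning_spec(),
                          acq = acquisition_spec()) {
  bins <- sample_trace_bins(trace, binning)
  all_disp <- do.call(rbind, bins)
  extra <- apply(abs(all_disp), 2, max)
  acq_fixed <- acq
  acq_fixed$grid <- acq_grid(geom, acq, extra_margin = extra)
  cache <- new.env(parent = emptyenv())
  seed_base <- (as.numeric(acq$seed) * 1000) %% .Machine$integer.max
  stationary <- render_phantom(geom, c(0, 0, 0), acq_fixed, cache)
  stationary$meta <- list(bin_label = "stationary", series_id = "stationary")
  stationary <- add_noise(stationary, acq$noise_sigma_hu, seed_base)
  vols <- vector("list", binning$n_bins)
  for (k in seq_len(binning$n_bins)) {
    acc <- NULL
    for (j in seq_len(nrow(bins[[k]]))) {
      r <- render_phantom(geom, bins[[k]][j, ], acq_fixed, cache)
      acc <- if (is.null(acc)) r$voxels else acc + r$voxels
    }
    v <- ct_volume(acc / nrow(bins[[k]]), stationary$spacing_mm,
                   stationary$origin_mm,
                   meta = list(bin_label = bin_label_for(k - 1L),
                               bin_index = k - 1L,
                               binning_mode = binning$mode,
                               series_id = bin_label_for(k - 1L)))
    vols[[k]] <- add_noise(v, acq$noise_sigma_hu, seed_base + k)
  }
  plugs <- find_plug(geom)
  plug_dims <- do.call(rbind, lapply(plugs, function(p) {
    data.frame(plug_id = p$id, x_mm = p$diameter_mm, y_mm = p$diameter_mm,
               z_mm = p$length_mm)
  }))
  gt <- list(
    plug_dims = plug_dims,
    bin_displacements = t(vapply(bins, colMeans, numeric(3))),
    sub_displacements = all_disp,
    achievable_p2p_mm = apply(all_disp, 2, function(v) max(v) - min(v)),
    trace_p2p_mm = trace_peak_to_peak(trace)
  )
  structure(list(stationary = stationary,
                 series = phase4d_series(vols, mode = binning$mode),
                 ground_truth = gt, trace = trace, binning = binning,
                 acq = acq_fixed),
            class = "qa4dct_simulation")
}

#' Write a simulation to disk as a series tree
#'
#' Writes the stationary volume and every bin through [write_series()] with
#' a ground-truth sidecar embedded in the manifest.
#'
#' @param sim A `qa4dct_simulation` from [simulate_4dct()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  gt <- sim$ground_truth
  gt$bin_displacements <- as.data.frame(gt$bin_displacements)
  gt$sub_displacements <- as.data.frame(gt$sub_displacements)
  write_series(c(list(sim$stationary), sim$series$volumes), path,
               extra = list(ground_truth = gt))
}
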