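#' Phantom and plug localization
#'
#' Localization proceeds in two stages: [locate_phantom()] estimates the
#' phantom pose (origin position plus in-plane rotation) from the
#' body-threshold mask, then [detect_plug()] / [measure_plug_dimensions()]
#' segment individual plugs by HU thresholding inside a search box seeded at
#' the expected plug position and measure centroid, per-axis FWHM and ROI HU
#' statistics.
#'
#' @name localization
NULL

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# world position of a phantom-frame point under a pose
pose_transform <- function(pose, pos) {
  as.numeric(rot_z(pose$rotation_deg) %*% pos) + pose$center_mm
}

# index ranges of an axis-aligned box (clamped to the volume)
box_indices <- function(vol, center_mm, half_mm) {
  d <- dim(vol$voxels)
  out <- vector("list", 3)
  for (a in 1:3) {
    coords <- axis_coords(vol, a)
    idx <- which(coords >= center_mm[a] - half_mm[a] &
                   coords <= center_mm[a] + half_mm[a])
    if (!length(idx)) {
      stopf("search box along axis %d lies outside the volume", a,
            class = "qa4dct_detection_error")
    }
    out[[a]] <- idx
  }
  out
}

# largest 6-connected component of a logical 3D array (iterative BFS on
# linear indices; arrays here are small search boxes)
largest_component <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  labels <- integer(n)
  idx_all <- which(mask)
  if (!length(idx_all)) return(mask & FALSE)
  nxy <- d[1] * d[2]
  current <- 0L
  best <- integer(0)
  remaining <- idx_all
  in_mask <- logical(n)
  in_mask[idx_all] <- TRUE
  visited <- logical(n)
  for (seed in idx_all) {
    if (visited[seed]) next
    current <- current + 1L
    comp <- seed
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier)) {
      ii <- frontier - 1L
      x <- ii %% d[1]
      y <- (ii %/% d[1]) %% d[2]
      z <- ii %/% nxy
      nb <- c(frontier[x > 0] - 1L, frontier[x < d[1] - 1L] + 1L,
              frontier[y > 0] - d[1], frontier[y < d[2] - 1L] + d[1],
              frontier[z > 0] - nxy, frontier[z < d[3] - 1L] + nxy)
      nb <- unique(nb)
      nb <- nb[in_mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- array(FALSE, dim = d)
  out[best] <- TRUE
  out
}

# directional erosion by one voxel along one axis
erode_axis <- function(mask, axis) {
  d <- dim(mask)
  pads <- d
  pads[axis] <- d[axis] + 2L
  pad <- array(FALSE, pads)
  il <- lapply(1:3, function(a) {
    if (a == axis) 1L + seq_len(d[a]) else seq_len(d[a])
  })
  pad[il[[1]], il[[2]], il[[3]]] <- mask
  sel <- function(off) {
    j <- il
    j[[axis]] <- j[[axis]] + off
    pad[j[[1]], j[[2]], j[[3]], drop = FALSE]
  }
  array(sel(0L) & sel(-1L) & sel(1L), dim = d)
}

# erode a physical rim (at least one voxel per axis) off a region so the
# remaining core excludes partial-volume and blur-ramp voxels
erode_rim <- function(mask, spacing, rim_mm = 1.8) {
  for (axis in 1:3) {
    k <- ceiling(rim_mm / spacing[axis])
    for (i in seq_len(k)) mask <- erode_axis(mask, axis)
  }
  mask
}

# erode a logical array by one voxel (6-neighborhood)
erode1 <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core
}

#' Locate the phantom in a volume
#'
#' The pose center is the centroid of the body-threshold mask (HU above the
#' air/background midpoint) shifted by the known offset between the body
#' cylinder center and the phantom origin. The in-plane rotation is
#' estimated from the distance-marker constellation when the markers are
#' resolvable, otherwise 0.
#'
#' @param vol A [ct_volume()].
#' @param geom The [phantom_geometry()].
#' @return A `phantom_pose`: `list(center_mm, rotation_deg)`.
#' @export
locate_phantom <- function(vol, geom) {
  bg_hu <- material_hu(geom, geom$background)
  thr <- (material_hu(geom, "air") + bg_hu) / 2
  # tiny offset so partial-volume voxels sitting exactly at the midpoint
  # level are excluded deterministically rather than by rounding noise
  mask <- vol$voxels > thr + 1e-3
  n <- sum(mask)
  # require at least ~5% of the nominal body volume to call it a phantom
  body_vox <- pi * (geom$outer_diameter_mm / 2)^2 * diff(geom$body_z_mm) /
    prod(vol$spacing_mm)
  if (n < 0.05 * body_vox) {
    stopf("no phantom-like object found (body mask has %d voxels)", n,
          class = "qa4dct_detection_error")
  }
  idx <- which(mask)
  d <- dim(vol$voxels)
  ii <- idx - 1L
  cx <- mean(axis_coords(vol, 1)[ii %% d[1] + 1L])
  cy <- mean(axis_coords(vol, 2)[(ii %/% d[1]) %% d[2] + 1L])
  cz <- mean(axis_coords(vol, 3)[ii %/% (d[1] * d[2]) + 1L])
  center <- c(cx, cy, cz) - body_center(geom)
  pose <- list(center_mm = center, rotation_deg = 0)
  rot <- tryCatch(estimate_rotation(vol, pose, geom), error = function(e) 0)
  pose$rotation_deg <- rot
  class(pose) <- "phantom_pose"
  pose
}

# rotation about Z from the marker constellation (mean wrapped angular
# offset of detected marker centroids vs their nominal angles)
estimate_rotation <- function(vol, pose, geom) {
  mod <- geometry_module(geom, "sensitometry")
  mk <- mod$markers
  if (is.null(mk) || length(mk$positions) < 2L) return(0)
  offs <- numeric(0)
  for (pos in mk$positions) {
    nominal <- c(pos$x_mm, pos$y_mm, mod$z_mm + pos$z_mm)
    cen <- marker_centroid(vol, pose, geom, nominal, mk)
    a_obs <- atan2(cen[2] - pose$center_mm[2], cen[1] - pose$center_mm[1])
    a_nom <- atan2(nominal[2], nominal[1])
    da <- (a_obs - a_nom + pi) %% (2 * pi) - pi
    offs <- c(offs, da)
  }
  deg <- mean(offs) * 180 / pi
  if (abs(deg) > 10) 0 else deg
}

marker_centroid <- function(vol, pose, geom, nominal, mk) {
  bg_hu <- material_hu(geom, geom$background)
  thr <- (material_hu(geom, mk$material) + bg_hu) / 2
  expected <- pose_transform(pose, nominal)
  half <- c(mk$diameter_mm / 2 + 4, mk$diameter_mm / 2 + 4,
            mk$length_mm / 2 + 5)
  bi <- box_indices(vol, expected, half)
  sub <- vol$voxels[bi[[1]], bi[[2]], bi[[3]], drop = FALSE]
  mask <- sub > thr
  if (!any(mask)) {
    stopf("marker not found near (%.1f, %.1f, %.1f) mm", expected[1],
          expected[2], expected[3], class = "qa4dct_detection_error")
  }
  mask <- largest_component(mask)
  region_centroid(vol, bi, mask)
}

region_centroid <- function(vol, bi, mask) {
  idx <- which(mask)
  d <- dim(mask)
  ii <- idx - 1L
  xs <- axis_coords(vol, 1)[bi[[1]]]
  ys <- axis_coords(vol, 2)[bi[[2]]]
  zs <- axis_coords(vol, 3)[bi[[3]]]
  c(mean(xs[ii %% d[1] + 1L]),
    mean(ys[(ii %/% d[1]) %% d[2] + 1L]),
    mean(zs[ii %/% (d[1] * d[2]) + 1L]))
}

#' Detect and measure one plug by HU thresholding
#'
#' The threshold is the midpoint of the plug's nominal HU and the local
#' background nominal HU; voxels beyond the threshold (above for plugs denser
#' than background, below for air-like plugs) inside a search box around the
#' expected position form the candidate region, of which the largest
#' 6-connected component is kept. The centroid is the unweighted centroid of
#' the region voxels; mean/sd HU are computed over the region core obtained
#' by eroding a ~1.8 mm rim (at least one voxel per axis) to exclude
#' partial-volume and blur-ramp voxels.
#'
#' @param vol A [ct_volume()].
#' @param pose A `phantom_pose` from [locate_phantom()].
#' @param plug A `plug_spec` as returned by [find_plug()].
#' @param geom The [phantom_geometry()].
#' @param xy_margin,z_margin Search-box margins in mm beyond the nominal plug
#'   half-extent; `xy_margin` defaults to half the plug diameter (capped at
#'   6 mm) so neighboring objects stay outside the box; widen `z_margin`
#'   when measuring motion-smeared projections.
#' @return A `plug_measurement`: plug id, bin label, `centroid_mm`,
#'   `fwhm_mm` (NA until [measure_plug_dimensions()]), `mean_hu`, `sd_hu`,
#'   `threshold_hu`, `n_voxels`, `boundary_flag`.
#' @export
detect_plug <- function(vol, pose, plug, geom, xy_margin = NULL,
                        z_margin = 8) {
  xy_margin <- xy_margin %||% min(6, plug$diameter_mm / 2)
  bg_name <- plug$module_material %||% geom$background
  bg_hu <- material_hu(geom, bg_name)
  plug_hu <- material_hu(geom, plug$material)
  thr <- (plug_hu + bg_hu) / 2
  above <- plug_hu > bg_hu
  expected <- pose_transform(pose, plug_center(plug))
  half <- c(plug$diameter_mm / 2 + xy_margin, plug$diameter_mm / 2 + xy_margin,
            plug$length_mm / 2 + z_margin)
  bi <- box_indices(vol, expected, half)
  sub <- vol$voxels[bi[[1]], bi[[2]], bi[[3]], drop = FALSE]
  mask <- if (above) sub > thr + 1e-3 else sub < thr - 1e-3
  if (!any(mask)) {
    stopf("plug '%s' not detected near (%.1f, %.1f, %.1f) mm", plug$id,
          expected[1], expected[2], expected[3],
          class = "qa4dct_detection_error")
  }
  mask <- largest_component(mask)
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  boundary <- any(idx[, 1] %in% c(1L, d[1])) ||
    any(idx[, 2] %in% c(1L, d[2])) || any(idx[, 3] %in% c(1L, d[3]))
  core <- erode_rim(mask, vol$spacing_mm)
  if (!any(core)) core <- erode1(mask)
  if (!any(core)) core <- mask
  vals <- sub[core]
  structure(list(plug_id = plug$id,
                 bin_label = vol$meta$bin_label %||% NA_character_,
                 centroid_mm = region_centroid(vol, bi, mask),
                 fwhm_mm = c(NA_real_, NA_real_, NA_real_),
                 mean_hu = mean(vals), sd_hu = stats::sd(vals),
                 threshold_hu = thr, n_voxels = sum(mask),
                 boundary_flag = boundary, box = bi),
            class = "plug_measurement")
}

#' Full width at half maximum of an HU profile
#'
#' The half level is `baseline + (peak - baseline) / 2`. Scanning outward
#' from the profile extremum, the outermost crossings of the half level on
#' each side are located by linear interpolation between adjacent samples
#' (ties broken toward the wider width); the width is the distance between
#' the two crossings. Profiles with `peak < baseline` (air-like dips) are
#' handled by negation and give the same width as their mirrored positive
#' counterpart.
#'
#' @param values Numeric HU samples.
#' @param positions Strictly increasing mm coordinates, same length.
#' @param baseline_hu,peak_hu Baseline and peak level defining the half
#'   maximum.
#' @return Width in mm.
#' @export
fwhm_profile <- function(values, positions, baseline_hu, peak_hu) {
  n <- length(values)
  stopifnot(length(positions) == n, n >= 2L)
  if (any(diff(positions) <= 0)) {
    stopf("positions must be strictly increasing",
          class = "qa4dct_validation_error")
  }
  if (peak_hu == baseline_hu) {
    stopf("peak equals baseline; half level undefined",
          class = "qa4dct_validation_error")
  }
  sgn <- if (peak_hu > baseline_hu) 1 else -1
  v <- sgn * values
  level <- sgn * (baseline_hu + (peak_hu - baseline_hu) / 2)
  imax <- which.max(v)
  if (v[imax] < level) {
    stopf("profile never attains the half level",
          class = "qa4dct_profile_truncation_error")
  }
  cross_out <- function(side) {
    if (side == "right") {
      i <- imax:(n - 1L)
      ok <- v[i] >= level & v[i + 1L] < level
      if (!any(ok)) {
        stopf("half level never crossed on the right of the extremum",
              class = "qa4dct_profile_truncation_error")
      }
      j <- max(i[ok])
      t <- (level - v[j]) / (v[j + 1L] - v[j])
      positions[j] + t * (positions[j + 1L] - positions[j])
    } else {
      if (imax == 1L) {
        stopf("half level never crossed on the left of the extremum",
              class = "qa4dct_profile_truncation_error")
      }
      i <- (imax - 1L):1L
      ok <- v[i] < level & v[i + 1L] >= level
      if (!any(ok)) {
        stopf("half level never crossed on the left of the extremum",
              class = "qa4dct_profile_truncation_error")
      }
      j <- min(i[ok])
      t <- (level - v[j]) / (v[j + 1L] - v[j])
      positions[j] + t * (positions[j + 1L] - positions[j])
    }
  }
  cross_out("right") - cross_out("left")
}

#' Measure plug dimensions by FWHM profiling
#'
#' Runs [detect_plug()], extracts axis-parallel profiles through the region
#' centroid (each averaged over a 3x3 perpendicular voxel neighborhood to
#' stabilize noisy bins), and applies [fwhm_profile()] per axis with the
#' local background nominal HU as baseline and the profile extremum as peak.
#'
#' @inheritParams detect_plug
#' @return A `plug_measurement` with `fwhm_mm` filled.
#' @export
measure_plug_dimensions <- function(vol, pose, plug, geom, xy_margin = NULL,
                                    z_margin = 8) {
  meas <- detect_plug(vol, pose, plug, geom, xy_margin, z_margin)
  bg_name <- plug$module_material %||% geom$background
  bg_hu <- material_hu(geom, bg_name)
  plug_hu <- material_hu(geom, plug$material)
  d <- dim(vol$voxels)
  ci <- vapply(1:3, function(a) {
    which.min(abs(axis_coords(vol, a) - meas$centroid_mm[a]))
  }, integer(1))
  bi <- meas$box
  for (axis in 1:3) {
    perp <- setdiff(1:3, axis)
    n1 <- clamp((ci[perp[1]] - 1L):(ci[perp[1]] + 1L), 1L, d[perp[1]])
    n2 <- clamp((ci[perp[2]] - 1L):(ci[perp[2]] + 1L), 1L, d[perp[2]])
    idx <- list(NULL, NULL, NULL)
    idx[[axis]] <- bi[[axis]]
    idx[[perp[1]]] <- unique(n1)
    idx[[perp[2]]] <- unique(n2)
    sub <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    prof <- apply(sub, axis, mean)
    pos <- axis_coords(vol, axis)[bi[[axis]]]
    peak <- if (plug_hu > bg_hu) max(prof) else min(prof)
    w <- tryCatch(fwhm_profile(prof, pos, bg_hu, peak), error = function(e) {
      stopf("plug '%s', axis %s: %s", plug$id, c("X", "Y", "Z")[axis],
            conditionMessage(e), class = class(e)[1])
    })
    meas$fwhm_mm[axis] <- w
  }
  meas
}
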