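#' Independent contour-based plug measurement
#'
#' A deliberately independent re-measurement of plug dimensions and
#' centroids used to cross-validate the thresholding/FWHM pipeline, in the
#' spirit of a manual contour-based analysis in a treatment-planning system:
#' the plug is contoured at the same half-maximum HU level (midpoint of the
#' nominal plug and background HU), and each dimension is the bounding
#' extent of the iso-contour along that axis — every grid line parallel to
#' the axis is scanned for its outermost sub-voxel level crossings and the
#' maximum extent over lines is reported. No connected-component filtering,
#' profile averaging or erosion is shared with the pipeline.
#'
#' @param vol A [ct_volume()].
#' @param pose The phantom pose.
#' @param plug A `plug_spec` from [find_plug()].
#' @param geom The [phantom_geometry()].
#' @param xy_margin,z_margin Search-box margins in mm.
#' @return List with `extents_mm` (length 3) and `centroid_mm` (binary
#'   centroid of all voxels beyond the level).
#' @export
contour_plug_measure <- function(vol, pose, plug, geom, xy_margin = NULL,
                                 z_margin = 8) {
  xy_margin <- xy_margin %||% min(6, plug$diameter_mm / 2)
  bg_hu <- material_hu(geom, plug$module_material %||% geom$background)
  plug_hu <- material_hu(geom, plug$material)
  level <- (plug_hu + bg_hu) / 2
  sgn <- if (plug_hu > bg_hu) 1 else -1
  expected <- pose_transform(pose, plug_center(plug))
  half <- c(plug$diameter_mm / 2 + xy_margin, plug$diameter_mm / 2 + xy_margin,
            plug$length_mm / 2 + z_margin)
  bi <- box_indices(vol, expected, half)
  sub <- sgn * vol$voxels[bi[[1]], bi[[2]], bi[[3]], drop = FALSE]
  lvl <- sgn * level
  d <- dim(sub)
  coords <- lapply(1:3, function(a) axis_coords(vol, a)[bi[[a]]])
  extents <- numeric(3)
  for (axis in 1:3) {
    perp <- setdiff(1:3, axis)
    pos <- coords[[axis]]
    best <- 0
    for (i in seq_len(d[perp[1]])) {
      for (j in seq_len(d[perp[2]])) {
        v <- switch(axis,
                    `1` = sub[, i, j],
                    `2` = sub[i, , j],
                    `3` = sub[i, j, ])
        inside <- which(v >= lvl)
        if (!length(inside)) next
        i0 <- min(inside)
        i1 <- max(inside)
        left <- if (i0 == 1L) pos[1] else {
          t <- (lvl - v[i0 - 1L]) / (v[i0] - v[i0 - 1L])
          pos[i0 - 1L] + t * (pos[i0] - pos[i0 - 1L])
        }
        right <- if (i1 == length(v)) pos[length(v)] else {
          t <- (v[i1] - lvl) / (v[i1] - v[i1 + 1L])
          pos[i1] + t * (pos[i1 + 1L] - pos[i1])
        }
        best <- max(best, right - left)
      }
    }
    if (best <= 0) {
      stopf("iso-contour for plug '%s' empty along axis %d", plug$id, axis,
            class = "qa4dct_detection_error")
    }
    extents[axis] <- best
  }
  mask <- sub >= lvl
  list(extents_mm = extents,
       centroid_mm = region_centroid(vol, bi, mask))
}
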