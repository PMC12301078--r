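# Synthetic Gaussian point-spread volume on a fine grid, with a matching
# geometry whose bead is point-like, used as the closed-form MTF oracle:
# a Gaussian PSF of width sigma has f10 = sqrt(ln 10 / (2 pi^2 sigma^2)).
psf_test_geometry <- function(bead_diameter = 0.01) {
  phantom_geometry(
    model = 504, outer_diameter_mm = 30, body_z_mm = c(-40, 40),
    background = "phantom_body", materials = qa4dct:::default_materials(),
    modules = list(
      module_spec("sensitometry", z_mm = -30, length_mm = 10),
      module_spec("spatial_resolution", z_mm = 0, length_mm = 10,
                  bead = list(x_mm = 0, y_mm = 0, z_mm = 0,
                              diameter_mm = bead_diameter,
                              material = "bead_metal")),
      module_spec("uniformity", z_mm = 30, length_mm = 10)
    )
  )
}

gaussian_psf_volume <- function(sigma_mm, spacing_xy = 0.25) {
  n <- 81L
  xs <- (seq_len(n) - (n + 1) / 2) * spacing_xy
  blob <- 1000 * exp(-outer(xs^2, xs^2, "+") / (2 * sigma_mm^2))
  vox <- array(0, dim = c(n, n, 3))
  vox[, , 2] <- blob
  ct_volume(vox, c(spacing_xy, spacing_xy, 1),
            origin_mm = c(xs[1], xs[1], -1))
}

origin_pose <- list(center_mm = c(0, 0, 0), rotation_deg = 0)

gaussian_mtf10 <- function(sigma_mm) 10 * sqrt(log(10) / (2 * pi^2 * sigma_mm^2))

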