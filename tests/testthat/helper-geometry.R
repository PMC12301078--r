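# Desk-scale phantom geometries for fast tests. The small geometry keeps the
# full module structure (sensitometry ring, markers, bead, low-contrast
# targets, uniformity cylinder) at roughly one-third linear scale so a
# render takes a fraction of a second.

small_geometry <- function() {
  plugs <- list(
    plug_spec("teflon", "teflon", 8, 12, 20, 0,
              roles = c("motion_surrogate", "hu_constancy")),
    plug_spec("air", "air", 8, 12, 20, 90,
              roles = c("motion_surrogate", "hu_constancy")),
    plug_spec("ldpe", "ldpe", 8, 12, 20, 180,
              roles = c("hu_constancy", "cnr_pair_member")),
    plug_spec("polystyrene", "polystyrene", 8, 12, 20, 240,
              roles = c("hu_constancy", "cnr_pair_member")),
    plug_spec("acrylic", "acrylic", 8, 12, 20, 300, roles = "hu_constancy")
  )
  markers <- list(material = "teflon", diameter_mm = 3, length_mm = 8,
                  nominal_spacing_mm = 16,
                  positions = list(list(x_mm = 8, y_mm = 8, z_mm = 0),
                                   list(x_mm = -8, y_mm = 8, z_mm = 0),
                                   list(x_mm = -8, y_mm = -8, z_mm = 0),
                                   list(x_mm = 8, y_mm = -8, z_mm = 0)))
  lc <- lapply(seq_along(c(8, 5, 3)), function(i) {
    list(diameter_mm = c(8, 5, 3)[i], contrast_pct = 1.0, r_mm = 14,
         theta_deg = (i - 1) * 120)
  })
  phantom_geometry(
    model = 504, outer_diameter_mm = 70, body_z_mm = c(-30, 52),
    background = "phantom_body",
    materials = qa4dct:::default_materials(),
    modules = list(
      module_spec("low_contrast", z_mm = -18, length_mm = 12,
                  low_contrast_targets = lc),
      module_spec("sensitometry", z_mm = 0, length_mm = 24, plugs = plugs,
                  markers = markers),
      module_spec("spatial_resolution", z_mm = 18, length_mm = 12,
                  bead = list(x_mm = 0, y_mm = 10, z_mm = 0,
                              diameter_mm = 1.0, material = "bead_metal")),
      module_spec("uniformity", z_mm = 38, length_mm = 24, diameter_mm = 50,
                  material = "water_equivalent")
    )
  )
}

# Minimal two-plug phantom for surgical synthesis tests.
tiny_geometry <- function() {
  phantom_geometry(
    model = 504, outer_diameter_mm = 40, body_z_mm = c(-15, 15),
    background = "phantom_body",
    materials = qa4dct:::default_materials(),
    modules = list(
      module_spec("sensitometry", z_mm = 0, length_mm = 20,
                  plugs = list(
                    plug_spec("teflon", "teflon", 8, 10, 10, 0,
                              roles = "motion_surrogate"),
                    plug_spec("air", "air", 8, 10, 10, 180,
                              roles = "motion_surrogate"))),
      module_spec("uniformity", z_mm = 12.5, length_mm = 5)
    )
  )
}

# Tiny phantom carrying only the CNR plug pair (degenerate-noise checks).
tiny_cnr_geometry <- function() {
  phantom_geometry(
    model = 504, outer_diameter_mm = 40, body_z_mm = c(-15, 15),
    background = "phantom_body",
    materials = qa4dct:::default_materials(),
    modules = list(
      module_spec("sensitometry", z_mm = 0, length_mm = 20,
                  plugs = list(
                    plug_spec("polystyrene", "polystyrene", 8, 10, 10, 0,
                              roles = "cnr_pair_member"),
                    plug_spec("ldpe", "ldpe", 8, 10, 10, 180,
                              roles = "cnr_pair_member"))),
      module_spec("uniformity", z_mm = 12.5, length_mm = 5)
    )
  )
}

noiseless_acq <- function(...) {
  acquisition_spec(noise_sigma_hu = 0, ...)
}

sharp_acq <- function(...) {
  acquisition_spec(noise_sigma_hu = 0, psf_sigma_mm = 0, ...)
}
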