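#' Phantom geometry model
#'
#' A `phantom_geometry` is a declarative description of a Catphan-style
#' cylindrical image-quality phantom: a material table, a solid background
#' cylinder, and a list of axial modules carrying sensitometry plugs, distance
#' markers, a point-spread bead, and low-contrast targets. The same geometry
#' object drives both synthetic rendering ([render_phantom()]) and analysis
#' (expected positions and nominal HU seed plug localization).
#'
#' Coordinates are right-handed patient-style axes: X lateral, Y
#' anterior-posterior, Z axial (the table / principal motion direction). All
#' positions are in mm relative to the phantom coordinate origin, which is the
#' center of the sensitometry module. In-plane positions of plugs and targets
#' are polar: `r_mm` radial offset and `theta_deg` measured counter-clockwise
#' from +X.
#'
#' @name phantom_geometry
NULL

#' Create a material specification
#'
#' @param name Material label, unique within a geometry.
#' @param nominal_hu Nominal CT number in Hounsfield units, within
#'   \[-1024, 3071\].
#' @return A `material_spec` list.
#' @export
material_spec <- function(name, nominal_hu) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_number(nominal_hu, "nominal_hu", min = HU_MIN, max = HU_MAX)
  structure(list(name = name, nominal_hu = as.numeric(nominal_hu)),
            class = "material_spec")
}

#' Create a plug specification
#'
#' Plugs are z-aligned cylinders inside a module. Roles mark how the analysis
#' uses a plug: `motion_surrogate` (high-contrast target tracked across bins),
#' `hu_constancy` (compared against its nominal HU), `cnr_pair_member`
#' (enters the low-contrast CNR pair).
#'
#' @param id Plug identifier (conventionally the material name).
#' @param material Material name, must exist in the geometry material table.
#' @param diameter_mm,length_mm Cylinder diameter and axial length in mm.
#' @param r_mm,theta_deg,z_mm Polar in-plane position and axial offset
#'   relative to the module center.
#' @param roles Character vector drawn from
#'   `c("motion_surrogate", "hu_constancy", "cnr_pair_member")`.
#' @return A `plug_spec` list.
#' @export
plug_spec <- function(id, material, diameter_mm, length_mm,
                      r_mm, theta_deg, z_mm = 0, roles = character()) {
  stopifnot(is.character(id), length(id) == 1L, is.character(material))
  check_number(diameter_mm, "diameter_mm", min = 1e-6)
  check_number(length_mm, "length_mm", min = 1e-6)
  check_number(r_mm, "r_mm", min = 0)
  check_number(theta_deg, "theta_deg")
  check_number(z_mm, "z_mm")
  allowed <- c("motion_surrogate", "hu_constancy", "cnr_pair_member")
  bad <- setdiff(roles, allowed)
  if (length(bad)) {
    stopf("unknown plug role(s): %s", paste(bad, collapse = ", "),
          class = "qa4dct_validation_error")
  }
  structure(list(id = id, material = material,
                 diameter_mm = as.numeric(diameter_mm),
                 length_mm = as.numeric(length_mm),
                 r_mm = as.numeric(r_mm), theta_deg = as.numeric(theta_deg),
                 z_mm = as.numeric(z_mm), roles = as.character(roles)),
            class = "plug_spec")
}

#' Create a module specification
#'
#' @param name One of `"sensitometry"`, `"uniformity"`,
#'   `"spatial_resolution"`, `"low_contrast"`.
#' @param z_mm Axial position of the module center relative to the phantom
#'   origin (sensitometry module center).
#' @param length_mm Axial extent of the module.
#' @param diameter_mm Diameter of the module region (defaults to the phantom
#'   outer diameter when `NA`).
#' @param material Optional material name filling the module region; `NULL`
#'   means the module is made of the phantom background material and only its
#'   features are rendered.
#' @param plugs List of [plug_spec()] objects.
#' @param bead Optional list `list(x_mm, y_mm, z_mm, diameter_mm, material)`
#'   describing the point-spread bead (spatial-resolution module only).
#' @param markers Optional list `list(material, diameter_mm, length_mm,
#'   nominal_spacing_mm, positions)` where `positions` is a list of
#'   `list(x_mm, y_mm, z_mm)` module-relative marker positions; markers are
#'   rendered as short z-aligned rods so their in-plane centroids stay sharp
#'   under axial motion blur.
#' @param low_contrast_targets Optional list of
#'   `list(diameter_mm, contrast_pct, r_mm, theta_deg)` supra-slice targets;
#'   a target's HU is background + 10 HU per percent nominal contrast.
#' @return A `module_spec` list.
#' @export
module_spec <- function(name, z_mm, length_mm, diameter_mm = NA,
                        material = NULL, plugs = list(), bead = NULL,
                        markers = NULL, low_contrast_targets = NULL) {
  name <- match.arg(name, c("sensitometry", "uniformity",
                            "spatial_resolution", "low_contrast"))
  check_number(z_mm, "z_mm")
  check_number(length_mm, "length_mm", min = 1e-6)
  structure(list(name = name, z_mm = as.numeric(z_mm),
                 length_mm = as.numeric(length_mm),
                 diameter_mm = as.numeric(diameter_mm),
                 material = material, plugs = plugs, bead = bead,
                 markers = markers,
                 low_contrast_targets = low_contrast_targets),
            class = "module_spec")
}

#' Create a phantom geometry
#'
#' @param model Phantom model label, `504` or `604`.
#' @param outer_diameter_mm Outer diameter of the phantom body cylinder.
#' @param body_z_mm Length-2 numeric, axial range `(zmin, zmax)` of the body
#'   cylinder relative to the phantom origin.
#' @param background Material name of the body.
#' @param materials List of [material_spec()] objects.
#' @param modules List of [module_spec()] objects.
#' @return A validated `phantom_geometry`.
#' @export
phantom_geometry <- function(model, outer_diameter_mm, body_z_mm,
                             background, materials, modules) {
  geom <- structure(list(model = as.integer(model),
                         outer_diameter_mm = as.numeric(outer_diameter_mm),
                         body_z_mm = as.numeric(body_z_mm),
                         background = background,
                         materials = materials, modules = modules),
                    class = "phantom_geometry")
  validate_geometry(geom)
}

#' Validate a phantom geometry
#'
#' Checks all structural invariants: unique material names with HU in the CT
#' dynamic range, every referenced material present, plugs inside the body
#' radius, non-overlapping module z-ranges, bead only in the
#' spatial-resolution module, and exactly one sensitometry and one uniformity
#' module.
#'
#' @param geom A `phantom_geometry`.
#' @return The geometry, invisibly unchanged, or an error of class
#'   `qa4dct_validation_error` naming the offending field.
#' @export
validate_geometry <- function(geom) {
  if (!inherits(geom, "phantom_geometry")) {
    stopf("not a phantom_geometry", class = "qa4dct_validation_error")
  }
  mats <- vapply(geom$materials, function(m) m$name, character(1))
  if (anyDuplicated(mats)) {
    stopf("duplicate material names: %s",
          paste(unique(mats[duplicated(mats)]), collapse = ", "),
          class = "qa4dct_validation_error")
  }
  for (m in geom$materials) {
    check_number(m$nominal_hu, paste0("materials[", m$name, "].nominal_hu"),
                 min = HU_MIN, max = HU_MAX)
  }
  check_number(geom$outer_diameter_mm, "outer_diameter_mm", min = 1e-6)
  check_number(geom$body_z_mm, "body_z_mm", len = 2L)
  if (diff(geom$body_z_mm) <= 0) {
    stopf("body_z_mm must be increasing", class = "qa4dct_validation_error")
  }
  if (!geom$background %in% mats) {
    stopf("background material '%s' not in material table", geom$background,
          class = "qa4dct_validation_error")
  }
  radius <- geom$outer_diameter_mm / 2
  mod_names <- vapply(geom$modules, function(m) m$name, character(1))
  if (sum(mod_names == "sensitometry") != 1L ||
      sum(mod_names == "uniformity") != 1L) {
    stopf("geometry must contain exactly one sensitometry and one uniformity module",
          class = "qa4dct_validation_error")
  }
  ranges <- t(vapply(geom$modules, function(m) {
    c(m$z_mm - m$length_mm / 2, m$z_mm + m$length_mm / 2)
  }, numeric(2)))
  ord <- order(ranges[, 1])
  ranges <- ranges[ord, , drop = FALSE]
  if (nrow(ranges) > 1 && any(ranges[-1, 1] < ranges[-nrow(ranges), 2] - 1e-9)) {
    stopf("module z-ranges overlap", class = "qa4dct_validation_error")
  }
  for (mod in geom$modules) {
    if (!is.null(mod$bead) && mod$name != "spatial_resolution") {
      stopf("bead present in module '%s' (allowed only in spatial_resolution)",
            mod$name, class = "qa4dct_validation_error")
    }
    if (!is.null(mod$material) && !mod$material %in% mats) {
      stopf("module '%s' material '%s' not in material table",
            mod$name, mod$material, class = "qa4dct_validation_error")
    }
    ids <- vapply(mod$plugs, function(p) p$id, character(1))
    if (anyDuplicated(ids)) {
      stopf("duplicate plug ids in module '%s'", mod$name,
            class = "qa4dct_validation_error")
    }
    for (p in mod$plugs) {
      if (!p$material %in% mats) {
        stopf("plug '%s' references unknown material '%s'", p$id, p$material,
              class = "qa4dct_validation_error")
      }
      if (p$r_mm + p$diameter_mm / 2 > radius + 1e-9) {
        stopf("plug '%s': radial offset + diameter/2 (%.1f mm) exceeds phantom radius (%.1f mm)",
              p$id, p$r_mm + p$diameter_mm / 2, radius,
              class = "qa4dct_validation_error")
      }
    }
    if (!is.null(mod$bead) && !mod$bead$material %in% mats) {
      stopf("bead references unknown material '%s'", mod$bead$material,
            class = "qa4dct_validation_error")
    }
    if (!is.null(mod$markers) && !mod$markers$material %in% mats) {
      stopf("markers reference unknown material '%s'", mod$markers$material,
            class = "qa4dct_validation_error")
    }
  }
  invisible(geom)
}

# Default nominal HU table. Air, LDPE and acrylic carry the conventional
# acceptance values used for HU constancy; the remaining entries are
# configuration defaults and can be overridden in a geometry config.
default_materials <- function() {
  list(
    material_spec("phantom_body", 100),
    material_spec("water_equivalent", 10),
    material_spec("air", -1000),
    material_spec("teflon", 990),
    material_spec("ldpe", -100),
    material_spec("polystyrene", -35),
    material_spec("acrylic", 120),
    material_spec("pmp", -200),
    material_spec("delrin", 340),
    material_spec("bead_metal", 3000)
  )
}

#' Built-in Catphan-style geometries
#'
#' Returns the packaged geometry for phantom model 504 or 604 with
#' manufacturer-nominal sensitometry plug dimensions (12.3 mm diameter,
#' 25.0 mm length; the model-604 air plug is 33.0 mm long). The sensitometry
#' module carries Teflon, Air, LDPE, polystyrene, acrylic and PMP plugs
#' (plus Delrin for model 604) on a 58.4 mm ring, four Teflon distance rods
#' with 50 mm nominal spacing, the spatial-resolution module a 1 mm metal
#' bead, the low-contrast module supra-slice target sets at 1.0/0.5/0.3%
#' nominal contrast, and the uniformity module a 150 mm water-equivalent
#' cylinder. Angular positions, marker spacing and target sizes follow common
#' Catphan CTP404/CTP486/CTP515/CTP528 conventions and are configuration
#' defaults, overridable via [load_geometry()].
#'
#' @param model `504` or `604`.
#' @return A validated [phantom_geometry()].
#' @export
#' @examples
#' g <- builtin_geometry(504)
#' find_plug(g, "teflon")$length_mm
builtin_geometry <- function(model) {
  model <- as.integer(model)
  if (!model %in% c(504L, 604L)) {
    stopf("unknown phantom model '%s' (supported: 504, 604)", model,
          class = "qa4dct_value_error")
  }
  ring <- 58.4
  air_len <- if (model == 604L) 33.0 else 25.0
  plugs <- list(
    plug_spec("teflon", "teflon", 12.3, 25.0, ring, 0,
              roles = c("motion_surrogate", "hu_constancy")),
    plug_spec("air", "air", 12.3, air_len, ring, 90,
              roles = c("motion_surrogate", "hu_constancy")),
    plug_spec("pmp", "pmp", 12.3, 25.0, ring, 150,
              roles = "hu_constancy"),
    plug_spec("ldpe", "ldpe", 12.3, 25.0, ring, 180,
              roles = c("hu_constancy", "cnr_pair_member")),
    plug_spec("polystyrene", "polystyrene", 12.3, 25.0, ring, 240,
              roles = c("hu_constancy", "cnr_pair_member")),
    plug_spec("acrylic", "acrylic", 12.3, 25.0, ring, 300,
              roles = "hu_constancy")
  )
  if (model == 604L) {
    plugs <- c(plugs, list(plug_spec("delrin", "delrin", 12.3, 25.0, ring, 60,
                                     roles = "hu_constancy")))
  }
  markers <- list(
    material = "teflon", diameter_mm = 3, length_mm = 10,
    nominal_spacing_mm = 50,
    positions = list(list(x_mm = 25, y_mm = 25, z_mm = 0),
                     list(x_mm = -25, y_mm = 25, z_mm = 0),
                     list(x_mm = -25, y_mm = -25, z_mm = 0),
                     list(x_mm = 25, y_mm = -25, z_mm = 0))
  )
  lc_targets <- c(
    lapply(seq_along(c(15, 9, 7, 5, 3, 2)), function(i) {
      list(diameter_mm = c(15, 9, 7, 5, 3, 2)[i], contrast_pct = 1.0,
           r_mm = 50, theta_deg = (i - 1) * 25)
    }),
    lapply(seq_along(c(15, 9, 7, 5, 3, 2)), function(i) {
      list(diameter_mm = c(15, 9, 7, 5, 3, 2)[i], contrast_pct = 0.5,
           r_mm = 50, theta_deg = 150 + (i - 1) * 25)
    }),
    lapply(seq_along(c(15, 9, 7)), function(i) {
      list(diameter_mm = c(15, 9, 7)[i], contrast_pct = 0.3,
           r_mm = 50, theta_deg = 300 + (i - 1) * 20)
    })
  )
  modules <- list(
    module_spec("low_contrast", z_mm = -45, length_mm = 30,
                low_contrast_targets = lc_targets),
    module_spec("sensitometry", z_mm = 0, length_mm = 40,
                plugs = plugs, markers = markers),
    module_spec("spatial_resolution", z_mm = 33, length_mm = 25,
                bead = list(x_mm = 0, y_mm = 25, z_mm = 0,
                            diameter_mm = 1.0, material = "bead_metal")),
    module_spec("uniformity", z_mm = 70, length_mm = 40, diameter_mm = 150,
                material = "water_equivalent")
  )
  phantom_geometry(model = model, outer_diameter_mm = 200,
                   body_z_mm = c(-65, 95), background = "phantom_body",
                   materials = default_materials(), modules = modules)
}

#' Look up a material's nominal HU
#' @param geom A `phantom_geometry`.
#' @param name Material name.
#' @return Nominal HU (numeric scalar).
#' @export
material_hu <- function(geom, name) {
  for (m in geom$materials) if (m$name == name) return(m$nominal_hu)
  stopf("material '%s' not found", name, class = "qa4dct_validation_error")
}

#' Find a plug by id or role
#'
#' @param geom A `phantom_geometry`.
#' @param id Plug id to look up (searched across all modules).
#' @param role If given instead of `id`, returns all plugs carrying the role.
#' @return A `plug_spec` (for `id`) or list of `plug_spec` (for `role`).
#' @export
find_plug <- function(geom, id = NULL, role = NULL) {
  plugs <- list()
  for (mod in geom$modules) {
    for (p in mod$plugs) {
      p$module_z_mm <- mod$z_mm
      p$module_material <- mod$material
      plugs <- c(plugs, list(p))
    }
  }
  if (!is.null(id)) {
    for (p in plugs) if (p$id == id) return(p)
    stopf("plug '%s' not found", id, class = "qa4dct_validation_error")
  }
  if (!is.null(role)) {
    return(Filter(function(p) role %in% p$roles, plugs))
  }
  plugs
}

#' Absolute position of a plug center in phantom coordinates
#' @param plug A `plug_spec` carrying `module_z_mm` (as returned by
#'   [find_plug()]).
#' @return Numeric length-3 `(x, y, z)` in mm.
#' @export
plug_center <- function(plug) {
  th <- plug$theta_deg * pi / 180
  c(plug$r_mm * cos(th), plug$r_mm * sin(th),
    (plug$module_z_mm %||% 0) + plug$z_mm)
}

geometry_module <- function(geom, name) {
  for (mod in geom$modules) if (mod$name == name) return(mod)
  stopf("geometry has no '%s' module", name,
        class = "qa4dct_configuration_error")
}

# Geometric center of the body cylinder in phantom coordinates; used by
# locate_phantom to convert a body-mask centroid into the pose of the origin.
body_center <- function(geom) c(0, 0, mean(geom$body_z_mm))

#' Serialize a geometry to a YAML config file
#'
#' @param geom A `phantom_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_geometry()] for the schema.
#' @export
write_geometry <- function(geom, path) {
  modules <- lapply(geom$modules, function(mod) {
    out <- list(name = mod$name, z_mm = mod$z_mm, length_mm = mod$length_mm)
    if (!is.na(mod$diameter_mm)) out$diameter_mm <- mod$diameter_mm
    if (!is.null(mod$material)) out$material <- mod$material
    if (length(mod$plugs)) {
      out$plugs <- lapply(mod$plugs, function(p) {
        list(id = p$id, material = p$material, diameter_mm = p$diameter_mm,
             length_mm = p$length_mm, r_mm = p$r_mm, theta_deg = p$theta_deg,
             z_mm = p$z_mm, roles = as.list(p$roles))
      })
    }
    if (!is.null(mod$bead)) out$bead <- mod$bead
    if (!is.null(mod$markers)) out$markers <- mod$markers
    if (!is.null(mod$low_contrast_targets)) {
      out$low_contrast_targets <- mod$low_contrast_targets
    }
    out
  })
  doc <- list(
    model = geom$model,
    outer_diameter_mm = geom$outer_diameter_mm,
    body_z_mm = as.list(geom$body_z_mm),
    background = geom$background,
    materials = lapply(geom$materials, function(m) {
      list(name = m$name, nominal_hu = m$nominal_hu)
    }),
    modules = modules
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a phantom geometry from a YAML config file
#'
#' The schema mirrors [write_geometry()] output: top-level keys `model`,
#' `outer_diameter_mm`, `body_z_mm`, `background`, `materials`
#' (list of `{name, nominal_hu}`), and `modules` (list of
#' `{name, z_mm, length_mm, diameter_mm?, material?, plugs?, bead?, markers?,
#' low_contrast_targets?}` with plug keys
#' `{id, material, diameter_mm, length_mm, r_mm, theta_deg, z_mm, roles}`).
#'
#' @param path Path to the YAML config.
#' @return A validated [phantom_geometry()].
#' @export
load_geometry <- function(path) {
  if (!file.exists(path)) {
    stopf("geometry config not found: %s", path, class = "qa4dct_io_error")
  }
  doc <- yaml::read_yaml(path)
  need <- c("model", "outer_diameter_mm", "body_z_mm", "background",
            "materials", "modules")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stopf("geometry config missing field(s): %s",
          paste(missing, collapse = ", "), class = "qa4dct_validation_error")
  }
  materials <- lapply(doc$materials, function(m) {
    material_spec(m$name, m$nominal_hu)
  })
  modules <- lapply(doc$modules, function(m) {
    plugs <- lapply(m$plugs %||% list(), function(p) {
      plug_spec(p$id, p$material, p$diameter_mm, p$length_mm,
                p$r_mm, p$theta_deg, p$z_mm %||% 0,
                roles = unlist(p$roles %||% list()))
    })
    module_spec(m$name, m$z_mm, m$length_mm, m$diameter_mm %||% NA,
                material = m$material, plugs = plugs, bead = m$bead,
                markers = m$markers,
                low_contrast_targets = m$low_contrast_targets)
  })
  phantom_geometry(model = doc$model,
                   outer_diameter_mm = doc$outer_diameter_mm,
                   body_z_mm = unlist(doc$body_z_mm),
                   background = doc$background,
                   materials = materials, modules = modules)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("<phantom_geometry> model %d, outer diameter %.0f mm, body z [%.0f, %.0f] mm\n",
              x$model, x$outer_diameter_mm, x$body_z_mm[1], x$body_z_mm[2]))
  for (mod in x$modules) {
    cat(sprintf("  %-18s z %+6.1f mm, length %.0f mm, %d plug(s)\n",
                mod$name, mod$z_mm, mod$length_mm, length(mod$plugs)))
  }
  invisible(x)
}
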