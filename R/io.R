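#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of HU values with voxel spacing and origin.
#' Axis order is fixed as (x, y, z) with z the slice (axial) axis; the origin
#' is the world position in mm of the center of voxel `[1, 1, 1]`. HU values
#' are clipped to the 12-bit CT dynamic range \[-1024, 3071\].
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing_mm Length-3 positive numeric, voxel spacing in mm.
#' @param origin_mm Length-3 numeric, world position of the first voxel
#'   center.
#' @param meta List of metadata: `series_id`, `bin_label` (one of
#'   `"stationary"`, `"bin_<k>"`, `"average"`, `"MIP"`, `"MinIP"`),
#'   `bin_index` (integer, bins only), `binning_mode`.
#' @return A `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      meta = list()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  check_number(spacing_mm, "spacing_mm", min = 1e-9, len = 3L)
  check_number(origin_mm, "origin_mm", len = 3L)
  structure(list(voxels = clamp(voxels, HU_MIN, HU_MAX),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing (%.2f, %.2f, %.2f) mm, bin '%s'\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], x$meta$bin_label %||% "?"))
  invisible(x)
}

#' Voxel-center world coordinates along one axis
#' @param vol A `ct_volume`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of mm coordinates.
#' @export
axis_coords <- function(vol, axis) {
  vol$origin_mm[axis] + (seq_len(dim(vol$voxels)[axis]) - 1) * vol$spacing_mm[axis]
}

same_grid <- function(a, b, tol = 0.01) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

#' Ordered binned 4DCT series
#'
#' @param volumes List of [ct_volume()] with distinct `bin_label`s and equal
#'   grids (shape, spacing, origin); reordered by `bin_index`.
#' @param mode Binning mode, `"phase"` or `"amplitude"`.
#' @return A `phase4d_series`.
#' @export
phase4d_series <- function(volumes, mode = "phase") {
  mode <- match.arg(mode, c("phase", "amplitude"))
  if (!length(volumes)) {
    stopf("empty 4D series", class = "qa4dct_input_error")
  }
  labels <- vapply(volumes, function(v) v$meta$bin_label %||% NA_character_,
                   character(1))
  if (anyNA(labels) || anyDuplicated(labels)) {
    stopf("bin labels must be present and unique; got: %s",
          paste(labels, collapse = ", "), class = "qa4dct_ambiguity_error")
  }
  idx <- vapply(volumes, function(v) as.integer(v$meta$bin_index %||% NA),
                integer(1))
  if (!anyNA(idx)) volumes <- volumes[order(idx)]
  for (v in volumes[-1]) {
    if (!same_grid(volumes[[1]], v)) {
      stopf("4D series member grids differ (shape/spacing/origin)",
            class = "qa4dct_format_error")
    }
  }
  structure(list(volumes = volumes, mode = mode,
                 n_bins = length(volumes)),
            class = "phase4d_series")
}

#' @export
print.phase4d_series <- function(x, ...) {
  cat(sprintf("<phase4d_series> %d bins, %s binning\n", x$n_bins, x$mode))
  invisible(x)
}

bin_label_for <- function(index) sprintf("bin_%02d", index)

#' Write CT volumes as a NIfTI series tree
#'
#' Writes one NIfTI-1 file per volume (float64 storage, so HU survive
#' losslessly) plus a `manifest.json` mapping each file to its role
#' (`stationary`, `bin`, `average`, `MIP`, `MinIP`), bin label/index, binning
#' mode, spacing and origin. The manifest is the authoritative source of
#' origin and role; file names also carry the bin label so a manifest-free
#' tree can still be classified.
#'
#' @param volumes A list of [ct_volume()] (roles read from `meta$bin_label`),
#'   or a [phase4d_series()].
#' @param path Output directory (created if absent).
#' @param extra Optional list merged into the manifest (e.g. ground truth).
#' @return `path`, invisibly.
#' @export
write_series <- function(volumes, path, extra = list()) {
  if (inherits(volumes, "phase4d_series")) volumes <- volumes$volumes
  if (inherits(volumes, "ct_volume")) volumes <- list(volumes)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    stopf("cannot create output directory: %s", path, class = "qa4dct_io_error")
  }
  entries <- list()
  for (v in volumes) {
    label <- v$meta$bin_label %||% "stationary"
    file <- file.path(path, paste0(gsub("[^A-Za-z0-9_.-]", "_", label),
                                   ".nii.gz"))
    img <- RNifti::asNifti(v$voxels, datatype = "double")
    img$pixdim <- c(1, v$spacing_mm, 1, 1, 1, 1)
    RNifti::writeNifti(img, file)
    role <- if (grepl("^bin_", label)) "bin" else label
    entries <- c(entries, list(list(
      file = basename(file), role = role, bin_label = label,
      bin_index = v$meta$bin_index, binning_mode = v$meta$binning_mode,
      series_id = v$meta$series_id %||% label,
      spacing_mm = v$spacing_mm, origin_mm = v$origin_mm
    )))
  }
  manifest <- c(list(format = "qa4dct-series", version = 1L,
                     volumes = entries), extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_one_volume <- function(file, entry = NULL) {
  img <- RNifti::readNifti(file)
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  if (length(dim(vox)) != 3L) {
    stopf("%s: expected a 3D volume, got %d dims", file, length(dim(vox)),
          class = "qa4dct_format_error")
  }
  spacing <- entry$spacing_mm %||% RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) {
    stopf("%s: non-positive voxel spacing in header", file,
          class = "qa4dct_format_error")
  }
  ct_volume(vox, spacing, entry$origin_mm %||% c(0, 0, 0),
            meta = list(bin_label = entry$bin_label,
                        bin_index = entry$bin_index,
                        binning_mode = entry$binning_mode,
                        series_id = entry$series_id))
}

classify_label <- function(fname) {
  base <- tolower(sub("\\.nii(\\.gz)?$", "", basename(fname)))
  if (grepl("stationary|static|ref", base)) return(list(role = "stationary", label = "stationary"))
  if (grepl("average|avg", base)) return(list(role = "average", label = "average"))
  if (grepl("minip", base)) return(list(role = "MinIP", label = "MinIP"))
  if (grepl("mip", base)) return(list(role = "MIP", label = "MIP"))
  m <- regmatches(base, regexpr("(bin|phase)[_-]?([0-9]+)", base))
  if (length(m)) {
    k <- as.integer(gsub("[^0-9]", "", m))
    return(list(role = "bin", label = bin_label_for(k), index = k))
  }
  list(role = "unknown", label = base)
}

#' Read a CT series tree
#'
#' Scans a directory for NIfTI volumes, classifies them as stationary /
#' 4D bin / derived (average, MIP, MinIP) using `manifest.json` when present
#' or file-name tokens otherwise, and validates that all 4D bins share one
#' grid.
#'
#' @param path Directory containing the series.
#' @return List with elements `stationary` ([ct_volume()] or `NULL`),
#'   `series` ([phase4d_series()] or `NULL`), `derived` (named list of
#'   [ct_volume()]), and `manifest` (parsed manifest or `NULL`).
#' @export
read_series_tree <- function(path) {
  if (!dir.exists(path)) {
    stopf("input path does not exist: %s", path, class = "qa4dct_io_error")
  }
  manifest_file <- file.path(path, "manifest.json")
  entries <- NULL
  manifest <- NULL
  if (file.exists(manifest_file)) {
    manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE,
                                    simplifyMatrix = FALSE)
    entries <- lapply(manifest$volumes, function(e) {
      e$file <- file.path(path, e$file)
      e$spacing_mm <- unlist(e$spacing_mm)
      e$origin_mm <- unlist(e$origin_mm)
      e
    })
  } else {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    entries <- lapply(files, function(f) {
      cls <- classify_label(f)
      list(file = f, role = cls$role, bin_label = cls$label,
           bin_index = cls$index)
    })
  }
  if (!length(entries)) {
    stopf("no CT volumes found under %s", path, class = "qa4dct_empty_input_error")
  }
  roles <- vapply(entries, function(e) e$role, character(1))
  bins <- entries[roles == "bin"]
  if (length(bins)) {
    labs <- vapply(bins, function(e) e$bin_label, character(1))
    if (anyDuplicated(labs)) {
      dup <- unique(labs[duplicated(labs)])
      stopf("duplicate bin label(s) %s in: %s", paste(dup, collapse = ", "),
            paste(basename(vapply(bins, `[[`, "", "file")), collapse = ", "),
            class = "qa4dct_ambiguity_error")
    }
  }
  stationary <- NULL
  derived <- list()
  bin_vols <- list()
  mode <- "phase"
  for (e in entries) {
    vol <- read_one_volume(e$file, e)
    if (e$role == "stationary") {
      stationary <- vol
    } else if (e$role == "bin") {
      mode <- e$binning_mode %||% mode
      bin_vols <- c(bin_vols, list(vol))
    } else if (e$role %in% c("average", "MIP", "MinIP")) {
      derived[[e$role]] <- vol
    }
  }
  series <- if (length(bin_vols)) phase4d_series(bin_vols, mode = mode) else NULL
  list(stationary = stationary, series = series, derived = derived,
       manifest = manifest)
}
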