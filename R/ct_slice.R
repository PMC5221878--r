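#' Construct a CT slice
#'
#' A `ct_slice` holds one axial CT image as a matrix of attenuation values in
#' Hounsfield units (HU), together with the physical pixel spacing, the nominal
#' reconstruction slice thickness and the reconstruction-kernel tag. Pixel
#' coordinates are `(row, col)`, 1-based in R, and refer to pixel centers; all
#' millimetre quantities are derived through the spacing.
#'
#' @param pixels Numeric matrix of HU values (finite, non-empty).
#' @param spacing_row,spacing_col Pixel spacing in mm (strictly positive).
#'   `spacing_col` defaults to `spacing_row` (isotropic pixels).
#' @param thickness_mm Nominal slice thickness in mm (1 and 5 in the study
#'   protocol this package models).
#' @param kernel Reconstruction kernel tag, `"sharp"` (high-frequency) or
#'   `"standard"`.
#' @param id Opaque identifier string.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing_row, spacing_col = spacing_row,
                     thickness_mm = 1, kernel = c("sharp", "standard"),
                     id = "slice") {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("HU values must be finite", call. = FALSE)
  stop_if_not_scalar(spacing_row, "spacing_row")
  stop_if_not_scalar(spacing_col, "spacing_col")
  if (spacing_row <= 0 || spacing_col <= 0) {
    stop("pixel spacing must be strictly positive", call. = FALSE)
  }
  stop_if_not_scalar(thickness_mm, "thickness_mm")
  kernel <- match.arg(kernel)
  structure(
    list(pixels = pixels, spacing_row = spacing_row, spacing_col = spacing_col,
         thickness_mm = thickness_mm, kernel = kernel, id = as.character(id)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice '%s'> %d x %d px, %.3g x %.3g mm/px, %g mm %s kernel, HU [%.0f, %.0f]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing_row, x$spacing_col,
              x$thickness_mm, x$kernel, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pixel area of a slice in mm^2
#' @param slice A `ct_slice`.
#' @return Area of one pixel in mm^2.
#' @export
pixel_area <- function(slice) slice$spacing_row * slice$spacing_col

#' Display window presets
#'
#' Linear display windows in the radiological convention: `level` is the HU at
#' mid-grey and `width` the HU range mapped onto the display scale. The two
#' presets used for tumor delineation in this analysis are the lung window
#' (width 1500 HU, level -700 HU) and the mediastinal window (width 450 HU,
#' level 50 HU).
#'
#' @param level Window level (center), HU.
#' @param width Window width, HU (> 0).
#' @param name Preset label.
#' @return A `window_preset` object.
#' @export
window_preset <- function(level, width, name = "custom") {
  stop_if_not_scalar(level, "level")
  stop_if_not_scalar(width, "width")
  if (width <= 0) stop("window width must be > 0", call. = FALSE)
  structure(list(level = level, width = width, name = name),
            class = "window_preset")
}

#' @rdname window_preset
#' @export
lung_window <- function() window_preset(level = -700, width = 1500, name = "lung")

#' @rdname window_preset
#' @export
mediastinal_window <- function() window_preset(level = 50, width = 450, name = "mediastinal")

#' Apply a display window to a slice
#'
#' Maps HU linearly onto `[0, 1]`: values at or below `level - width/2` become
#' 0, values at or above `level + width/2` become 1. The map is monotone
#' non-decreasing in HU.
#'
#' @param slice A `ct_slice`.
#' @param preset A `window_preset`.
#' @return Numeric matrix in `[0, 1]`, same dimensions as the slice.
#' @export
apply_window <- function(slice, preset) {
  stopifnot(inherits(slice, "ct_slice"), inherits(preset, "window_preset"))
  lo <- preset$level - preset$width / 2
  out <- (slice$pixels - lo) / preset$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Load a CT slice from a plain raster with JSON sidecar metadata
#'
#' Reads one axial slice from either an in-memory matrix or a headerless CSV
#' raster of stored pixel values, plus a metadata list (or sidecar JSON file
#' `<path>.json`) carrying the pixel spacing and, optionally, the linear HU
#' calibration. When `rescale_slope`/`rescale_intercept` are present the stored
#' values are converted as `HU = stored * slope + intercept`; otherwise the
#' stored values are taken to be HU already.
#'
#' @param source Path to a CSV raster, or a numeric matrix.
#' @param metadata Named list with `spacing_row`, `spacing_col` (mm, required),
#'   and optionally `thickness_mm`, `kernel`, `id`, `rescale_slope`,
#'   `rescale_intercept`. If `NULL` and `source` is a path, the sidecar
#'   `<source>.json` is read.
#' @return A `ct_slice` with pixels in HU.
#' @export
load_ct_slice <- function(source, metadata = NULL) {
  if (is.character(source)) {
    if (is.null(metadata)) {
      sidecar <- paste0(source, ".json")
      if (!file.exists(sidecar)) {
        stop("no metadata supplied and sidecar file not found: ", sidecar,
             call. = FALSE)
      }
      metadata <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    }
    pixels <- as.matrix(utils::read.csv(source, header = FALSE))
    dimnames(pixels) <- NULL
  } else if (is.matrix(source)) {
    pixels <- source
  } else if (is.array(source)) {
    stop("expected a single 2D slice, got an array with dim = ",
         paste(dim(source), collapse = "x"), call. = FALSE)
  } else {
    stop("'source' must be a file path or a numeric matrix", call. = FALSE)
  }
  for (field in c("spacing_row", "spacing_col")) {
    if (is.null(metadata[[field]])) {
      stop("metadata is missing required field '", field, "'", call. = FALSE)
    }
  }
  slope <- metadata$rescale_slope %||% 1
  intercept <- metadata$rescale_intercept %||% 0
  ct_slice(pixels * slope + intercept,
           spacing_row = metadata$spacing_row,
           spacing_col = metadata$spacing_col,
           thickness_mm = metadata$thickness_mm %||% 1,
           kernel = metadata$kernel %||% "sharp",
           id = metadata$id %||% "slice")
}

#' Save a CT slice as CSV raster + JSON sidecar
#'
#' Writes the HU matrix as a headerless CSV (`path`) and the metadata as
#' `<path>.json`. HU are stored as-is (floating point), so a load/save/load
#' round trip is bit-exact.
#'
#' @param slice A `ct_slice`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  utils::write.table(slice$pixels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(spacing_row = slice$spacing_row, spacing_col = slice$spacing_col,
               thickness_mm = slice$thickness_mm, kernel = slice$kernel,
               id = slice$id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
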