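#' Construct an ROI mask
#'
#' A binary tumor mask drawn on the pixel grid of a `ct_slice`, with the seed
#' point that produced it, the attenuation bounds used for growing, and the
#' history of applied exclusions.
#'
#' @param mask Logical matrix (TRUE = inside the ROI).
#' @param seed Integer `(row, col)` seed location.
#' @param lower_hu,upper_hu Attenuation bounds used for region growing, HU.
#' @param exclusions Character vector of exclusion ids already applied.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, seed, lower_hu = -Inf, upper_hu = Inf,
                     exclusions = character()) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  mask <- mask > 0 & !is.na(mask)
  seed <- as.integer(seed)
  if (length(seed) != 2 || any(seed < 1) || seed[1] > nrow(mask) ||
      seed[2] > ncol(mask)) {
    stop("seed (row, col) must lie inside the image", call. = FALSE)
  }
  structure(list(mask = mask, seed = seed, lower_hu = lower_hu,
                 upper_hu = upper_hu, exclusions = as.character(exclusions)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px of %d x %d, seed (%d, %d), HU [%s, %s], %d exclusion(s)\n",
              sum(x$mask), nrow(x$mask), ncol(x$mask), x$seed[1], x$seed[2],
              format(x$lower_hu), format(x$upper_hu), length(x$exclusions)))
  invisible(x)
}

check_congruent <- function(roi, slice) {
  if (!identical(dim(roi$mask), dim(slice$pixels))) {
    stop("mask and slice grids are incongruent (",
         paste(dim(roi$mask), collapse = "x"), " vs ",
         paste(dim(slice$pixels), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a binary mask as PNG
#'
#' Masks are stored as 8-bit greyscale PNG with 0 = background and 255 = ROI.
#'
#' @param roi An `roi_mask` (or plain logical matrix for `write_mask_png`).
#' @param path PNG file path.
#' @return `read_mask_png` returns a logical matrix; `write_mask_png` returns
#'   `path` invisibly.
#' @export
write_mask_png <- function(roi, path) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi > 0
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Run-length encode / decode a binary mask (JSON-friendly)
#'
#' Column-major run-length encoding: runs of TRUE pixels as (start, length)
#' pairs over the flattened matrix, plus the matrix dimensions. `write_mask_rle`
#' and `read_mask_rle` serialize the encoding as JSON.
#'
#' @param mask Logical matrix or `roi_mask`.
#' @param rle_list A list as produced by `mask_to_rle`.
#' @param path JSON file path.
#' @return `mask_to_rle` returns a list with `dim`, `starts`, `lengths`;
#'   `rle_to_mask` the logical matrix.
#' @export
mask_to_rle <- function(mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask > 0
  r <- rle(as.vector(m))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  list(dim = dim(m), starts = starts[keep], lengths = r$lengths[keep])
}

#' @rdname mask_to_rle
#' @export
rle_to_mask <- function(rle_list) {
  m <- logical(prod(rle_list$dim))
  if (length(rle_list$starts)) {
    idx <- unlist(mapply(function(s, l) seq.int(s, length.out = l),
                         rle_list$starts, rle_list$lengths, SIMPLIFY = FALSE))
    m[idx] <- TRUE
  }
  matrix(m, rle_list$dim[1], rle_list$dim[2])
}

#' @rdname mask_to_rle
#' @export
write_mask_rle <- function(mask, path) {
  jsonlite::write_json(mask_to_rle(mask), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname mask_to_rle
#' @export
read_mask_rle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rle_to_mask(x)
}
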