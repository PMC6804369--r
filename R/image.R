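#' Read a side-view RGB image
#'
#' Reads an 8-bit RGB PNG or TIFF into the array layout used throughout the
#' package: a numeric `H x W x 3` array with channel values on 0--255 and
#' row 1 at the image top. Grayscale files are replicated across channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric `H x W x 3` array, values in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop_invalid_input(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid_input(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext)))
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write an RGB array as PNG
#' @param pixels Numeric `H x W x 3` array, values in `[0, 255]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(pixels, path) {
  check_rgb(pixels)
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Write a binary mask as a black-and-white PNG for inspection
#' @param mask Logical `H x W` matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

check_rgb <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_invalid_input("image must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop_invalid_input("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_invalid_input("channel values must lie in [0, 255] with no NA")
  invisible(pixels)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_invalid_input("mask must be a logical matrix")
  if (anyNA(mask)) stop_invalid_input("mask must not contain NA")
  invisible(mask)
}
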