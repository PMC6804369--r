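#' Tray layout: vertical split line, container ROIs and soil reference row
#'
#' A side-view image of one measuring tray shows two plant containers
#' separated by a vertical divider (a metal mesh in the reference setup).
#' The layout records where that divider sits, the column range occupied by
#' each container, and the row of the soil surface from which canopy height
#' is measured.
#'
#' All indices are 1-based with row 1 at the image top. Column ranges are
#' half-open: `left_roi = c(c0, c1)` covers columns `c0` to `c1 - 1`, so a
#' pixel exactly at the start column of the right ROI belongs to the right
#' container and to it only.
#'
#' @param split_column Integer column index of the vertical dividing line.
#' @param left_roi,right_roi Integer vectors `c(c0, c1)`, half-open column
#'   ranges of the left and right containers. Must not overlap, and
#'   `split_column` must lie between them (inclusive of the gap bounds).
#' @param soil_row Integer row index of the soil surface reference line.
#' @param width,height Optional image dimensions the layout is meant for;
#'   when supplied the ROIs and `soil_row` are checked against them.
#' @return An object of class `tray_layout`.
#' @examples
#' tray_layout(split_column = 240, left_roi = c(11, 231),
#'             right_roi = c(251, 471), soil_row = 330)
#' @export
tray_layout <- function(split_column, left_roi, right_roi, soil_row,
                        width = NULL, height = NULL) {
  chk_range <- function(r, what) {
    if (length(r) != 2L || anyNA(r) || r[1] >= r[2] || r[1] < 1)
      stop_invalid_layout(sprintf("%s must be c(c0, c1) with 1 <= c0 < c1", what))
    as.integer(r)
  }
  left_roi <- chk_range(left_roi, "left_roi")
  right_roi <- chk_range(right_roi, "right_roi")
  if (left_roi[2] > right_roi[1])
    stop_invalid_layout("left_roi and right_roi must not overlap (left before right)")
  split_column <- as.integer(split_column)
  if (is.na(split_column) || split_column < left_roi[2] || split_column > right_roi[1])
    stop_invalid_layout("split_column must lie between the two ROIs")
  soil_row <- as.integer(soil_row)
  if (is.na(soil_row) || soil_row < 1)
    stop_invalid_layout("soil_row must be a positive row index")
  if (!is.null(width) && (right_roi[2] > width + 1L || split_column > width))
    stop_invalid_layout("layout columns exceed image width")
  if (!is.null(height) && soil_row > height)
    stop_invalid_layout("soil_row exceeds image height")
  structure(
    list(split_column = split_column, left_roi = left_roi,
         right_roi = right_roi, soil_row = soil_row),
    class = "tray_layout")
}

#' @export
print.tray_layout <- function(x, ...) {
  cat("Tray layout (1-based, half-open column ranges)\n")
  cat(sprintf("  left container : columns [%d, %d)\n", x$left_roi[1], x$left_roi[2]))
  cat(sprintf("  right container: columns [%d, %d)\n", x$right_roi[1], x$right_roi[2]))
  cat(sprintf("  split column   : %d\n", x$split_column))
  cat(sprintf("  soil row       : %d\n", x$soil_row))
  invisible(x)
}

#' Read a tray layout from a YAML file
#'
#' The file must provide the keys `split_column`, `left_roi`, `right_roi`
#' (each a two-element sequence) and `soil_row`.
#'
#' @param path Path to a YAML file.
#' @inheritParams tray_layout
#' @return A [tray_layout()] object.
#' @export
read_tray_layout <- function(path, width = NULL, height = NULL) {
  if (!file.exists(path)) stop_invalid_input(sprintf("layout file not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("split_column", "left_roi", "right_roi", "soil_row")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop_invalid_layout(paste("layout file lacks keys:", paste(missing, collapse = ", ")))
  tray_layout(y$split_column, unlist(y$left_roi), unlist(y$right_roi), y$soil_row,
              width = width, height = height)
}

#' Write a tray layout to YAML
#' @param layout A [tray_layout()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tray_layout <- function(layout, path) {
  stopifnot(inherits(layout, "tray_layout"))
  yaml::write_yaml(lapply(unclass(layout), as.integer), path)
  invisible(path)
}

# ROI of one container as c(c0, c1), half-open.
container_roi <- function(layout, container = c("left", "right")) {
  container <- match.arg(container)
  if (container == "left") layout$left_roi else layout$right_roi
}
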