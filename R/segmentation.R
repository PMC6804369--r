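#' Excess-green index of an RGB image
#'
#' ExG = 2G - R - B, the standard vegetation index for separating green
#' canopy from soil and background in visible-light images. Values range
#' over `[-510, 510]` for 8-bit channels.
#'
#' @param pixels Numeric `H x W x 3` array, values in `[0, 255]`.
#' @return Numeric `H x W` matrix.
#' @export
excess_green <- function(pixels) {
  check_rgb(pixels)
  2 * pixels[, , 2] - pixels[, , 1] - pixels[, , 3]
}

#' Segment green vegetation in a side-view RGB image
#'
#' Builds the binary "green mask" used by the canopy-height algorithm.
#' The default method computes the excess-green index and thresholds it
#' with Otsu's method; alternatively a fixed threshold on the index can be
#' supplied, which reproduces a given segmentation exactly and is the
#' method of choice when illumination is controlled.
#'
#' A contrast-free image (all index values identical, e.g. a saturated
#' frame) yields an empty mask under the Otsu method rather than an error.
#'
#' @param pixels Numeric `H x W x 3` array, values in `[0, 255]`.
#' @param method `"excess_green_otsu"` (default) or `"fixed_threshold"`.
#' @param threshold Fixed threshold on the excess-green index (required for
#'   `method = "fixed_threshold"`); pixels with `ExG > threshold` are kept.
#' @return Logical `H x W` mask (`TRUE` = vegetation).
#' @seealso [clean_mask()], [split_containers()]
#' @examples
#' img <- array(0, dim = c(4, 4, 3)); img[, , 2] <- 255
#' sum(compute_green_mask(img, "fixed_threshold", threshold = 50))  # 16
#' @export
compute_green_mask <- function(pixels,
                               method = c("excess_green_otsu", "fixed_threshold"),
                               threshold = NULL) {
  check_rgb(pixels)
  method <- match.arg(method)
  exg <- excess_green(pixels)
  if (method == "fixed_threshold") {
    if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L)
      stop_invalid_input("fixed_threshold requires a single numeric 'threshold'")
    return(exg > threshold)
  }
  rng <- range(exg)
  if (rng[1] == rng[2]) {
    # no contrast: nothing can be called vegetation
    return(matrix(FALSE, nrow(exg), ncol(exg)))
  }
  # Otsu on the index rescaled to [0, 1]; threshold mapped back to index units.
  norm <- (exg - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
  norm > thr
}

#' Split a tray mask into per-container masks
#'
#' Assigns mask pixels to the left or right container according to the
#' layout's half-open column ranges; pixels outside both ROIs (including
#' those on the divider between them) are dropped from both outputs. The
#' two outputs partition the in-ROI pixels exactly.
#'
#' @param mask Logical `H x W` matrix.
#' @param layout A [tray_layout()] valid for the mask geometry.
#' @return A list with logical matrices `left` and `right`, each `H x W`.
#' @export
split_containers <- function(mask, layout) {
  check_mask(mask)
  stopifnot(inherits(layout, "tray_layout"))
  W <- ncol(mask)
  if (layout$split_column < 1L || layout$split_column > W)
    stop_invalid_layout("split_column lies outside the image")
  if (layout$right_roi[2] > W + 1L)
    stop_invalid_layout("right_roi exceeds the image width")
  keep <- function(roi) {
    out <- matrix(FALSE, nrow(mask), W)
    cols <- seq.int(roi[1], roi[2] - 1L)
    out[, cols] <- mask[, cols]
    out
  }
  list(left = keep(layout$left_roi), right = keep(layout$right_roi))
}

# 8-connected component labels of a logical mask. 0 = background.
# Built on igraph: foreground pixels are vertices, edges join 8-neighbours.
label_components <- function(mask) {
  check_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  H <- nrow(mask)
  vid <- integer(length(mask))
  vid[idx] <- seq_along(idx)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  edges <- integer(0)
  # right, down, down-right, down-left neighbours cover all 8-adjacencies
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nr <- row + d[1]; nc <- col + d[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= ncol(mask)
    nidx <- (nc[ok] - 1L) * H + nr[ok]
    hit <- vid[nidx] > 0L
    if (any(hit))
      edges <- c(edges, rbind(vid[idx[ok]][hit], vid[nidx][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Remove small connected components from a mask
#'
#' Suppresses speckle noise before height estimation: any 8-connected
#' component with fewer than `min_component_px` pixels is erased.
#' `min_component_px = 0` (and 1) is the identity. The operation is
#' idempotent.
#'
#' @param mask Logical `H x W` matrix.
#' @param min_component_px Minimum component size (pixels) to keep;
#'   non-negative integer.
#' @return Logical `H x W` mask.
#' @export
clean_mask <- function(mask, min_component_px) {
  check_mask(mask)
  if (!is.numeric(min_component_px) || length(min_component_px) != 1L ||
      is.na(min_component_px) || min_component_px < 0)
    stop_invalid_input("min_component_px must be a non-negative integer")
  if (min_component_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
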