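#' Line-intersection criterion for one image row
#'
#' The stopping criterion of the line-descent algorithm: `crit = A / B`,
#' where `A` is the number of vegetation-mask pixels on the horizontal line
#' at `row` inside the container ROI and `B` is the length of that line
#' (the ROI width in pixels). The value is the fraction of the line that
#' intersects the canopy mask.
#'
#' @param mask Logical `H x W` matrix.
#' @param row Row index (1 = image top).
#' @param roi Half-open column range `c(c0, c1)`; `B = c1 - c0`.
#' @return A fraction in `[0, 1]`.
#' @export
crit_for_row <- function(mask, row, roi) {
  check_mask(mask)
  roi <- as.integer(roi)
  if (length(roi) != 2L || roi[2] <= roi[1])
    stop_invalid_input("roi must be a half-open column range c(c0, c1) of width >= 1")
  if (roi[1] < 1L || roi[2] > ncol(mask) + 1L)
    stop_invalid_input("roi exceeds the mask width")
  row <- as.integer(row)
  if (is.na(row) || row < 1L || row > nrow(mask))
    stop_invalid_input("row lies outside the mask")
  cols <- seq.int(roi[1], roi[2] - 1L)
  sum(mask[row, cols]) / length(cols)
}

#' Projected canopy height by line descent
#'
#' Estimates the projected height of a dense canopy from its vegetation
#' mask. A horizontal line is placed one row above the topmost mask pixel
#' inside the ROI and lowered one pixel at a time; at each position the
#' criterion [crit_for_row()] is evaluated. The descent stops at the first
#' row whose criterion strictly exceeds the threshold `tau`; that row is
#' the canopy-top proxy, and the height is its distance above the soil
#' reference row.
#'
#' If no row down to `soil_row` ever exceeds `tau`, the result has
#' `height_px = 0`, `stop_row = soil_row` and flag
#' `"threshold_never_exceeded"`. An ROI with no mask pixel at or above
#' `soil_row` raises a `canopydyn_no_plant` condition.
#'
#' @param mask Logical `H x W` matrix.
#' @param roi Half-open column range `c(c0, c1)` of the container.
#' @param soil_row Soil reference row (1-based); rows below it are ignored.
#' @param tau Stopping threshold, a fraction in `(0, 1]`. Default 0.2.
#' @return An object of class `height_result`: a list with `stop_row`,
#'   `height_px = soil_row - stop_row`, `crit_profile` (data frame of
#'   visited rows and their criterion values, in descent order),
#'   `threshold_used`, and `flag` (`NA` or `"threshold_never_exceeded"`).
#' @examples
#' m <- matrix(FALSE, 12, 10); m[8, ] <- TRUE
#' r <- line_descent_height(m, roi = c(1, 11), soil_row = 12, tau = 0.5)
#' r$height_px  # 4
#' @export
line_descent_height <- function(mask, roi, soil_row, tau = 0.2) {
  check_mask(mask)
  roi <- as.integer(roi)
  if (length(roi) != 2L || roi[2] <= roi[1] || roi[1] < 1L || roi[2] > ncol(mask) + 1L)
    stop_invalid_input("roi must be a valid half-open column range within the mask")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1)
    stop_invalid_input("tau must be a fraction in (0, 1]")
  soil_row <- as.integer(soil_row)
  if (is.na(soil_row) || soil_row < 1L || soil_row > nrow(mask))
    stop_invalid_input("soil_row lies outside the mask")
  cols <- seq.int(roi[1], roi[2] - 1L)
  B <- length(cols)
  # per-row mask coverage, only rows at or above the soil reference
  A <- rowSums(mask[seq_len(soil_row), cols, drop = FALSE])
  rows_with_plant <- which(A > 0L)
  if (!length(rows_with_plant))
    stop_no_plant("no vegetation pixels inside the ROI at or above soil_row")
  start_row <- max(1L, rows_with_plant[1] - 1L)
  visited <- seq.int(start_row, soil_row)
  crit <- A[visited] / B
  hit <- which(crit > tau)
  if (length(hit)) {
    stop_at <- hit[1]
    stop_row <- visited[stop_at]
    flag <- NA_character_
    profile <- data.frame(row = visited[seq_len(stop_at)],
                          crit = crit[seq_len(stop_at)])
  } else {
    stop_row <- soil_row
    flag <- "threshold_never_exceeded"
    profile <- data.frame(row = visited, crit = crit)
  }
  structure(
    list(stop_row = stop_row,
         height_px = soil_row - stop_row,
         crit_profile = profile,
         threshold_used = tau,
         flag = flag),
    class = "height_result")
}

#' @export
print.height_result <- function(x, ...) {
  cat("Projected canopy height (line descent)\n")
  cat(sprintf("  stop row : %s\n", x$stop_row))
  cat(sprintf("  height   : %s px above soil row\n", x$height_px))
  cat(sprintf("  tau      : %g (criterion threshold)\n", x$threshold_used))
  if (!is.na(x$flag)) cat(sprintf("  flag     : %s\n", x$flag))
  invisible(x)
}

no_plant_result <- function(tau) {
  structure(
    list(stop_row = NA_integer_, height_px = NA_real_,
         crit_profile = data.frame(row = integer(), crit = numeric()),
         threshold_used = tau, flag = "no_plant"),
    class = "height_result")
}

#' Canopy heights of both containers in one tray image
#'
#' Full per-image pipeline: green-mask segmentation, speckle cleanup,
#' container split at the layout's vertical line, then line descent per
#' container. An empty container yields a result flagged `"no_plant"`
#' (with `NA` height) instead of aborting the other container.
#'
#' @param pixels Numeric `H x W x 3` RGB array, values in `[0, 255]`.
#' @param layout A [tray_layout()].
#' @param tau Stopping threshold of the line descent.
#' @param method,threshold Segmentation method and fixed threshold, passed
#'   to [compute_green_mask()].
#' @param min_component_px Speckle-cleanup size passed to [clean_mask()].
#' @return A list with `height_result` elements `left` and `right`.
#' @export
heights_for_tray <- function(pixels, layout, tau = 0.2,
                             method = "excess_green_otsu", threshold = NULL,
                             min_component_px = 12) {
  check_rgb(pixels)
  stopifnot(inherits(layout, "tray_layout"))
  if (layout$soil_row > dim(pixels)[1])
    stop_invalid_layout("soil_row exceeds image height")
  mask <- compute_green_mask(pixels, method = method, threshold = threshold)
  mask <- clean_mask(mask, min_component_px)
  halves <- split_containers(mask, layout)
  one <- function(m, roi) {
    tryCatch(line_descent_height(m, roi, layout$soil_row, tau),
             canopydyn_no_plant = function(e) no_plant_result(tau))
  }
  list(left = one(halves$left, layout$left_roi),
       right = one(halves$right, layout$right_roi))
}
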