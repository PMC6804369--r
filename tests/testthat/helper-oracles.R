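# Independent oracles and small fixture builders, kept deliberately naive
# so they share no code with the implementation they check.

# Brute-force line descent: compute crit for every row from the top of the
# image down to soil_row and take the first row with crit > tau.
naive_line_descent <- function(mask, roi, soil_row, tau) {
  cols <- roi[1]:(roi[2] - 1)
  stopifnot(any(mask[1:soil_row, cols]))
  for (row in 1:soil_row) {
    A <- 0
    for (cc in cols) A <- A + as.integer(mask[row, cc])
    if (A / length(cols) > tau)
      return(list(stop_row = row, height_px = soil_row - row, flag = NA))
  }
  list(stop_row = soil_row, height_px = 0, flag = "threshold_never_exceeded")
}

# Two-pass Pearson correlation, written out longhand.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

random_mask <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# Small flat green-on-black image: rows `green_rows` fully green.
flat_tray_image <- function(h, w, green_rows) {
  px <- array(0, dim = c(h, w, 3))
  px[green_rows, , 2] <- 255
  px
}
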