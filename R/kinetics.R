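#' Day-indexed canopy-height curve
#'
#' @param day Integer vector of day indices (strictly increasing).
#' @param height_px Non-negative canopy heights in pixels.
#' @param variant `"W"` (well-watered) or `"D"` (water-stressed).
#' @param tray_id,container Optional provenance labels.
#' @return A data frame of class `growth_curve` with columns `day` and
#'   `height_px` and attributes `variant`, `tray_id`, `container`.
#' @export
growth_curve <- function(day, height_px, variant = c("W", "D"),
                         tray_id = NA_character_, container = NA_character_) {
  variant <- match.arg(variant)
  day <- as.integer(day)
  if (anyNA(day) || is.unsorted(day, strictly = TRUE))
    stop_invalid_input("days must be strictly increasing integers")
  if (length(height_px) != length(day) || anyNA(height_px) || any(height_px < 0))
    stop_invalid_input("heights must be non-negative and match the days")
  structure(data.frame(day = day, height_px = as.numeric(height_px)),
            variant = variant, tray_id = tray_id, container = container,
            class = c("growth_curve", "data.frame"))
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` by OLS and reports the coefficient of
#' determination (the squared Pearson correlation of x and y) and the
#' two-sided p-value of the slope t-test. This is the model behind every
#' stress-decline and recovery slope in the trait extraction.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points, with
#'   non-constant `x`.
#' @return A list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @examples
#' linear_fit(0:2, c(0, 1, 1))  # slope 0.5, intercept 1/6, r2 0.75
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop_invalid_input("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_insufficient_data("linear fit needs at least 3 points")
  if (diff(range(x)) == 0) stop_insufficient_data("x values are all equal")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noise-free curves fit perfectly
  slope <- unname(stats::coef(fit)[2])
  # constant y: slope 0, r2 0 by convention, slope test undefined -> p = 1
  if (diff(range(y)) == 0) {
    return(list(slope = 0, intercept = y[1], r2 = 0, p = 1, n = length(x)))
  }
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r2 = unname(sm$r.squared),
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' First day the watered and stressed height curves separate
#'
#' Two rules are available. With replicated per-day observations (several
#' trays per variant), a per-day Kruskal--Wallis test at level `alpha`
#' flags the first day the two variants differ. Without replicates, a
#' relative-gap rule flags the first day the mean stressed height falls
#' more than `delta` (default 10%) below the mean watered height.
#' `rule = "auto"` picks Kruskal--Wallis when both variants have at least
#' two observations per day.
#'
#' @param W,D Data frames with columns `day` and `height_px` (replicate
#'   rows per day allowed, e.g. one per tray), for the well-watered and
#'   water-stressed variants.
#' @param rule `"auto"`, `"kruskal"` or `"gap"`.
#' @param delta Relative-gap threshold for the gap rule.
#' @param alpha Significance level for the Kruskal--Wallis rule.
#' @return Integer day, with attribute `rule` recording the rule applied.
#'   If the curves never separate a `canopydyn_no_separation` condition is
#'   raised.
#' @export
detect_separation_day <- function(W, D, rule = c("auto", "kruskal", "gap"),
                                  delta = 0.10, alpha = 0.05) {
  rule <- match.arg(rule)
  for (nm in list(W, D))
    if (!all(c("day", "height_px") %in% names(nm)))
      stop_invalid_input("curves need columns 'day' and 'height_px'")
  days <- sort(intersect(unique(W$day), unique(D$day)))
  if (length(days) < 4L)
    stop_insufficient_data("curves share fewer than 4 common days")
  reps <- function(cv) min(table(cv$day[cv$day %in% days]))
  if (rule == "auto")
    rule <- if (reps(W) >= 2L && reps(D) >= 2L) "kruskal" else "gap"
  for (d in days) {
    w <- W$height_px[W$day == d]
    x <- D$height_px[D$day == d]
    sep <- if (rule == "kruskal") {
      # directional: separation means the stressed curve falls below W
      if (length(unique(c(w, x))) == 1L || mean(x) >= mean(w)) FALSE
      else stats::kruskal.test(list(w, x))$p.value < alpha
    } else {
      mean(w) > 0 && (mean(w) - mean(x)) / mean(w) > delta
    }
    if (isTRUE(sep)) return(structure(as.integer(d), rule = rule))
  }
  stop_no_separation("watered and stressed curves never separate under the chosen rule")
}

#' Drought and recovery traits of a stressed canopy-height curve
#'
#' Extracts the trait set used to summarise water-deficit kinetics:
#' \describe{
#'   \item{max_height (Max)}{canopy height at curve separation: the maximum
#'     over `[separation_day, decline onset]`.}
#'   \item{min_height (Min)}{minimum height over the stress window
#'     `[separation_day, rewater_day]`.}
#'   \item{stress_slope (Slope)}{OLS slope (px/day) over
#'     `[decline onset, rewater_day]`, with `r2_stress`, `p_stress`.}
#'   \item{max_recovery (MaxR)}{maximum height after rewatering, over
#'     `(rewater_day, end_day]`.}
#'   \item{recovery_slope (SlopeR)}{OLS slope over `(rewater_day, end_day]`,
#'     with `r2_recovery`, `p_recovery`.}
#' }
#' The decline onset is the first day in the stress window whose
#' first-difference is negative (the day height starts dropping); if the
#' curve never drops it falls back to `separation_day`. Both fit windows
#' are reported so the regression is fully reproducible.
#'
#' @param curve Data frame with columns `day`, `height_px` (a
#'   [growth_curve()] of the stressed variant).
#' @param separation_day,rewater_day,end_day Window bounds, days present in
#'   the curve, `separation_day < rewater_day < end_day`. `end_day`
#'   defaults to the last day of the curve.
#' @return An object of class `stress_traits` (a one-row data frame with
#'   the fields above plus `separation_day`, `decline_onset`,
#'   `rewater_day`, `end_day`).
#' @export
extract_stress_traits <- function(curve, separation_day, rewater_day,
                                  end_day = max(curve$day)) {
  if (!all(c("day", "height_px") %in% names(curve)))
    stop_invalid_input("curve needs columns 'day' and 'height_px'")
  day <- as.integer(curve$day); h <- as.numeric(curve$height_px)
  o <- order(day); day <- day[o]; h <- h[o]
  if (anyDuplicated(day))
    stop_invalid_input("curve must hold one height per day (average replicates first)")
  separation_day <- as.integer(separation_day)
  rewater_day <- as.integer(rewater_day)
  end_day <- as.integer(end_day)
  if (!(separation_day < rewater_day && rewater_day < end_day))
    stop_invalid_input("need separation_day < rewater_day < end_day")
  if (!all(c(separation_day, rewater_day, end_day) %in% day))
    stop_invalid_input("window bounds must be days present in the curve")

  stress_idx <- which(day >= separation_day & day <= rewater_day)
  if (length(stress_idx) < 3L)
    stop_insufficient_data("stress window holds fewer than 3 points")
  # decline onset: first day in the stress window where height starts to drop
  dh <- diff(h[stress_idx])
  onset_idx <- if (any(dh < 0)) stress_idx[which(dh < 0)[1]] else stress_idx[1]
  decline_onset <- day[onset_idx]

  fit_idx <- which(day >= decline_onset & day <= rewater_day)
  if (length(fit_idx) < 3L) fit_idx <- stress_idx  # degenerate late onset
  stress_fit <- linear_fit(day[fit_idx], h[fit_idx])

  rec_idx <- which(day > rewater_day & day <= end_day)
  if (length(rec_idx) < 3L)
    stop_insufficient_data("recovery window holds fewer than 3 points")
  rec_fit <- linear_fit(day[rec_idx], h[rec_idx])

  out <- data.frame(
    separation_day = separation_day,
    decline_onset = decline_onset,
    rewater_day = rewater_day,
    end_day = end_day,
    max_height = max(h[day >= separation_day & day <= decline_onset]),
    min_height = min(h[stress_idx]),
    stress_slope = stress_fit$slope,
    r2_stress = stress_fit$r2,
    p_stress = stress_fit$p,
    max_recovery = max(h[rec_idx]),
    recovery_slope = rec_fit$slope,
    r2_recovery = rec_fit$r2,
    p_recovery = rec_fit$p)
  class(out) <- c("stress_traits", "data.frame")
  out
}
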