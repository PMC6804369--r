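#' Fluorescence trace of one plant/pixel/timepoint
#'
#' Bundles the measured chlorophyll-fluorescence levels of a quenching
#' protocol: dark-adapted minimal (`F0`) and maximal (`FM`) fluorescence,
#' steady-state fluorescence in the light (`Ft`) and light-adapted maximal
#' fluorescence (`FMprime`). The light-adapted minimal level `F0prime` may
#' be measured or left `NULL`, in which case downstream computations use
#' the estimate of [estimate_F0prime()].
#'
#' Invariants: all levels positive, `FM >= F0`, `FMprime >= Ft`. A trace
#' with `FMprime > FM` is physically implausible and triggers a warning
#' (not an error), as it can arise from measurement noise.
#'
#' @param F0,FM,Ft,FMprime Positive fluorescence levels (arbitrary units).
#' @param F0prime Optional measured light-adapted minimal fluorescence.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(F0, FM, Ft, FMprime, F0prime = NULL) {
  vals <- c(F0 = F0, FM = FM, Ft = Ft, FMprime = FMprime)
  if (anyNA(vals) || any(vals <= 0))
    stop_invalid_input("all fluorescence levels must be positive")
  if (FM < F0) stop_invalid_trace("FM must be >= F0")
  if (Ft > FMprime) stop_invalid_trace("Ft must not exceed FMprime")
  if (FMprime > FM)
    warning("FMprime exceeds FM; trace is physically implausible", call. = FALSE)
  if (!is.null(F0prime)) {
    if (is.na(F0prime) || F0prime <= 0) stop_invalid_input("F0prime must be positive")
    if (F0prime >= FMprime) stop_degenerate_trace("F0prime must be below FMprime")
  }
  structure(list(F0 = F0, FM = FM, Ft = Ft, FMprime = FMprime,
                 F0prime = F0prime),
            class = "fluor_trace")
}

#' Estimate the light-adapted minimal fluorescence F0'
#'
#' When F0' is not measured it is estimated from the dark-adapted levels
#' and the light-adapted maximum by the Oxborough--Baker relation
#' `F0' = F0 / (Fv/FM + F0/FM')` with `Fv = FM - F0`. In the dark-adapted
#' limit `FM' = FM` the estimate reduces to `F0` exactly, and the estimate
#' is homogeneous of degree 1 in the fluorescence levels (rescaling the
#' trace rescales F0').
#'
#' @param F0,FM,FMprime Positive fluorescence levels with `FM > F0`.
#' @return Estimated `F0'` (positive, below `FMprime`).
#' @examples
#' estimate_F0prime(1000, 5000, 3000)  # 882.35...
#' @export
estimate_F0prime <- function(F0, FM, FMprime) {
  vals <- c(F0, FM, FMprime)
  if (anyNA(vals) || any(vals <= 0))
    stop_invalid_input("F0, FM and FMprime must be positive")
  if (FM <= F0) stop_invalid_input("FM must exceed F0")
  F0 / ((FM - F0) / FM + F0 / FMprime)
}

#' Quenching-analysis quantum yields and qP
#'
#' Computes the chlorophyll-fluorescence quenching parameters from a
#' trace:
#' \describe{
#'   \item{phi_Po}{maximum quantum yield of PSII photochemistry,
#'     dark-adapted: `(FM - F0) / FM` (Fv/FM).}
#'   \item{phi_PSII}{maximal light-adapted PSII yield:
#'     `(FM' - F0') / FM'`.}
#'   \item{qP}{coefficient of photochemical quenching,
#'     `(FM' - Ft) / (FM' - F0')` — the fraction of open PSII centers.}
#'   \item{phi_P}{actual photochemical yield, `qP * phi_PSII`
#'     (equivalently `(FM' - Ft) / FM'`).}
#'   \item{phi_fD}{constitutive (basal) dissipation yield, `Ft / FM`.}
#'   \item{phi_NPQ}{regulatory non-photochemical quenching yield,
#'     `Ft/FM' - Ft/FM`.}
#' }
#' The three light-adapted yields partition absorbed light:
#' `phi_P + phi_NPQ + phi_fD = 1`, exactly by construction. All yields are
#' invariant under rescaling the whole trace by a positive constant.
#'
#' @param trace A [fluor_trace()], or `F0` given as the first of the raw
#'   levels with the remaining arguments.
#' @param F0,FM,Ft,FMprime,F0prime Raw levels, used when `trace` is not a
#'   `fluor_trace` (then `trace` is taken as `F0`).
#' @return An object of class `quenching_yields`: a list of the six
#'   fractions plus `F0prime_source` (`"measured"` or `"estimated"`).
#' @examples
#' quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 1500, FMprime = 3000))
#' @export
quenching_yields <- function(trace, FM = NULL, Ft = NULL, FMprime = NULL,
                             F0prime = NULL, F0 = NULL) {
  if (!inherits(trace, "fluor_trace")) {
    if (is.null(F0)) F0 <- trace
    trace <- fluor_trace(F0 = F0, FM = FM, Ft = Ft, FMprime = FMprime,
                         F0prime = F0prime)
  }
  src <- if (is.null(trace$F0prime)) "estimated" else "measured"
  f0p <- if (src == "measured") trace$F0prime
         else estimate_F0prime(trace$F0, trace$FM, trace$FMprime)
  if (trace$FMprime <= f0p)
    stop_degenerate_trace("FMprime must exceed F0prime")
  if (trace$Ft > trace$FMprime)
    stop_invalid_trace("Ft must not exceed FMprime")
  with(trace, {
    phi_Po <- (FM - F0) / FM
    phi_PSII <- (FMprime - f0p) / FMprime
    qP <- (FMprime - Ft) / (FMprime - f0p)
    structure(list(
      phi_Po = phi_Po,
      phi_PSII = phi_PSII,
      qP = qP,
      phi_P = qP * phi_PSII,
      phi_NPQ = Ft / FMprime - Ft / FM,
      phi_fD = Ft / FM,
      F0prime = f0p,
      F0prime_source = src), class = "quenching_yields")
  })
}

#' @export
print.quenching_yields <- function(x, digits = 4, ...) {
  cat("Chlorophyll-fluorescence quenching yields\n")
  for (nm in c("phi_Po", "phi_PSII", "qP", "phi_P", "phi_NPQ", "phi_fD"))
    cat(sprintf("  %-8s %s\n", nm, format(x[[nm]], digits = digits)))
  cat(sprintf("  (F0' %s: %s)\n", x$F0prime_source, format(x$F0prime, digits = digits)))
  invisible(x)
}

#' Mean quenching yields over a plant mask
#'
#' Computes per-pixel yields from co-registered fluorescence frames and
#' averages them over the vegetation mask (mean of per-pixel yields, not
#' yields of mean fluorescence — the two differ for heterogeneous
#' canopies; set `aggregate = "of_means"` for the latter). The partition
#' identity is preserved by the per-pixel mean, since a mean of values
#' each summing to 1 sums to 1.
#'
#' @param frames Named list of `H x W` matrices `F0`, `FM`, `Ft`,
#'   `FMprime`, optionally `F0prime`.
#' @param mask Logical `H x W` matrix; must contain at least one pixel.
#' @param aggregate `"of_pixels"` (default, mean of per-pixel yields) or
#'   `"of_means"` (yields of mask-mean fluorescence).
#' @return A `quenching_yields` object.
#' @export
yields_over_mask <- function(frames, mask,
                             aggregate = c("of_pixels", "of_means")) {
  aggregate <- match.arg(aggregate)
  check_mask(mask)
  need <- c("F0", "FM", "Ft", "FMprime")
  if (!all(need %in% names(frames)))
    stop_invalid_input("frames must contain matrices F0, FM, Ft, FMprime")
  for (nm in intersect(c(need, "F0prime"), names(frames)))
    if (!is.matrix(frames[[nm]]) || !all(dim(frames[[nm]]) == dim(mask)))
      stop_invalid_input(sprintf("frame '%s' is not co-registered with the mask", nm))
  idx <- which(mask)
  if (!length(idx)) stop_no_plant("mask contains no vegetation pixels")
  has_f0p <- "F0prime" %in% names(frames)
  if (aggregate == "of_means") {
    return(quenching_yields(fluor_trace(
      F0 = mean(frames$F0[idx]), FM = mean(frames$FM[idx]),
      Ft = mean(frames$Ft[idx]), FMprime = mean(frames$FMprime[idx]),
      F0prime = if (has_f0p) mean(frames$F0prime[idx]))))
  }
  per_px <- lapply(idx, function(i) {
    quenching_yields(fluor_trace(
      F0 = frames$F0[i], FM = frames$FM[i], Ft = frames$Ft[i],
      FMprime = frames$FMprime[i],
      F0prime = if (has_f0p) frames$F0prime[i]))
  })
  fields <- c("phi_Po", "phi_PSII", "qP", "phi_P", "phi_NPQ", "phi_fD", "F0prime")
  out <- lapply(fields, function(f) mean(vapply(per_px, `[[`, numeric(1), f)))
  names(out) <- fields
  out$F0prime_source <- if (has_f0p) "measured" else "estimated"
  structure(out, class = "quenching_yields")
}
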