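#' Specification of a synthetic side-view tray image
#'
#' Describes the scene the renderer draws: two containers of grass-like
#' blades seen from the side, separated by a vertical divider, on a
#' uniform background with a soil band at the bottom. Blades are solid
#' quadratic strokes rising from the soil row; their tips are spread over
#' `tip_spread` rows below the container's canopy-top row, with every
#' fifth blade forced to reach the top exactly so the recorded canopy top
#' is attained.
#'
#' @param H,W Image size in pixels (rows, columns).
#' @param layout A [tray_layout()]; by default containers of equal width
#'   with a 10-px outer margin, a 20-px central gap, and the soil row 30 px
#'   above the bottom.
#' @param canopy_top Length-2 integer vector, canopy-top row of the left
#'   and right container (1 = image top); must lie above `soil_row`. A
#'   value of `NA` renders an empty container.
#' @param n_blades Blades per container.
#' @param blade_width Stroke width in pixels.
#' @param tip_spread Rows over which blade tips are spread below the
#'   canopy top.
#' @param curvature_max Maximum horizontal bow of a blade (px).
#' @param noise Salt-and-pepper corruption: fraction of pixels replaced by
#'   random colors, in `[0, 0.2]`. Default 0.01.
#' @param seed Optional integer; a given seed renders bit-identically.
#' @return An object of class `canopy_spec`.
#' @export
canopy_spec <- function(H = 360, W = 480, layout = NULL,
                        canopy_top = c(150, 150), n_blades = 50,
                        blade_width = 3, tip_spread = 6, curvature_max = 12,
                        noise = 0.01, seed = NULL) {
  if (is.null(layout)) {
    half <- (W - 40L) %/% 2L
    layout <- tray_layout(split_column = W %/% 2L,
                          left_roi = c(11L, 11L + half),
                          right_roi = c(W - 9L - half, W - 9L),
                          soil_row = H - 30L,
                          width = W, height = H)
  }
  if (length(canopy_top) != 2L) stop_invalid_spec("canopy_top must have two elements")
  for (ct in canopy_top[!is.na(canopy_top)])
    if (ct < 1L || ct >= layout$soil_row)
      stop_invalid_spec("canopy_top rows must lie above soil_row (and be >= 1)")
  if (noise < 0 || noise > 0.2)
    stop_invalid_spec("noise fraction must lie in [0, 0.2]")
  if (n_blades < 0 || blade_width < 1 || tip_spread < 0)
    stop_invalid_spec("n_blades, blade_width, tip_spread must be sensible")
  structure(list(H = as.integer(H), W = as.integer(W), layout = layout,
                 canopy_top = as.integer(canopy_top), n_blades = as.integer(n_blades),
                 blade_width = as.integer(blade_width),
                 tip_spread = as.integer(tip_spread),
                 curvature_max = curvature_max, noise = noise, seed = seed),
            class = "canopy_spec")
}

#' Render a synthetic tray image with ground truth
#'
#' Draws the scene described by a [canopy_spec()] and returns the image
#' together with its exact foreground truth: the binary mask of drawn
#' blade pixels before noise corruption, and the topmost foreground row of
#' each container ROI. Rendering is a pure function of the spec and seed.
#'
#' @param spec A [canopy_spec()].
#' @return A list with `pixels` (`H x W x 3`, 0--255), `truth` (logical
#'   `H x W`), `truth_top_rows` (named vector, `NA` for an empty
#'   container), and `layout`.
#' @export
render_tray <- function(spec) {
  stopifnot(inherits(spec, "canopy_spec"))
  with_seed(spec$seed, {
    H <- spec$H; W <- spec$W; lay <- spec$layout
    npx <- H * W
    # background: light wall above the soil band, dark substrate below
    R <- matrix(175, H, W); G <- matrix(178, H, W); B <- matrix(182, H, W)
    soil <- seq.int(lay$soil_row, H)
    R[soil, ] <- 95; G[soil, ] <- 72; B[soil, ] <- 48
    jitter_bg <- function(m) m + matrix(stats::runif(npx, -8, 8), H, W)
    R <- jitter_bg(R); G <- jitter_bg(G); B <- jitter_bg(B)
    # vertical divider (metal mesh) at the split column
    R[, lay$split_column] <- 70; G[, lay$split_column] <- 70; B[, lay$split_column] <- 75

    truth <- matrix(FALSE, H, W)
    draw_container <- function(roi, top) {
      if (is.na(top) || spec$n_blades == 0L) return()
      cols_ok <- c(roi[1], roi[2] - 1L)
      for (b in seq_len(spec$n_blades)) {
        x0 <- stats::runif(1, cols_ok[1] + 1, cols_ok[2] - spec$blade_width)
        tip <- if (b %% 5L == 1L) top
               else top + sample.int(spec$tip_spread + 1L, 1L) - 1L
        tip <- min(tip, lay$soil_row - 1L)
        len <- lay$soil_row - tip
        bow <- stats::runif(1, -spec$curvature_max, spec$curvature_max)
        s <- seq(0, 1, length.out = max(3L, 3L * len))
        rows <- round(lay$soil_row - s * len)
        cols <- round(x0 + bow * s^2)
        for (wdt in seq_len(spec$blade_width) - 1L) {
          cc <- pmin(pmax(cols + wdt, cols_ok[1]), cols_ok[2])
          truth[cbind(rows, cc)] <<- TRUE
        }
      }
    }
    draw_container(lay$left_roi, spec$canopy_top[1])
    draw_container(lay$right_roi, spec$canopy_top[2])

    fg <- which(truth)
    if (length(fg)) {
      R[fg] <- stats::runif(length(fg), 30, 80)
      G[fg] <- stats::runif(length(fg), 130, 200)
      B[fg] <- stats::runif(length(fg), 20, 70)
    }
    # salt-and-pepper corruption, applied after the truth is recorded
    n_noise <- round(spec$noise * npx)
    if (n_noise > 0) {
      at <- sample.int(npx, n_noise)
      R[at] <- stats::runif(n_noise, 0, 255)
      G[at] <- stats::runif(n_noise, 0, 255)
      B[at] <- stats::runif(n_noise, 0, 255)
    }
    pixels <- array(c(R, G, B), dim = c(H, W, 3))
    pixels[pixels < 0] <- 0; pixels[pixels > 255] <- 255

    top_of <- function(roi) {
      cols <- seq.int(roi[1], roi[2] - 1L)
      rows <- which(rowSums(truth[, cols, drop = FALSE]) > 0L)
      if (length(rows)) rows[1] else NA_integer_
    }
    list(pixels = pixels, truth = truth,
         truth_top_rows = c(left = top_of(lay$left_roi),
                            right = top_of(lay$right_roi)),
         layout = lay)
  })
}

#' Specification of synthetic drought/recovery growth kinetics
#'
#' Piecewise-linear model of the projected canopy-height curves of a
#' well-watered (W) and a water-stressed (D) container. Both variants grow
#' at `growth_rate` until `separation_day`; D then declines at
#' `stress_slope` until `rewater_day` and recovers at `recovery_slope`
#' until the last day; W keeps growing until `rewater_day` and then
#' saturates to `plateau_rate`. The defaults reproduce the study
#' conditions this generator emulates: 19 daily measurements, curve
#' separation at day 8 with a maximum near 1040 px, a stress decline of
#' -70 px/day until rewatering at day 15, and a recovery of +150 px/day.
#' Measurement noise is multiplicative Gaussian with standard deviation
#' `noise_sd` of the height (default 2%).
#'
#' @param days Integer day axis (default 1:19).
#' @param growth_rate Shared early growth rate, px/day.
#' @param separation_day Day the two curves separate.
#' @param stress_slope Decline rate under stress, px/day (<= 0).
#' @param rewater_day Day the stressed container is rewatered.
#' @param recovery_slope Regrowth rate after rewatering, px/day (>= 0).
#' @param plateau_rate W growth rate after `rewater_day` (default a
#'   quarter of `growth_rate`).
#' @param noise_sd Gaussian noise sd as a fraction of height.
#' @param n_trays Number of replicate trays.
#' @param seed Optional integer seed.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(days = 1:19, growth_rate = 130, separation_day = 8,
                          stress_slope = -70, rewater_day = 15,
                          recovery_slope = 150, plateau_rate = growth_rate / 4,
                          noise_sd = 0.02, n_trays = 3, seed = NULL) {
  days <- as.integer(days)
  if (anyNA(days) || is.unsorted(days, strictly = TRUE))
    stop_invalid_spec("days must be strictly increasing integers")
  if (!(separation_day < rewater_day && rewater_day < max(days)))
    stop_invalid_spec("need separation_day < rewater_day < last day")
  if (stress_slope > 0) stop_invalid_spec("stress_slope must be <= 0")
  if (recovery_slope < 0) stop_invalid_spec("recovery_slope must be >= 0")
  if (noise_sd < 0) stop_invalid_spec("noise_sd must be >= 0")
  if (n_trays < 1) stop_invalid_spec("need at least one tray")
  structure(list(days = days, growth_rate = growth_rate,
                 separation_day = as.integer(separation_day),
                 stress_slope = stress_slope,
                 rewater_day = as.integer(rewater_day),
                 recovery_slope = recovery_slope, plateau_rate = plateau_rate,
                 noise_sd = noise_sd, n_trays = as.integer(n_trays),
                 seed = seed),
            class = "kinetics_spec")
}

#' Noise-free canopy height of the kinetic model
#'
#' @param spec A [kinetics_spec()].
#' @param days Days at which to evaluate (default the spec's axis).
#' @param variant `"W"` or `"D"`.
#' @return Numeric vector of heights (px).
#' @export
kinetics_truth <- function(spec, days = spec$days, variant = c("W", "D")) {
  stopifnot(inherits(spec, "kinetics_spec"))
  variant <- match.arg(variant)
  g <- spec$growth_rate
  w_at <- function(d) ifelse(d <= spec$rewater_day, g * d,
                             g * spec$rewater_day + spec$plateau_rate * (d - spec$rewater_day))
  if (variant == "W") return(w_at(days))
  peak <- g * spec$separation_day
  trough <- peak + spec$stress_slope * (spec$rewater_day - spec$separation_day)
  ifelse(days <= spec$separation_day, g * days,
    ifelse(days <= spec$rewater_day,
           peak + spec$stress_slope * (days - spec$separation_day),
           trough + spec$recovery_slope * (days - spec$rewater_day)))
}

#' Simulate replicated W/D growth-curve series
#'
#' Evaluates the piecewise-linear truth of [kinetics_truth()] on the day
#' axis for each tray and variant and adds i.i.d. multiplicative Gaussian
#' noise (`sd = noise_sd * height`), truncated at zero. With
#' `noise_sd = 0` the output is exactly the injected piecewise-linear
#' curve.
#'
#' @param spec A [kinetics_spec()].
#' @return A data frame of class `growth_series` with columns `tray`,
#'   `variant`, `day`, `height_px` and `height_true`; the spec is attached
#'   as attribute `spec`.
#' @export
simulate_growth_series <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  with_seed(spec$seed, {
    grid <- expand.grid(tray = seq_len(spec$n_trays), variant = c("W", "D"),
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      truth <- kinetics_truth(spec, variant = grid$variant[i])
      noisy <- truth * (1 + stats::rnorm(length(truth), 0, spec$noise_sd))
      data.frame(tray = grid$tray[i], variant = grid$variant[i],
                 day = spec$days, height_px = pmax(noisy, 0),
                 height_true = truth)
    }))
    structure(out, spec = spec, class = c("growth_series", "data.frame"))
  })
}

#' @export
plot.growth_series <- function(x, ...) {
  cols <- c(W = "#1b7837", D = "#b2182b")
  graphics::plot(range(x$day), range(x$height_px), type = "n",
                 xlab = "day", ylab = "projected canopy height (px)", ...)
  for (tr in unique(x$tray)) for (v in c("W", "D")) {
    s <- x[x$tray == tr & x$variant == v, ]
    graphics::lines(s$day, s$height_px, col = cols[v],
                    lty = if (v == "D") 2 else 1)
  }
  graphics::legend("topleft", legend = c("W (watered)", "D (stressed)"),
                   col = cols, lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate chlorophyll-fluorescence traces
#'
#' Draws `n` random traces that satisfy the [fluor_trace()] invariants.
#' Under no stress the dark-adapted maximum yield phi_Po is centred near
#' 0.81 (the healthy-leaf range); increasing `stress_level` lowers phi_Po
#' and deepens non-photochemical quenching (lower FM'/FM), raising
#' phi_NPQ. Steady-state fluorescence Ft is drawn strictly between the
#' Oxborough--Baker F0' and FM', so every trace yields valid quenching
#' parameters. F0' is left unmeasured (estimated downstream).
#'
#' @param n Number of traces (>= 1).
#' @param stress_level Stress severity in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A data frame with columns `F0`, `FM`, `Ft`, `FMprime`.
#' @export
simulate_fluor_traces <- function(n, stress_level = 0, seed = NULL) {
  if (n < 1) stop_invalid_input("n must be >= 1")
  if (stress_level < 0 || stress_level > 1)
    stop_invalid_input("stress_level must lie in [0, 1]")
  with_seed(seed, {
    phi_Po <- pmin(pmax(stats::rnorm(n, 0.815 - 0.12 * stress_level, 0.012),
                        0.60), 0.84)
    FM <- stats::runif(n, 3000, 6000)
    F0 <- FM * (1 - phi_Po)
    # light-adapted maximum between F0 and FM; quenching deepens with stress
    q <- pmin(pmax(stats::rnorm(n, 0.80 - 0.30 * stress_level, 0.05), 0.15), 0.98)
    FMprime <- F0 + q * (FM - F0)
    f0p <- F0 / ((FM - F0) / FM + F0 / FMprime)
    u <- stats::runif(n, 0.10 + 0.35 * stress_level, 0.90)
    Ft <- f0p + u * (FMprime - f0p)
    data.frame(F0 = F0, FM = FM, Ft = Ft, FMprime = FMprime)
  })
}

# The 47 monitored variables: 15 image-/manually-derived traits and 32
# biochemical variables (19 amino acids, 8 polyamines, 3 antioxidant
# enzymes, 2 group totals). `dir` is the loading of the latent stress
# factor used by simulate_trait_table: metabolites and dissipation yields
# rise together under stress, growth- and photochemistry-related traits
# fall together.
trait_variables <- function() {
  tr <- data.frame(
    name = c("canopy_height", "slope", "biomass", "leaf_length", "leaf_width",
             "length_width", "RWC", "Chl", "BBCH", "Phi_Po", "Phi_PSII",
             "Phi_P", "qP", "Phi_NPQ", "Phi_fD"),
    class = "trait",
    baseline = c(1000, 150, 2.0, 18, 0.6, 30, 92, 40, 15, 0.80, 0.70,
                 0.50, 0.71, 0.20, 0.30),
    dir = c(-1, -1, -1, -1, -1, -0.3, -1, -0.5, -0.5, -0.3, -0.5,
            -0.5, -0.3, 1, 0.5))
  aa <- data.frame(
    name = c("Ala", "Arg", "Asn", "Asp", "Cit", "GABA", "Gln", "Glu", "Gly",
             "His", "Ile", "Leu", "Met", "OH_Pro", "Phe", "Pro", "Ser",
             "Trp", "Tyr"),
    class = "amino_acid", baseline = 50, dir = 1)
  pa <- data.frame(
    name = c("Agm", "Cad", "DAP", "Put", "Spd", "Spm", "Tryp", "Tyra"),
    class = "polyamine", baseline = 20, dir = 1)
  enz <- data.frame(name = c("CAT", "POX", "APX"), class = "enzyme",
                    baseline = 5, dir = 1)
  tot <- data.frame(name = c("total_AA", "total_PA"), class = "total",
                    baseline = c(950, 160), dir = 1)
  rbind(tr, aa, pa, enz, tot)
}

#' Default injected group effects for the synthetic trait table
#'
#' Log2 shifts of the stressed (D) relative to the watered (W) group, per
#' phase, patterned on the qualitative picture the method is designed to
#' resolve: strong proline/hydroxyproline and polyamine accumulation under
#' stress; citrulline, spermidine and APX rising mainly after rewatering
#' (Cit at log2 = 3.55); growth traits and PSII yields depressed under
#' stress and partially recovered afterwards.
#'
#' @return A list with named numeric vectors `stress` and `recovery`.
#' @export
default_trait_effects <- function() {
  list(
    stress = c(Pro = 4.5, OH_Pro = 4.0, GABA = 1.5, Cit = 1.2, Glu = 1.0,
               Ala = 1.0, Arg = 1.0, Trp = 1.2, total_AA = 1.5,
               Cad = 3.0, DAP = 2.5, Tryp = 2.5, Tyra = 3.0, Put = 1.5,
               Spm = 1.0, Agm = 0.8, total_PA = 1.8,
               CAT = 1.0, POX = 1.0, APX = 0.3,
               canopy_height = -0.6, slope = -1.5, biomass = -1.0,
               leaf_length = -0.6, leaf_width = -0.5, RWC = -1.0,
               Chl = -0.4, BBCH = -0.6, Phi_Po = -0.12, Phi_PSII = -0.4,
               Phi_P = -0.5, qP = -0.3, Phi_NPQ = 0.8, Phi_fD = 0.4),
    recovery = c(Pro = 2.0, OH_Pro = 2.0, Cit = 3.55, Spd = 1.0,
                 Cad = 2.0, DAP = 1.0, Tyra = 2.0, Put = 1.5,
                 total_AA = 0.8, total_PA = 1.0, APX = 2.0,
                 canopy_height = -0.3, biomass = -1.0, leaf_length = -0.4,
                 RWC = -0.07, Phi_Po = -0.05, Phi_PSII = -0.15,
                 Phi_NPQ = 0.4, Phi_fD = 0.2))
}

#' Simulate a trait-and-metabolite table with injected effects
#'
#' Generates the tabular counterpart of a full screening experiment:
#' `n_per_group` sample units for each of the four groups W/D x
#' stress/recovery, with 47 numeric variables (15 traits, 32 biochemical
#' variables). Group means of the D samples are shifted by the injected
#' log2 `effects`; a latent per-sample factor (sd `latent_sd` on the log
#' scale) loads positively on metabolites and negatively on growth
#' traits, giving the correlated structure a PCA separates; multiplicative
#' lognormal noise of coefficient of variation `noise_cv` is added on top.
#' With zero effects all four groups are exchangeable.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param effects A list like [default_trait_effects()]; named log2 shifts
#'   applied to D samples per phase.
#' @param latent_sd Standard deviation of the latent factor (log scale).
#' @param noise_cv Lognormal noise coefficient of variation.
#' @param seed Optional integer seed.
#' @return A data frame: `sample_id`, `tray`, `variant`, `phase`, then the
#'   47 numeric variables.
#' @export
simulate_trait_table <- function(n_per_group = 3,
                                 effects = default_trait_effects(),
                                 latent_sd = 0.10, noise_cv = 0.10,
                                 seed = NULL) {
  if (n_per_group < 3) stop_invalid_input("n_per_group must be >= 3")
  vars <- trait_variables()
  with_seed(seed, {
    groups <- expand.grid(variant = c("W", "D"), phase = c("stress", "recovery"),
                          stringsAsFactors = FALSE)
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      v <- groups$variant[gi]; ph <- groups$phase[gi]
      eff <- effects[[ph]]
      for (s in seq_len(n_per_group)) {
        z <- stats::rnorm(1, 0, latent_sd)
        e <- ifelse(vars$name %in% names(eff) & v == "D",
                    eff[vars$name], 0)
        e[is.na(e)] <- 0
        vals <- vars$baseline * 2^e * exp(vars$dir * z) *
          exp(stats::rnorm(nrow(vars), 0, noise_cv))
        row <- as.data.frame(as.list(stats::setNames(vals, vars$name)))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(sample_id = sprintf("%s_%s_%d", v, ph, s), tray = s,
                     variant = v, phase = ph), row)
      }
    }
    do.call(rbind, rows)
  })
}
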