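test_that("render_tray is deterministic and records exact ground truth", {
  sp <- canopy_spec(seed = 31)
  r1 <- render_tray(sp)
  r2 <- render_tray(sp)
  expect_identical(r1$pixels, r2$pixels)
  expect_identical(r1$truth, r2$truth)

  # truth tops equal the requested canopy-top rows (a blade is forced there)
  expect_equal(unname(r1$truth_top_rows), sp$canopy_top)

  # zero blades: empty truth, and the canopy module reports no plant
  sp0 <- canopy_spec(n_blades = 0, noise = 0, seed = 1)
  r0 <- render_tray(sp0)
  expect_equal(sum(r0$truth), 0)
  expect_error(line_descent_height(r0$truth, sp0$layout$left_roi,
                                   sp0$layout$soil_row, 0.2),
               class = "canopydyn_no_plant")

  # noise-free rendering: line descent lands within 3 px of the truth top
  spn <- canopy_spec(noise = 0, seed = 32)
  rn <- render_tray(spn)
  res <- line_descent_height(rn$truth, spn$layout$left_roi,
                             spn$layout$soil_row, 0.2)
  truth_h <- spn$layout$soil_row - rn$truth_top_rows[["left"]]
  expect_lte(abs(res$height_px - truth_h), 3)

  expect_error(canopy_spec(canopy_top = c(400, 100)), class = "canopydyn_invalid_spec")
  expect_error(canopy_spec(noise = 0.5), class = "canopydyn_invalid_spec")
})

test_that("growth series: piecewise-linear truth, seeded noise, W/D structure", {
  ks <- kinetics_spec(noise_sd = 0, n_trays = 2, seed = 5)
  s <- simulate_growth_series(ks)
  expect_equal(nrow(s), 2 * 2 * length(ks$days))
  expect_identical(s$height_px, s$height_true)

  # W and D coincide up to the separation day and differ afterwards
  w <- kinetics_truth(ks, variant = "W")
  d <- kinetics_truth(ks, variant = "D")
  pre <- ks$days <= ks$separation_day
  expect_equal(d[pre], w[pre])
  expect_true(all(d[!pre] < w[!pre]))

  # same seed gives identical noisy output
  ksn <- kinetics_spec(noise_sd = 0.02, seed = 6)
  expect_identical(simulate_growth_series(ksn), simulate_growth_series(ksn))

  # identical curves (no-stress control): detection must fail
  ctl <- simulate_growth_series(kinetics_spec(noise_sd = 0, n_trays = 1, seed = 7))
  Wc <- ctl[ctl$variant == "W", c("day", "height_px")]
  expect_error(detect_separation_day(Wc, Wc, rule = "gap"),
               class = "canopydyn_no_separation")

  expect_error(kinetics_spec(separation_day = 16, rewater_day = 15),
               class = "canopydyn_invalid_spec")
  expect_error(kinetics_spec(stress_slope = 10), class = "canopydyn_invalid_spec")
})

test_that("fluorescence trace generator respects invariants and stress trend", {
  tr0 <- simulate_fluor_traces(400, stress_level = 0, seed = 21)
  expect_true(all(tr0$F0 > 0 & tr0$FM >= tr0$F0))
  expect_true(all(tr0$FMprime > tr0$Ft & tr0$Ft > 0))
  expect_true(all(tr0$FM >= tr0$FMprime))
  phi_Po <- (tr0$FM - tr0$F0) / tr0$FM
  expect_gte(mean(phi_Po), 0.78)
  expect_lte(mean(phi_Po), 0.84)

  # stress lowers phi_Po and raises phi_NPQ on average
  tr1 <- simulate_fluor_traces(400, stress_level = 1, seed = 22)
  y0 <- colMeans(do.call(rbind, lapply(seq_len(200), function(i)
    unlist(quenching_yields(tr0$F0[i], FM = tr0$FM[i], Ft = tr0$Ft[i],
                            FMprime = tr0$FMprime[i])[c("phi_Po", "phi_NPQ")]))))
  y1 <- colMeans(do.call(rbind, lapply(seq_len(200), function(i)
    unlist(quenching_yields(tr1$F0[i], FM = tr1$FM[i], Ft = tr1$Ft[i],
                            FMprime = tr1$FMprime[i])[c("phi_Po", "phi_NPQ")]))))
  expect_lt(y1[["phi_Po"]], y0[["phi_Po"]])
  expect_gt(y1[["phi_NPQ"]], y0[["phi_NPQ"]])

  expect_identical(simulate_fluor_traces(50, 0.3, seed = 23),
                   simulate_fluor_traces(50, 0.3, seed = 23))
})

test_that("trait table carries 47 variables and the injected effects", {
  tt <- simulate_trait_table(n_per_group = 4, seed = 41)
  meta <- c("sample_id", "tray", "variant", "phase")
  expect_equal(ncol(tt) - length(meta), 47)
  expect_equal(nrow(tt), 4 * 4)
  expect_identical(simulate_trait_table(n_per_group = 4, seed = 41), tt)

  # injected Pro effect is recovered by the fold-change estimator
  eff <- list(stress = c(Pro = 3), recovery = c(Pro = 0.5))
  tt2 <- simulate_trait_table(n_per_group = 20, effects = eff,
                              latent_sd = 0.05, noise_cv = 0.05, seed = 42)
  st <- tt2[tt2$phase == "stress", ]
  fc <- log2_fold_change(mean(st$Pro[st$variant == "D"]),
                         mean(st$Pro[st$variant == "W"]))
  expect_lt(abs(fc - 3), 0.3)

  # zero effects: variants are exchangeable, so PC1-vs-variant tests are
  # null across seeds (median p near 0.5, well above any rejection level)
  ps <- vapply(1:15, function(s) {
    tt0 <- simulate_trait_table(n_per_group = 10, effects = list(
      stress = numeric(0), recovery = numeric(0)), seed = 100 + s)
    pc <- trait_pca(tt0[, !(names(tt0) %in% c("sample_id", "tray"))])
    stats::kruskal.test(pc$scores$PC1, factor(tt0$variant))$p.value
  }, numeric(1))
  expect_gt(median(ps), 0.1)

  # default effects: within the stress phase, PC1 separates W from D
  # completely in nearly every replicate
  sep <- vapply(1:10, function(s) {
    ttd <- simulate_trait_table(n_per_group = 6, seed = 200 + s)
    pcd <- trait_pca(ttd[, !(names(ttd) %in% c("sample_id", "tray"))])
    sc <- pcd$scores$PC1[ttd$phase == "stress"]
    vr <- ttd$variant[ttd$phase == "stress"]
    max(sc[vr == "D"]) < min(sc[vr == "W"]) ||
      min(sc[vr == "D"]) > max(sc[vr == "W"])
  }, logical(1))
  expect_gte(mean(sep), 0.9)
})
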