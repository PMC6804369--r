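test_that("F0' estimate matches hand arithmetic and its limits", {
  expect_equal(estimate_F0prime(1000, 5000, 3000), 1000 / (0.8 + 1 / 3))
  # dark-adapted limit FM' = FM reduces to F0
  expect_equal(estimate_F0prime(1000, 5000, 5000), 1000)
  # homogeneous of degree 1
  expect_equal(estimate_F0prime(2000, 10000, 6000),
               2 * estimate_F0prime(1000, 5000, 3000))
  expect_error(estimate_F0prime(-1, 5000, 3000), class = "canopydyn_invalid_input")
  expect_error(estimate_F0prime(5000, 5000, 3000), class = "canopydyn_invalid_input")
})

test_that("quenching yields reproduce the worked trace and the limit cases", {
  y <- quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 1500,
                                    FMprime = 3000))
  expect_equal(y$phi_Po, 0.8)
  expect_equal(y$phi_PSII, (3000 - 1000 / (0.8 + 1/3)) / 3000, tolerance = 1e-12)
  expect_equal(y$phi_PSII, 0.70588, tolerance = 1e-4)
  expect_equal(y$qP, 0.70833, tolerance = 1e-4)
  expect_equal(y$phi_P, 0.5)
  expect_equal(y$phi_fD, 0.3)
  expect_equal(y$phi_NPQ, 0.2)
  expect_equal(y$phi_P + y$phi_NPQ + y$phi_fD, 1, tolerance = 1e-12)
  expect_equal(y$F0prime_source, "estimated")

  # dark-adapted, no NPQ: qP = 1, phi_NPQ = 0, phi_P = phi_Po
  yd <- quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 1000,
                                     FMprime = 5000, F0prime = 1000))
  expect_equal(yd$qP, 1)
  expect_equal(yd$phi_NPQ, 0)
  expect_equal(yd$phi_P, yd$phi_Po)
  expect_equal(yd$phi_fD, 0.2)
  expect_equal(yd$F0prime_source, "measured")

  # fully closed centers Ft = FM': qP = 0 and the partition is all non-photochemical
  yc <- quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 3000,
                                     FMprime = 3000))
  expect_equal(yc$qP, 0)
  expect_equal(yc$phi_P, 0)
  expect_equal(yc$phi_NPQ + yc$phi_fD, 1)

  expect_error(fluor_trace(F0 = 1000, FM = 5000, Ft = 3500, FMprime = 3000),
               class = "canopydyn_invalid_trace")
  expect_error(quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 100,
                                            FMprime = 3000, F0prime = 3000)),
               class = "canopydyn_degenerate_trace")
  expect_warning(fluor_trace(F0 = 1000, FM = 5000, Ft = 1000, FMprime = 5500),
                 "implausible")
})

test_that("partition identity and phi_P equivalence hold over random traces", {
  tr <- simulate_fluor_traces(2000, stress_level = 0.5, seed = 77)
  for (i in seq_len(nrow(tr))) {
    y <- quenching_yields(fluor_trace(F0 = tr$F0[i], FM = tr$FM[i],
                                      Ft = tr$Ft[i], FMprime = tr$FMprime[i]))
    expect_lt(abs(y$phi_P + y$phi_NPQ + y$phi_fD - 1), 1e-9)
    expect_lt(abs(y$phi_P - (tr$FMprime[i] - tr$Ft[i]) / tr$FMprime[i]), 1e-12)
  }
})

test_that("yields are invariant under rescaling the whole trace", {
  base <- quenching_yields(fluor_trace(F0 = 800, FM = 4100, Ft = 1900,
                                       FMprime = 2700))
  for (k in c(0.1, 3, 250)) {
    sc <- quenching_yields(fluor_trace(F0 = 800 * k, FM = 4100 * k,
                                       Ft = 1900 * k, FMprime = 2700 * k))
    for (nm in c("phi_Po", "phi_PSII", "qP", "phi_P", "phi_NPQ", "phi_fD"))
      expect_equal(sc[[nm]], base[[nm]], tolerance = 1e-12)
  }
})

test_that("mask aggregation averages per-pixel yields and keeps the identity", {
  mk <- function(v) matrix(v, 2, 2)
  # uniform frames equal the scalar computation
  frames <- list(F0 = mk(1000), FM = mk(5000), Ft = mk(1500), FMprime = mk(3000))
  mask <- matrix(TRUE, 2, 2)
  y <- yields_over_mask(frames, mask)
  expect_equal(y$phi_P, 0.5)
  expect_equal(y$phi_P + y$phi_NPQ + y$phi_fD, 1, tolerance = 1e-12)

  # two-region frame: Ft differs by pixel; mean of per-pixel phi_P
  frames2 <- frames
  frames2$Ft <- matrix(c(1500, 1500, 600, 600), 2, 2)
  y2 <- yields_over_mask(frames2, mask)
  expect_equal(y2$phi_P, mean(c(0.5, 0.5, 0.8, 0.8)))
  expect_equal(y2$phi_P + y2$phi_NPQ + y2$phi_fD, 1, tolerance = 1e-12)

  # restricting the mask to one region equals that region's scalar yields
  mreg <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  y3 <- yields_over_mask(frames2, mreg)
  ysc <- quenching_yields(fluor_trace(F0 = 1000, FM = 5000, Ft = 600,
                                      FMprime = 3000))
  expect_equal(y3$phi_P, ysc$phi_P, tolerance = 1e-12)
  expect_equal(y3$qP, ysc$qP, tolerance = 1e-12)

  expect_error(yields_over_mask(frames, matrix(FALSE, 2, 2)),
               class = "canopydyn_no_plant")
  expect_error(yields_over_mask(frames, matrix(TRUE, 3, 3)),
               class = "canopydyn_invalid_input")
})
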