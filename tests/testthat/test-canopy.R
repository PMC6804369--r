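test_that("crit_for_row counts mask pixels over the ROI width", {
  m <- matrix(FALSE, 5, 10)
  m[2, c(1, 4, 7)] <- TRUE
  expect_equal(crit_for_row(m, 2, c(1, 11)), 0.3)
  expect_equal(crit_for_row(m, 3, c(1, 11)), 0)     # empty row
  m[4, ] <- TRUE
  expect_equal(crit_for_row(m, 4, c(1, 11)), 1)     # fully covered
  expect_error(crit_for_row(m, 2, c(4, 4)), class = "canopydyn_invalid_input")
  expect_error(crit_for_row(m, 99, c(1, 11)), class = "canopydyn_invalid_input")
})

test_that("line descent reproduces hand-derived stop rows and heights", {
  # only full-width row is row 8 (rows above empty): stop there, height 4
  m <- matrix(FALSE, 12, 10); m[8, ] <- TRUE
  r <- line_descent_height(m, c(1, 11), soil_row = 12, tau = 0.5)
  expect_equal(r$stop_row, 8)
  expect_equal(r$height_px, 4)
  expect_true(is.na(r$flag))
  # profile: visited rows end at the stop row, criterion values bounded
  expect_equal(tail(r$crit_profile$row, 1), 8)
  expect_true(all(r$crit_profile$crit >= 0 & r$crit_profile$crit <= 1))
  expect_true(all(head(r$crit_profile$crit, -1) <= 0.5))
  expect_gt(tail(r$crit_profile$crit, 1), 0.5)

  # single pixel at row 3 of 12: crit 0.1 beats tau 0.05, height 9
  m1 <- matrix(FALSE, 12, 10); m1[3, 5] <- TRUE
  r1 <- line_descent_height(m1, c(1, 11), soil_row = 12, tau = 0.05)
  expect_equal(r1$stop_row, 3)
  expect_equal(r1$height_px, 9)

  # same mask, tau 0.5: threshold never exceeded
  r2 <- line_descent_height(m1, c(1, 11), soil_row = 12, tau = 0.5)
  expect_equal(r2$height_px, 0)
  expect_equal(r2$stop_row, 12)
  expect_equal(r2$flag, "threshold_never_exceeded")

  expect_error(line_descent_height(matrix(FALSE, 5, 5), c(1, 6), 5, 0.2),
               class = "canopydyn_no_plant")
})

test_that("line descent agrees with the brute-force row scan on random masks", {
  set.seed(101)
  for (i in 1:300) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    m <- random_mask(h, w, runif(1, 0.05, 0.6))
    roi <- c(1, w + 1)
    if (!any(m)) next
    for (tau in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      want <- naive_line_descent(m, roi, h, tau)
      got <- line_descent_height(m, roi, h, tau)
      expect_equal(got$stop_row, want$stop_row)
      expect_equal(got$height_px, want$height_px)
      expect_equal(is.na(got$flag), is.na(want$flag))
    }
  }
})

test_that("height is monotone in mask content and in tau", {
  set.seed(202)
  for (i in 1:40) {
    m <- random_mask(14, 12, 0.3)
    if (!any(m[1:14, ])) next
    roi <- c(1, 13)
    r <- line_descent_height(m, roi, 14, 0.4)
    # adding pixels at/above the stop row can only raise or keep the height
    m_plus <- m
    empty_above <- which(!m & row(m) <= r$stop_row)
    if (length(empty_above)) {
      m_plus[sample(empty_above, 1)] <- TRUE
      r_plus <- line_descent_height(m_plus, roi, 14, 0.4)
      expect_gte(r_plus$height_px, r$height_px)
    }
    # height is non-increasing in tau
    taus <- c(0.1, 0.2, 0.4, 0.6, 0.8)
    hs <- sapply(taus, function(tt) line_descent_height(m, roi, 14, tt)$height_px)
    expect_true(all(diff(hs) <= 0))
  }
})

test_that("heights_for_tray measures both containers against ground truth", {
  lay <- tray_layout(split_column = 240, left_roi = c(11, 231),
                     right_roi = c(251, 471), soil_row = 200)
  sp <- canopy_spec(H = 230, W = 480, layout = lay, canopy_top = c(40, 60),
                    seed = 11)
  r <- render_tray(sp)
  hr <- heights_for_tray(r$pixels, lay, tau = 0.2)
  expect_lte(abs(hr$left$height_px - 160), 3)
  expect_lte(abs(hr$right$height_px - 140), 3)

  # identical canopies left and right differ by at most a pixel
  sp2 <- canopy_spec(H = 230, W = 480, layout = lay, canopy_top = c(50, 50),
                     seed = 12)
  hr2 <- heights_for_tray(render_tray(sp2)$pixels, lay, tau = 0.2)
  expect_lte(abs(hr2$left$height_px - hr2$right$height_px), 1)

  # blank right container: left stays valid, right is flagged no_plant
  sp3 <- canopy_spec(H = 230, W = 480, layout = lay, canopy_top = c(40, NA),
                     seed = 13)
  hr3 <- heights_for_tray(render_tray(sp3)$pixels, lay, tau = 0.2)
  expect_false(is.na(hr3$left$height_px))
  expect_equal(hr3$right$flag, "no_plant")
  expect_true(is.na(hr3$right$height_px))
})

test_that("estimated height tracks truth across a simulated series (MAE <= 3 px)", {
  ks <- kinetics_spec(noise_sd = 0, n_trays = 1)
  days <- c(6, 9, 12, 15, 17, 19)
  errs <- c()
  for (i in seq_along(days)) {
    hD <- kinetics_truth(ks, days[i], "D")
    hW <- kinetics_truth(ks, days[i], "W")
    H <- 2800L; soil <- 2700L
    lay <- tray_layout(split_column = 270, left_roi = c(11, 251),
                       right_roi = c(291, 531), soil_row = soil)
    sp <- canopy_spec(H = H, W = 540, layout = lay,
                      canopy_top = round(c(soil - hD, soil - hW)), seed = 500 + i)
    r <- render_tray(sp)
    hr <- heights_for_tray(r$pixels, lay, tau = 0.2)
    errs <- c(errs, abs(hr$left$height_px - hD), abs(hr$right$height_px - hW))
  }
  expect_lte(mean(errs), 3)
})
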