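test_that("spherical ROI median matches a brute-force oracle, with lower-middle ties", {
  vol <- array(100, c(9, 9, 9))
  expect_equal(roi_enhancement(vol, c(5, 5, 5), 3, c(1, 1, 1)), 100)
  # radius below half the voxel size isolates the center voxel
  vol[5, 5, 5] <- 7
  expect_equal(roi_enhancement(vol, c(5, 5, 5), 0.4, c(1, 1, 1)), 7)
  # five-voxel sphere: center + 4 in-plane neighbours (1x1x2 mm voxels)
  vol5 <- array(999, c(9, 9, 9))
  vol5[5, 5, 5] <- 30; vol5[4, 5, 5] <- 10; vol5[6, 5, 5] <- 50
  vol5[5, 4, 5] <- 20; vol5[5, 6, 5] <- 40
  vals <- c(10, 20, 30, 40, 50)
  oracle <- sort(vals)[floor((length(vals) + 1) / 2)]
  expect_equal(roi_enhancement(vol5, c(5, 5, 5), 1, c(1, 1, 2)), oracle)
  expect_equal(oracle, 30)
  # even count: 1D sphere of 4 voxels, lower-middle convention
  vol4 <- array(0, c(4, 1, 1)); vol4[, 1, 1] <- c(10, 20, 30, 40)
  expect_equal(roi_enhancement(vol4, c(2, 1, 1), 2, c(1, 1, 1)),
               sort(c(10, 20, 30, 40))[2])
})

test_that("AV ratio subtracts blood density and guards its denominator", {
  expect_equal(av_ratio(140, 90, 40), 2)
  expect_equal(av_ratio(40, 140, 40), 0)
  expect_true(is.na(av_ratio(140, 40, 40)))
  expect_equal(av_ratio(30, 90, 40), 0)  # negative excess clamps to 0
  r <- av_ratio(c(140, 40, 140), c(90, 140, 40))
  expect_equal(r, c(2, 0, NA))
})

test_that("contrast arrival interpolates the baseline + delta crossing", {
  a <- c(40, 40, 40, 60, 120); t <- c(0, 2, 4, 6, 8)
  expect_equal(contrast_arrival(a, t, extraction_params(arrival_delta_hu = 10)), 5)
  expect_error(contrast_arrival(rep(40, 5), t),
               class = "collateraltime_arrival_error")
  # arrival is monotone nondecreasing in the detection delta
  a2 <- c(40, 40, 45, 70, 150, 200)
  t2 <- seq(0, 10, 2)
  arr <- sapply(c(1, 5, 20, 60), function(d)
    contrast_arrival(a2, t2, extraction_params(arrival_delta_hu = d)))
  expect_true(all(diff(arr) >= 0))
})

test_that("extracted curves have one sample per frame and reflect phantom symmetry", {
  cfg <- small_config(collateral_fraction = 1, collateral_delay_s = 0)
  ph <- generate_phantom(cfg)
  tic <- extract_tics(ph$series, ph$regions)
  expect_equal(nrow(tic), length(ph$series$times_s))
  expect_equal(nrow(tic), 30)  # 2 s frames over 58 s
  cr <- tic$cr_percent[!is.na(tic$cr_percent)]
  expect_true(length(cr) > 5)
  expect_equal(cr, rep(100, length(cr)))
  # arterial peak precedes the venous peak by the configured delay
  dpk <- tic$time_s[which.max(tic$venous_hu)] - tic$time_s[which.max(tic$arterial_hu)]
  expect_lte(abs(dpk - cfg$venous_delay_s), cfg$frame_interval_s)
  # av validity tracks venous > blood exactly
  expect_identical(is.na(tic$av_ratio), !(tic$venous_hu > 40))
})

test_that("dropping the last frame only changes trailing curve samples", {
  ph <- generate_phantom(small_config(seed = 3))
  tic_full <- extract_tics(ph$series, ph$regions)
  n <- length(ph$series$times_s)
  short <- new_ctp_series(ph$series$data[, , , -n, drop = FALSE],
                          ph$series$times_s[-n], ph$series$voxel_size_mm)
  tic_short <- extract_tics(short, ph$regions)
  expect_equal(as.data.frame(tic_short), as.data.frame(tic_full[-n, ]))
})

test_that("time-invariant MIP dominates every frame and preserves symmetry", {
  set.seed(4)
  dat <- array(rnorm(5 * 5 * 5 * 6, 50, 20), c(5, 5, 5, 6))
  ser <- new_ctp_series(dat, seq(0, 10, 2), c(1, 1, 1))
  mip <- time_invariant_mip(ser)
  for (i in 1:6) expect_true(all(mip >= dat[, , , i]))
  # duplicated single frame: MIP equals the frame
  ser2 <- new_ctp_series(array(rep(dat[, , , 1], 2), c(5, 5, 5, 2)),
                         c(0, 2), c(1, 1, 1))
  expect_equal(time_invariant_mip(ser2), dat[, , , 1])
  # symmetric phantom: CR of the MIP is exactly 100
  ph <- generate_phantom(small_config(collateral_fraction = 1,
                                      collateral_delay_s = 0))
  expect_equal(cr_mip(ph$series, ph$regions), 100)
})

test_that("the MIP CR captures late collateral filling missed at the arterial peak", {
  ph <- generate_phantom(small_config(collateral_fraction = 0.6,
                                      collateral_delay_s = 3))
  tic <- extract_tics(ph$series, ph$regions)
  cr_at_art_peak <- tic$cr_percent[which.max(tic$arterial_hu)]
  expect_gte(cr_mip(ph$series, ph$regions), cr_at_art_peak)
})
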