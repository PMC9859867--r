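test_that("equilibrium is the interpolated downward crossing of the AV ratio through 1", {
  # ratios 1.5 then 0.8 at t = 10, 12: crossing at 10 + 2 * 0.5/0.7
  tic <- make_tic(c(10, 12), arterial = c(100, 80), venous = c(80, 90),
                  arrival_s = 0)
  expect_equal(find_equilibrium(tic), 10 + 2 * (0.5 / 0.7), tolerance = 1e-12)
  # an exact sample at ratio 1 after the peak is returned as-is
  tic2 <- make_tic(c(10, 12, 14), arterial = c(100, 80, 60),
                   venous = c(80, 80, 80), arrival_s = 0)
  expect_equal(find_equilibrium(tic2), 12)
  # ratio never falling back through 1: no equilibrium
  tic3 <- make_tic(c(10, 12, 14), arterial = c(100, 120, 140),
                   venous = c(60, 60, 60), arrival_s = 0)
  expect_error(find_equilibrium(tic3),
               class = "collateraltime_equilibrium_error")
})

# synthetic ratio curve hitting round values: r = 1 + 20*(a-40)/..., built
# from constant venous excess so ratio values are exact
ratio_tic <- function(r, times = seq(0, by = 2, length.out = length(r))) {
  make_tic(times, arterial = 40 + 20 * r, venous = rep(60, length(r)),
           arrival_s = times[1])
}

test_that("normalization sends the peak to 1 and equilibrium to 0", {
  tic <- ratio_tic(c(1.2, 3, 2, 1.5, 1, 0.5, 0.3, 0.4))
  nc <- normalize_av_curve(tic)
  expect_equal(attr(nc, "t_peak_s"), 2)
  expect_equal(nc$normalized[nc$time_s == 2], 1)
  expect_equal(attr(nc, "t_equi_s"), 8)
  expect_equal(nc$normalized[nc$time_s == 8], 0)
  expect_equal(nc$normalized[nc$time_s == 10], (0.5 - 1) / (3 - 1))
  expect_equal(attr(nc, "t_min_s"), 12)
  # flat curve is degenerate
  expect_error(normalize_av_curve(ratio_tic(rep(1, 6))),
               class = "collateraltime_equilibrium_error")
})

test_that("phase classification follows the normalized thresholds with later-phase ties", {
  tic <- ratio_tic(c(1.2, 3, 2, 1.5, 1, 0.5, 0.3, 0.4))
  nc <- normalize_av_curve(tic)
  # v = 0.6 on the upslope (before the peak) is early arterial
  t_up <- 0 + (0.6 - 0.1) / (1 - 0.1) * 2  # interp between v(0)=0.1, v(2)=1
  expect_equal(classify_phase(nc, t_up), "EA")
  # v = 0.6 after the peak is peak arterial
  t_down <- 2 + (1 - 0.6) / (1 - 0.5) * 2  # interp between v(2)=1, v(4)=0.5
  expect_equal(classify_phase(nc, t_down), "PA")
  # v = -0.2 between equilibrium and the minimum is early venous
  expect_equal(classify_phase(nc, 9.5), "PV")
  # after the minimum: late venous
  expect_equal(classify_phase(nc, 13), "LV")
  # boundary v = 0.5 after the peak belongs to the later phase (EQ)
  expect_equal(classify_phase(nc, 4), "EQ")
  expect_error(classify_phase(nc, 100), class = "collateraltime_range_error")
})

test_that("phase labels are temporally ordered along the curve", {
  ph <- generate_phantom(small_config())
  tic <- extract_tics(ph$series, ph$regions)
  nc <- normalize_av_curve(tic)
  vr <- attr(nc, "valid_range")
  tt <- seq(vr[1], vr[2], 0.05)
  lab <- classify_phase(nc, tt)
  idx <- as.integer(factor(lab, levels = c("PRE", "EA", "PA", "EQ", "PV", "LV")))
  expect_true(all(diff(idx) >= 0))
})

test_that("normalization is invariant to a shared rescaling of both enhancement excesses", {
  ph <- generate_phantom(small_config())
  tic <- extract_tics(ph$series, ph$regions)
  scaled <- make_tic(tic$time_s,
                     arterial = 40 + 2.7 * (tic$arterial_hu - 40),
                     venous = 40 + 2.7 * (tic$venous_hu - 40),
                     arrival_s = attr(tic, "arrival_s"))
  nc <- normalize_av_curve(tic)
  nc2 <- normalize_av_curve(scaled)
  expect_equal(nc2$normalized, nc$normalized, tolerance = 1e-10)
  expect_equal(attr(nc2, "t_equi_s"), attr(nc, "t_equi_s"), tolerance = 1e-10)
})
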