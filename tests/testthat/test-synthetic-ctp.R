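test_that("identical config and seed give bit-identical phantoms, different seeds differ", {
  cfg <- small_config(noise_sd_hu = 5, seed = 11L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$series$data, b$series$data)
  c2 <- generate_phantom(small_config(noise_sd_hu = 5, seed = 12L))
  expect_false(identical(a$series$data, c2$series$data))
})

test_that("symmetric noise-free phantom has mirror-identical vessel enhancement", {
  ph <- generate_phantom(small_config(collateral_fraction = 1,
                                      collateral_delay_s = 0))
  nx <- dim(ph$series$data)[1]
  for (i in c(1, 6, 10)) {
    frame <- ph$series$data[, , , i]
    occ <- frame * ph$regions$mca_occluded_mask
    con <- frame * ph$regions$mca_contralateral_mask
    expect_equal(occ[nx:1, , ], con, tolerance = 1e-12)
  }
})

test_that("zero collateral fraction leaves the occluded side unenhanced", {
  ph <- generate_phantom(small_config(collateral_fraction = 0))
  tic <- extract_tics(ph$series, ph$regions)
  expect_true(all(tic$vol_occluded_ml == 0))
  expect_true(all(tic$cr_percent[!is.na(tic$cr_percent)] == 0))
})

test_that("occluded-side enhanced volume is monotone in collateral fraction", {
  vols <- sapply(c(0.2, 0.5, 0.8, 1), function(f) {
    ph <- generate_phantom(small_config(collateral_fraction = f))
    tic <- extract_tics(ph$series, ph$regions)
    tic$vol_occluded_ml
  })
  for (j in 2:ncol(vols)) expect_true(all(vols[, j] >= vols[, j - 1]))
})

test_that("venous ROI peak lags the arterial ROI peak by the configured delay", {
  cfg <- small_config(venous_delay_s = 6)
  ph <- generate_phantom(cfg)
  tic <- extract_tics(ph$series, ph$regions)
  t_art <- tic$time_s[which.max(tic$arterial_hu)]
  t_ven <- tic$time_s[which.max(tic$venous_hu)]
  expect_lte(abs((t_ven - t_art) - cfg$venous_delay_s), cfg$frame_interval_s)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(collateral_fraction = 1.2),
               class = "collateraltime_config_error")
  expect_error(phantom_config(frame_interval_s = 4, duration_s = 40),
               class = "collateraltime_config_error")  # fewer than 20 frames
  expect_error(phantom_config(aif_beta = 0),
               class = "collateraltime_config_error")
})

test_that("mCTA sampling times follow offset + cumulative delays and match CTP frames", {
  ph <- generate_phantom(small_config())
  s <- sample_mcta(ph, 8, c(8, 8))
  expect_equal(s$times_s, c(8, 16, 24))
  expect_equal(s$truth$true_mcta_offset_s, 8)
  # noise-free sampling at a frame time reproduces that CTP frame
  i16 <- which(ph$series$times_s == 16)
  expect_equal(s$volumes[[2]], ph$series$data[, , , i16], tolerance = 1e-12)
  # zero delays give three identical volumes
  s0 <- sample_mcta(ph, 20, c(0, 0))
  expect_identical(s0$volumes[[1]], s0$volumes[[3]])
  expect_error(sample_mcta(ph, 50, c(8, 8)),
               class = "collateraltime_range_error")
})

test_that("cohort generation is seeded, sized, and covariates track the collateral fraction", {
  co <- generate_cohort(58, small_config(), seed = 5)
  expect_equal(nrow(co), 58)
  expect_true(all(co$aspects >= 0 & co$aspects <= 10))
  expect_true(all(co$nihss >= 0 & co$nihss <= 42))
  expect_identical(co, generate_cohort(58, small_config(), seed = 5))
  expect_false(identical(co$collateral_fraction,
                         generate_cohort(58, small_config(), seed = 6)$collateral_fraction))
  # zero covariate noise: deterministic monotone link
  co0 <- generate_cohort(20, small_config(), seed = 5,
                         covariate_noise_sd = c(0, 0))
  ord <- order(co0$collateral_fraction)
  expect_true(all(diff(co0$aspects[ord]) >= 0))
  expect_true(all(diff(co0$nihss[ord]) <= 0))
  expect_error(generate_cohort(1, small_config()),
               class = "collateraltime_parameter_error")
})
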