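test_that("ratios sampled from the CTP curve are recovered at the true offset", {
  ph <- generate_phantom(small_config())
  tic <- extract_tics(ph$series, ph$regions)
  truth <- 16.3
  al <- align_mcta(tic_av_at(tic, truth + c(0, 8, 16)), c(8, 8), tic)
  expect_lte(abs(al$offset_s - truth), 0.1)
  expect_lt(al$residual, 1e-6)
  expect_equal(al$aligned_times_s, al$offset_s + c(0, 8, 16))
})

test_that("the returned offset is a global minimum of the objective", {
  ph <- generate_phantom(small_config(seed = 9))
  tic <- extract_tics(ph$series, ph$regions)
  ratios <- tic_av_at(tic, 18.7 + c(0, 8, 16)) + c(0.02, -0.03, 0.01)
  al <- align_mcta(ratios, c(8, 8), tic)
  ok <- !is.na(tic$av_ratio) & tic$time_s >= attr(tic, "arrival_s")
  obj <- function(off) sum(abs(ratios - approx(tic$time_s[ok], tic$av_ratio[ok],
                                               xout = off + c(0, 8, 16))$y))
  set.seed(1)
  rand <- runif(500, min(tic$time_s[ok]), max(tic$time_s[ok]) - 16)
  expect_true(all(obj(al$offset_s) <= sapply(rand, obj) + 1e-12))
})

test_that("a rigid time shift of curve and samples shifts the recovered offset equally", {
  ph <- generate_phantom(small_config())
  tic <- extract_tics(ph$series, ph$regions)
  al1 <- align_mcta(tic_av_at(tic, 16 + c(0, 8, 16)), c(8, 8), tic)
  delta <- 4
  shifted <- make_tic(tic$time_s + delta, tic$arterial_hu, tic$venous_hu,
                      arrival_s = attr(tic, "arrival_s") + delta,
                      vol_occ = tic$vol_occluded_ml,
                      vol_con = tic$vol_contralateral_ml)
  al2 <- align_mcta(tic_av_at(tic, 16 + c(0, 8, 16)), c(8, 8), shifted)
  expect_lte(abs((al2$offset_s - al1$offset_s) - delta), 0.1 + 1e-9)
})

test_that("flat ratio curves warn and fall back to the earliest offset", {
  flat <- make_tic(seq(0, 40, 2), arterial = rep(80, 21),
                   venous = rep(60, 21), arrival_s = 0)
  expect_warning(al <- align_mcta(c(2, 2, 2), c(8, 8), flat),
                 class = "collateraltime_degenerate_alignment_warning")
  expect_equal(al$offset_s, 0)
})

test_that("infeasible windows and manual overrides are handled", {
  ph <- generate_phantom(small_config())
  tic <- extract_tics(ph$series, ph$regions)
  expect_error(align_mcta(c(1, 1, 1), c(40, 40), tic),
               class = "collateraltime_alignment_error")
  al <- align_mcta(tic_av_at(tic, 14 + c(0, 8, 16)), c(8, 8), tic,
                   offset_s = 20)
  expect_equal(al$offset_s, 20)
})

test_that("phase counts tabulate by mCTA position and conserve subjects", {
  df <- tibble::tibble(
    position = rep(c("baseline", "delay1", "delay2"), 4),
    phase = c("EQ", "PV", "LV", "EQ", "PV", "LV", "PA", "EQ", "PV", "EQ", "LV", "LV"))
  tab <- summarize_phase_distribution(df)
  expect_equal(nrow(tab), 3)
  counts <- as.matrix(tab[, c("PRE", "EA", "PA", "EQ", "PV", "LV")])
  expect_equal(unname(rowSums(counts)), c(4, 4, 4))
  expect_equal(tab$EQ[tab$position == "baseline"], 3L)
  expect_error(summarize_phase_distribution(df[0, ]),
               class = "collateraltime_parameter_error")
})
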