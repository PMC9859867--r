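# Shared fixtures: small noise-free phantoms and hand-built curve tables.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(32L, 32L, 16L), noise_sd_hu = 0)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# Build a tic_curves object directly from per-frame vectors, bypassing the
# image stage, for curve-level unit tests.
make_tic <- function(times, arterial, venous, blood_hu = 40,
                     vol_occ = NULL, vol_con = NULL, arrival_s = NULL) {
  n <- length(times)
  if (is.null(vol_occ)) vol_occ <- rep(1, n)
  if (is.null(vol_con)) vol_con <- rep(1, n)
  df <- tibble::tibble(
    time_s = times,
    vol_occluded_ml = vol_occ,
    vol_contralateral_ml = vol_con,
    cr_percent = collateral_ratio(vol_occ, vol_con),
    arterial_hu = arterial,
    venous_hu = venous,
    av_ratio = av_ratio(arterial, venous, blood_hu)
  )
  if (is.null(arrival_s))
    arrival_s <- tryCatch(contrast_arrival(arterial, times),
                          error = function(e) min(times))
  as_tic_curves(df, arrival_s = arrival_s, blood_hu = blood_hu)
}

# Interpolate a tic's valid AV-ratio curve (the same linear interpolation
# the alignment search uses), for sampling synthetic mCTA ratios.
tic_av_at <- function(tic, t) {
  ok <- !is.na(tic$av_ratio) & tic$time_s >= attr(tic, "arrival_s")
  stats::approx(tic$time_s[ok], tic$av_ratio[ok], xout = t)$y
}
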