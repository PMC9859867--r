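# Independent oracles used by the property and acceptance tests.

# A random (but seeded by the caller) bolus protocol evaluated through the
# analytic truth curves at CTP frame times.
random_truth_tic <- function() {
  cfg <- phantom_config(
    aif_t0_s = runif(1, 6, 10),
    aif_alpha = runif(1, 2.5, 3.5),
    aif_beta = runif(1, 1.2, 1.8),
    aif_amplitude_hu = runif(1, 200, 300),
    venous_delay_s = runif(1, 5, 7),
    noise_sd_hu = 0)
  tc <- phantom_truth_curves(cfg, seq(0, cfg$duration_s, cfg$frame_interval_s))
  as_tic_curves(tc)
}

# Interval-based labeler built directly from the phase definition: boundary
# times are solved on the piecewise-linear normalized curve (upslope crossing
# of 0.2, the peak, the downslope crossing of 0.5, the equilibrium zero, the
# minimum), and a time is labelled by the interval it falls in. This is an
# independent route from classify_phase(), which evaluates thresholds
# pointwise.
phase_interval_oracle <- function(nc, tt) {
  ok <- !is.na(nc$normalized) & nc$time_s >= (attr(nc, "arrival_s") %||% -Inf)
  ts <- nc$time_s[ok]; vs <- nc$normalized[ok]
  val <- function(t) stats::approx(ts, vs, xout = t)$y
  t_peak <- attr(nc, "t_peak_s")
  t_equi <- attr(nc, "t_equi_s")
  t_min <- attr(nc, "t_min_s")
  cross_before_peak <- function(level) {
    if (vs[1] >= level) return(ts[1])
    for (i in seq_len(sum(ts < t_peak))) {
      if (vs[i] < level && vs[i + 1] >= level)
        return(ts[i] + (level - vs[i]) / (vs[i + 1] - vs[i]) * (ts[i + 1] - ts[i]))
    }
    Inf
  }
  cross_after_peak <- function(level) {
    idx <- which(ts >= t_peak)
    for (i in idx[-length(idx)]) {
      if (vs[i] > level && vs[i + 1] <= level)
        return(ts[i] + (vs[i] - level) / (vs[i] - vs[i + 1]) * (ts[i + 1] - ts[i]))
    }
    Inf
  }
  t02 <- cross_before_peak(0.2)
  t05 <- cross_after_peak(0.5)
  boundaries <- c(t02, t_peak, t05, t_equi, t_min)
  labels <- vapply(tt, function(t) {
    if (t < t02) "PRE"
    else if (t < t_peak) "EA"
    else if (t < t05) "PA"
    else if (t < t_equi) "EQ"
    else if (t <= t_min) "PV"
    else "LV"
  }, character(1))
  list(labels = labels, boundaries = boundaries)
}
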