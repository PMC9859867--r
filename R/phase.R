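#' Equilibrium point of the AV enhancement-ratio curve
#'
#' The equilibrium point is the time after the AV-ratio peak at which
#' arterial and venous enhancement are equal, i.e. the first downward
#' crossing of the raw AV ratio through 1, located by linear interpolation
#' between the bracketing frames. A sample lying exactly on 1 after the peak
#' is returned as-is.
#'
#' Pre-contrast noise can push the venous density just above the blood
#' baseline and produce spurious ratio spikes, so AV-ratio analysis is
#' restricted to times at or after contrast arrival whenever the curves
#' carry an arrival time.
#'
#' @param curves A `"tic_curves"` object from [extract_tics()] (or any data
#'   frame with `time_s` and `av_ratio` columns).
#' @return Equilibrium time in seconds.
#' @export
find_equilibrium <- function(curves) {
  ok <- av_valid_idx(curves)
  t <- curves$time_s[ok]
  r <- curves$av_ratio[ok]
  if (length(r) < 2L || !any(r > 1))
    abort("AV ratio never exceeds 1; no equilibrium point.",
          class = "collateraltime_equilibrium_error")
  pk <- which.max(r)
  for (i in seq_len(length(r) - 1L)) {
    if (i < pk) next
    if (r[i] == 1) return(t[i])
    if (r[i] > 1 && r[i + 1L] < 1)
      return(t[i] + (r[i] - 1) / (r[i] - r[i + 1L]) * (t[i + 1L] - t[i]))
  }
  if (r[length(r)] == 1) return(t[length(r)])
  abort("AV ratio never falls back through 1; no equilibrium point.",
        class = "collateraltime_equilibrium_error")
}

#' Normalize the AV enhancement-ratio curve
#'
#' Per-subject normalization of the AV-ratio curve: the equilibrium point
#' (raw ratio = 1) is offset to 0 and the result is divided by its maximum,
#' \deqn{\tilde r(t) = \frac{r(t) - 1}{r(t_{peak}) - 1},}
#' so every subject's curve peaks at exactly 1 and crosses 0 at equilibrium.
#' Landmarks recorded: `t_peak_s` (AV-ratio maximum, earliest frame on
#' ties), `t_equi_s` (interpolated equilibrium), and `t_min_s` (the
#' post-equilibrium minimum; if acquisition ends while the curve is still
#' falling this is the last valid sample time).
#'
#' @param curves A `"tic_curves"` object.
#' @return A tibble of class `"av_curve"` with columns `time_s`,
#'   `normalized` (NA where the raw ratio is invalid), and attributes
#'   `t_peak_s`, `t_equi_s`, `t_min_s`, `valid_range`, `arrival_s`.
#' @export
normalize_av_curve <- function(curves) {
  t_equi <- find_equilibrium(curves)
  ok <- av_valid_idx(curves)
  t <- curves$time_s[ok]; r <- curves$av_ratio[ok]
  pk <- which.max(r)
  if (r[pk] <= 1)
    abort("flat AV-ratio curve: maximum does not exceed 1, normalization is degenerate.",
          class = "collateraltime_degenerate_curve_error")
  normalized <- (curves$av_ratio - 1) / (r[pk] - 1)
  nv <- normalized[ok]
  post <- which(t >= t_equi)
  t_min <- if (length(post)) t[post[which.min(nv[post])]] else t[length(t)]
  structure(tibble(time_s = curves$time_s, normalized = normalized),
            t_peak_s = t[pk], t_equi_s = t_equi, t_min_s = t_min,
            valid_range = range(t), arrival_s = attr(curves, "arrival_s"),
            class = c("av_curve", class(tibble())))
}

#' Classify a time point into a contrast acquisition phase
#'
#' Phases are defined on the subject's normalized AV enhancement-ratio
#' curve: early arterial (EA) is the upslope from 0.2 to 1.0, peak arterial
#' (PA) the downslope from 1.0 to 0.5, equilibrium (EQ) the downslope from
#' 0.5 to 0 (ending at the equilibrium time), early venous (PV) from 0 to
#' the curve minimum, and late venous (LV) from the minimum back towards 0.
#' Times before the 0.2 upslope threshold (or before contrast arrival) are
#' labelled PRE. Upslope versus downslope is operationalized as before/after
#' the curve peak; boundary values belong to the later phase, and times at
#' or beyond the equilibrium point stay venous even if measurement noise
#' pushes the ratio fractionally back above 1.
#'
#' @param curve An `"av_curve"` from [normalize_av_curve()].
#' @param t Time(s) in seconds, within the curve's valid range.
#' @return Character vector of phase labels
#'   (`"PRE"`, `"EA"`, `"PA"`, `"EQ"`, `"PV"`, `"LV"`).
#' @export
classify_phase <- function(curve, t) {
  stopifnot(inherits(curve, "av_curve"))
  vr <- attr(curve, "valid_range")
  if (any(t < vr[1] | t > vr[2]))
    abort("time outside the valid range of the normalized curve.",
          class = "collateraltime_range_error")
  ok <- !is.na(curve$normalized)
  v <- approx(curve$time_s[ok], curve$normalized[ok], xout = t)$y
  t_peak <- attr(curve, "t_peak_s")
  t_equi <- attr(curve, "t_equi_s")
  t_min <- attr(curve, "t_min_s")
  arrival <- attr(curve, "arrival_s") %||% -Inf
  out <- character(length(t))
  for (i in seq_along(t)) {
    out[i] <- if (t[i] < arrival) "PRE"
    else if (t[i] < t_peak) {
      if (v[i] < 0.2) "PRE" else "EA"
    } else if (t[i] < t_equi) {
      if (v[i] > 0.5) "PA" else "EQ"
    } else if (t[i] <= t_min) "PV"
    else "LV"
  }
  out
}

# valid AV-ratio samples: defined ratio, at or after contrast arrival
av_valid_idx <- function(curves) {
  arrival <- attr(curves, "arrival_s") %||% -Inf
  !is.na(curves$av_ratio) & curves$time_s >= arrival
}

#' @export
print.av_curve <- function(x, ...) {
  cat(sprintf("<av_curve> peak %.2fs, equilibrium %.2fs, minimum %.2fs (valid %.0f-%.0f s)\n",
              attr(x, "t_peak_s"), attr(x, "t_equi_s"), attr(x, "t_min_s"),
              attr(x, "valid_range")[1], attr(x, "valid_range")[2]))
  NextMethod()
}
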