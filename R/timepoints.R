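#' Locate the six predefined CTP landmark time points
#'
#' Landmarks at which a collateral ratio is read off: the peak of enhanced
#' vessel volume on the non-occluded side (`vol_max`) and the occluded side
#' (`vol_occluded_max`), the arterial peak (`arterial_max`), the venous peak
#' (`venous_max`), the AV-ratio peak (`av_max`), and the equilibrium point
#' (`equi`, arterial = venous enhancement). Peaks are frame-level argmax
#' times (earliest frame on ties); the equilibrium point is interpolated
#' between frames. Times are reported both absolute and relative to contrast
#' arrival.
#'
#' An optional centered moving average (`ext$smoothing_window`) is applied
#' to the curves for peak finding only; stored curves are never smoothed.
#'
#' @param curves A `"tic_curves"` object.
#' @param ext An [extraction_params()].
#' @return A tibble with columns `landmark`, `time_s`,
#'   `time_since_arrival_s`. A landmark whose curve is all-missing gets `NA`.
#' @export
find_timepoints <- function(curves, ext = extraction_params()) {
  if (nrow(curves) == 0L)
    abort("empty curves.", class = "collateraltime_parameter_error")
  k <- ext$smoothing_window
  arg_peak <- function(x) {
    x <- roll_mean(x, k)
    if (all(is.na(x))) return(NA_real_)
    curves$time_s[which.max(replace(x, is.na(x), -Inf))]
  }
  t_equi <- tryCatch(find_equilibrium(curves), error = function(e) NA_real_)
  av <- replace(curves$av_ratio, !av_valid_idx(curves), NA_real_)
  out <- tibble(
    landmark = c("vol_max", "vol_occluded_max", "arterial_max", "venous_max",
                 "av_max", "equi"),
    time_s = c(arg_peak(curves$vol_contralateral_ml),
               arg_peak(curves$vol_occluded_ml),
               arg_peak(curves$arterial_hu),
               arg_peak(curves$venous_hu),
               arg_peak(av),
               t_equi)
  )
  out$time_since_arrival_s <- out$time_s - attr(curves, "arrival_s")
  out
}

# centered moving average with truncated edge windows, NA-aware
roll_mean <- function(x, k) {
  if (k <= 1L) return(x)
  h <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Assemble the per-subject collateral-ratio profile
#'
#' Reads the CR at each CTP landmark (from the nearest acquired frame — the
#' CR is a ratio of segmented volumes and only exists at frames), and joins
#' the time-invariant MIP CR and the three temporally aligned mCTA CRs with
#' their phases. Missing landmarks yield missing CRs, never fabricated
#' values.
#'
#' @param curves A `"tic_curves"` object.
#' @param landmarks Landmark table from [find_timepoints()]; computed from
#'   `curves` when `NULL`.
#' @param cr_mip_value Timing-invariant CR from [cr_mip()] (optional).
#' @param alignment An `"mcta_alignment"` (optional).
#' @param mcta_crs Three mCTA collateral ratios (optional).
#' @param ext An [extraction_params()].
#' @return A one-row tibble: the six landmark CRs (`cr_vol_max`,
#'   `cr_vol_occluded_max`, `cr_arterial_max`, `cr_venous_max`, `cr_equi`,
#'   `cr_av_max`) with their times since arrival (`t_*`), `cr_mip`,
#'   `cr_mcta_baseline`/`_delay1`/`_delay2` with aligned times and phases.
#' @export
extract_cr_profile <- function(curves, landmarks = NULL, cr_mip_value = NA_real_,
                               alignment = NULL, mcta_crs = NULL,
                               ext = extraction_params()) {
  if (is.null(landmarks)) landmarks <- find_timepoints(curves, ext)
  cr_at <- function(t) {
    if (is.na(t)) return(NA_real_)
    curves$cr_percent[which.min(abs(curves$time_s - t))]
  }
  prof <- as.list(setNames(
    vapply(landmarks$time_s, cr_at, numeric(1)),
    paste0("cr_", landmarks$landmark)))
  prof <- c(prof, as.list(setNames(landmarks$time_since_arrival_s,
                                   paste0("t_", landmarks$landmark))))
  prof$cr_mip <- cr_mip_value
  mc <- if (is.null(mcta_crs)) rep(NA_real_, 3L) else mcta_crs
  prof$cr_mcta_baseline <- mc[1]
  prof$cr_mcta_delay1 <- mc[2]
  prof$cr_mcta_delay2 <- mc[3]
  if (!is.null(alignment)) {
    prof$t_mcta_baseline <- alignment$aligned_times_s[1] - attr(curves, "arrival_s")
    prof$t_mcta_delay1 <- alignment$aligned_times_s[2] - attr(curves, "arrival_s")
    prof$t_mcta_delay2 <- alignment$aligned_times_s[3] - attr(curves, "arrival_s")
    prof$phase_mcta_baseline <- alignment$phases[1]
    prof$phase_mcta_delay1 <- alignment$phases[2]
    prof$phase_mcta_delay2 <- alignment$phases[3]
  }
  as_tibble(prof)
}

#' The ten collateral-ratio variable names
#'
#' Column order of the cohort table: six CTP landmark CRs, the
#' timing-invariant MIP CR, and the three mCTA CRs.
#' @return Character vector of length 10.
#' @export
cr_variables <- function() {
  c("cr_vol_max", "cr_vol_occluded_max", "cr_arterial_max", "cr_venous_max",
    "cr_equi", "cr_av_max", "cr_mip",
    "cr_mcta_baseline", "cr_mcta_delay1", "cr_mcta_delay2")
}
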