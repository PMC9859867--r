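#' Temporally align mCTA acquisitions to the CTP time axis
#'
#' The three mCTA volumes are placed on the CTP time axis using the known
#' inter-acquisition delays and a single unknown offset, chosen to minimize
#' the summed absolute difference between the three mCTA AV enhancement
#' ratios and the CTP AV-ratio curve at the corresponding times. The search
#' is exhaustive on a grid (default 0.1 s) over the CTP curve's valid range,
#' with the curve linearly interpolated between frames; ties go to the
#' earliest offset. Each aligned volume is also assigned a contrast
#' acquisition phase via [classify_phase()].
#'
#' @param mcta_ratios Three AV enhancement ratios, one per mCTA volume.
#' @param delays_s Two inter-acquisition delays in seconds.
#' @param ctp_curves A `"tic_curves"` object for the same subject.
#' @param grid_step_s Offset-grid resolution in seconds.
#' @param offset_s Optional manual override: skips the search and evaluates
#'   the objective at this offset only (the explicit fallback for subjects
#'   whose automatic alignment fails).
#' @param use_normalized Match on the normalized AV-ratio curve instead of
#'   raw ratios (sensitivity analysis; the primary definition uses raw
#'   ratios and is the default).
#' @return A list of class `"mcta_alignment"`: `offset_s`,
#'   `aligned_times_s` (three values), `residual` (objective at the
#'   optimum), `per_volume_ratio_diff` (three absolute differences),
#'   `phases` (three phase labels, NA if the phase model is degenerate).
#' @export
align_mcta <- function(mcta_ratios, delays_s, ctp_curves, grid_step_s = 0.1,
                       offset_s = NULL, use_normalized = FALSE) {
  if (length(mcta_ratios) != 3L || any(is.na(mcta_ratios)))
    abort("`mcta_ratios` must be three valid AV ratios.",
          class = "collateraltime_parameter_error")
  if (length(delays_s) != 2L || any(delays_s < 0))
    abort("`delays_s` must be two non-negative gaps.",
          class = "collateraltime_parameter_error")
  ok <- av_valid_idx(ctp_curves)
  if (sum(ok) < 2L)
    abort("CTP AV-ratio curve has fewer than 2 valid samples.",
          class = "collateraltime_alignment_error")
  tt <- ctp_curves$time_s[ok]
  rr <- ctp_curves$av_ratio[ok]
  target <- mcta_ratios
  if (use_normalized) {
    nc <- normalize_av_curve(ctp_curves)
    scale <- (max(rr) - 1)
    rr <- (rr - 1) / scale
    target <- (mcta_ratios - 1) / scale
  }
  cum <- cumsum(c(0, delays_s))
  objective <- function(off) {
    ri <- approx(tt, rr, xout = off + cum)$y
    sum(abs(target - ri))
  }
  if (is.null(offset_s)) {
    hi <- max(tt) - cum[3]
    if (hi < min(tt))
      abort("no feasible offset places all three mCTA volumes inside the valid CTP range.",
            class = "collateraltime_alignment_error")
    cand <- seq(min(tt), hi, by = grid_step_s)
    if (diff(range(rr)) < 1e-9)
      warn("CTP AV-ratio curve is flat; alignment is degenerate, returning the earliest offset.",
           class = "collateraltime_degenerate_alignment_warning")
    obj <- vapply(cand, objective, numeric(1))
    best <- cand[which.min(obj)]
    res <- min(obj)
  } else {
    if (offset_s + cum[3] > max(tt) || offset_s < min(tt))
      abort("manual offset places an mCTA volume outside the valid CTP range.",
            class = "collateraltime_alignment_error")
    best <- offset_s
    res <- objective(offset_s)
  }
  aligned <- best + cum
  ctp_at <- approx(tt, rr, xout = aligned)$y
  phases <- tryCatch(
    classify_phase(normalize_av_curve(ctp_curves), aligned),
    error = function(e) rep(NA_character_, 3L))
  structure(list(offset_s = best, aligned_times_s = aligned, residual = res,
                 per_volume_ratio_diff = abs(target - ctp_at),
                 phases = phases),
            class = "mcta_alignment")
}

#' @export
print.mcta_alignment <- function(x, ...) {
  cat(sprintf("<mcta_alignment> offset %.1fs, times %s, residual %.4f, phases %s\n",
              x$offset_s, paste(sprintf("%.1f", x$aligned_times_s), collapse = "/"),
              x$residual, paste(x$phases, collapse = "/")))
  invisible(x)
}

#' @export
tidy.mcta_alignment <- function(x, ...) {
  tibble(position = c("baseline", "delay1", "delay2"),
         aligned_time_s = x$aligned_times_s,
         ratio_diff = x$per_volume_ratio_diff,
         phase = x$phases)
}

#' @export
glance.mcta_alignment <- function(x, ...) {
  tibble(offset_s = x$offset_s, residual = x$residual)
}

phase_levels <- c("PRE", "EA", "PA", "EQ", "PV", "LV")

#' Phase distribution of aligned mCTA acquisitions across a cohort
#'
#' Contingency counts of contrast acquisition phase by mCTA position
#' (baseline / delay 1 / delay 2), the layout used to report in which phase
#' each acquisition was made.
#'
#' @param alignments A list of `"mcta_alignment"` objects, or a data frame
#'   with `position` and `phase` columns.
#' @return A tibble with one row per mCTA position and one count column per
#'   phase; counts in each row sum to the number of subjects with a
#'   classified phase at that position.
#' @export
summarize_phase_distribution <- function(alignments) {
  df <- if (is.data.frame(alignments)) as_tibble(alignments)
        else dplyr::bind_rows(lapply(alignments, tidy))
  if (nrow(df) == 0L)
    abort("need at least one alignment.", class = "collateraltime_parameter_error")
  df$phase <- factor(df$phase, levels = phase_levels)
  df$position <- factor(df$position, levels = c("baseline", "delay1", "delay2"))
  out <- as.data.frame(table(position = df$position, phase = df$phase))
  tidyr::pivot_wider(as_tibble(out), names_from = "phase",
                     values_from = "Freq")
}
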