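#' Curve-extraction parameters
#'
#' @param blood_hu Average density of unclotted blood (HU), subtracted from
#'   arterial and venous densities before the AV enhancement ratio is formed.
#' @param arrival_delta_hu Arterial rise above the pre-contrast baseline that
#'   defines contrast arrival (HU).
#' @param smoothing_window Odd number of frames for the moving average used
#'   when locating curve landmarks; 1 disables smoothing. Stored curves are
#'   never smoothed — smoothing only affects landmark finding.
#' @param roi_radius_mm Radius of the spherical ROI used for arterial/venous
#'   enhancement when a [region_spec()] does not state one.
#' @return A list of class `"extraction_params"`.
#' @export
extraction_params <- function(blood_hu = 40, arrival_delta_hu = 10,
                              smoothing_window = 1, roi_radius_mm = 3) {
  if (arrival_delta_hu <= 0)
    abort("`arrival_delta_hu` must be positive.",
          class = "collateraltime_parameter_error")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1)
    abort("`smoothing_window` must be an odd integer >= 1.",
          class = "collateraltime_parameter_error")
  structure(list(blood_hu = blood_hu, arrival_delta_hu = arrival_delta_hu,
                 smoothing_window = as.integer(smoothing_window),
                 roi_radius_mm = roi_radius_mm),
            class = "extraction_params")
}

#' Median enhancement of a spherical ROI
#'
#' Median image intensity over voxels whose centers lie within `radius_mm` of
#' the ROI center voxel's center. The median uses the lower-middle convention
#' for even counts (the `n/2`-th order statistic), which keeps the value an
#' observed intensity and is deterministic for oracle checks.
#'
#' @param volume 3D HU array.
#' @param center 1-based voxel index triplet.
#' @param radius_mm Sphere radius in mm.
#' @param voxel_size_mm Per-axis voxel size in mm.
#' @return Median intensity (HU).
#' @export
roi_enhancement <- function(volume, center, radius_mm, voxel_size_mm) {
  grid <- dim(volume)
  if (any(center < 1) || any(center > grid))
    abort("ROI center lies outside the image grid.",
          class = "collateraltime_geometry_error")
  span <- pmax(floor(radius_mm / voxel_size_mm), 0)
  rng <- lapply(1:3, function(a)
    max(1, center[a] - span[a]):min(grid[a], center[a] + span[a]))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  d2 <- ((g$x - center[1]) * voxel_size_mm[1])^2 +
        ((g$y - center[2]) * voxel_size_mm[2])^2 +
        ((g$z - center[3]) * voxel_size_mm[3])^2
  g <- g[d2 <= radius_mm^2, , drop = FALSE]
  if (nrow(g) == 0L)
    abort("spherical ROI contains no voxel centers.",
          class = "collateraltime_geometry_error")
  vals <- sort(volume[cbind(g$x, g$y, g$z)])
  vals[floor((length(vals) + 1) / 2)]
}

#' Arteriovenous enhancement ratio
#'
#' `(arterial - blood_hu) / (venous - blood_hu)`, the blood-subtracted
#' arterial-to-venous enhancement ratio. The ratio is undefined (`NA`) until
#' venous density exceeds the blood baseline; a negative arterial excess is
#' clamped to 0 so the pre-contrast ratio stays interpretable.
#'
#' @param arterial,venous Densities in HU; vectorized.
#' @param blood_hu Blood baseline (HU), default 40.
#' @return Ratio (dimensionless), `NA` where `venous <= blood_hu`.
#' @examples
#' av_ratio(140, 90)  # 2
#' @export
av_ratio <- function(arterial, venous, blood_hu = 40) {
  ifelse(venous > blood_hu, pmax(arterial - blood_hu, 0) / (venous - blood_hu),
         NA_real_)
}

#' Contrast arrival time from the arterial curve
#'
#' Arrival is the time at which arterial density first exceeds its
#' pre-contrast baseline (mean of the first two frames) by
#' `arrival_delta_hu`, linearly interpolated to the crossing between that
#' frame and its predecessor.
#'
#' @param arterial_hu Per-frame arterial densities.
#' @param times_s Per-frame acquisition times (seconds).
#' @param params An [extraction_params()].
#' @return Arrival time in seconds.
#' @export
contrast_arrival <- function(arterial_hu, times_s, params = extraction_params()) {
  if (length(arterial_hu) < 3L)
    abort("need at least 3 frames to detect contrast arrival.",
          class = "collateraltime_parameter_error")
  baseline <- mean(arterial_hu[1:2])
  threshold <- baseline + params$arrival_delta_hu
  idx <- which(arterial_hu >= threshold)[1]
  if (is.na(idx))
    abort("the arterial curve never exceeds baseline + arrival_delta_hu.",
          class = "collateraltime_arrival_error")
  if (idx == 1L) return(times_s[1])
  a0 <- arterial_hu[idx - 1L]; a1 <- arterial_hu[idx]
  t0 <- times_s[idx - 1L]; t1 <- times_s[idx]
  if (a1 == a0) return(t1)
  t0 + (threshold - a0) / (a1 - a0) * (t1 - t0)
}

#' Extract the four CTP time-intensity curves
#'
#' Per frame: enhanced vessel volumes on the occluded and contralateral side
#' (subtraction-threshold segmentation against the unenhanced baseline), the
#' collateral ratio, arterial and venous ROI enhancement (median over a
#' sphere), and the blood-subtracted AV enhancement ratio. Contrast arrival
#' is detected on the arterial curve.
#'
#' @param series A `ctp_series`.
#' @param regions A [region_spec()].
#' @param seg A [segmentation_params()].
#' @param ext An [extraction_params()].
#' @return A tibble of class `"tic_curves"`, one row per frame, with columns
#'   `time_s`, `vol_occluded_ml`, `vol_contralateral_ml`, `cr_percent`,
#'   `arterial_hu`, `venous_hu`, `av_ratio`. Attributes: `arrival_s`,
#'   `blood_hu`, `voxel_size_mm`.
#' @export
extract_tics <- function(series, regions, seg = segmentation_params(),
                         ext = extraction_params()) {
  stopifnot(inherits(series, "ctp_series"), inherits(regions, "region_spec"))
  if (!identical(dim(series$data)[1:3], dim(regions$mca_occluded_mask)))
    abort("series and region masks must share a grid.",
          class = "collateraltime_shape_error")
  nf <- dim(series$data)[4]
  baseline <- frame_baseline(series, seg)
  vs <- series$voxel_size_mm
  r_art <- regions$arterial_roi$radius_mm %||% ext$roi_radius_mm
  r_ven <- regions$venous_roi$radius_mm %||% ext$roi_radius_mm
  rows <- purrr::map(seq_len(nf), function(i) {
    frame <- series$data[, , , i]
    m_occ <- segment_vessels(frame, baseline, seg, regions$mca_occluded_mask)
    m_con <- segment_vessels(frame, baseline, seg, regions$mca_contralateral_mask)
    v_occ <- enhanced_vessel_volume(m_occ, vs)
    v_con <- enhanced_vessel_volume(m_con, vs)
    tibble(
      time_s = series$times_s[i],
      vol_occluded_ml = v_occ,
      vol_contralateral_ml = v_con,
      cr_percent = collateral_ratio(v_occ, v_con, seg),
      arterial_hu = roi_enhancement(frame, regions$arterial_roi$center, r_art, vs),
      venous_hu = roi_enhancement(frame, regions$venous_roi$center, r_ven, vs)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$av_ratio <- av_ratio(out$arterial_hu, out$venous_hu, ext$blood_hu)
  arrival <- contrast_arrival(out$arterial_hu, out$time_s, ext)
  new_tic_curves(out, arrival_s = arrival, blood_hu = ext$blood_hu,
                 voxel_size_mm = vs)
}

#' Assemble a time-intensity curve table from measured values
#'
#' Builds a `"tic_curves"` object from per-frame measurements obtained
#' outside the image pipeline (e.g. the phantom's analytic ground-truth
#' curves, or values exported by other software). Missing volume/CR columns
#' are filled with `NA`; the AV ratio and contrast arrival are computed when
#' absent.
#'
#' @param data Data frame with `time_s`, `arterial_hu`, `venous_hu`, and
#'   optionally `vol_occluded_ml`, `vol_contralateral_ml`, `cr_percent`,
#'   `av_ratio`.
#' @param arrival_s Contrast arrival time; detected with
#'   [contrast_arrival()] when `NULL`.
#' @param blood_hu Blood baseline used for the AV ratio.
#' @param ext An [extraction_params()] for arrival detection.
#' @return A `"tic_curves"` tibble.
#' @export
as_tic_curves <- function(data, arrival_s = NULL, blood_hu = 40,
                          ext = extraction_params(blood_hu = blood_hu)) {
  df <- as_tibble(data)
  for (col in c("vol_occluded_ml", "vol_contralateral_ml", "cr_percent"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$av_ratio))
    df$av_ratio <- av_ratio(df$arterial_hu, df$venous_hu, blood_hu)
  if (is.null(arrival_s))
    arrival_s <- contrast_arrival(df$arterial_hu, df$time_s, ext)
  new_tic_curves(df[, c("time_s", "vol_occluded_ml", "vol_contralateral_ml",
                        "cr_percent", "arterial_hu", "venous_hu", "av_ratio")],
                 arrival_s = arrival_s, blood_hu = blood_hu)
}

new_tic_curves <- function(df, arrival_s, blood_hu, voxel_size_mm = NULL) {
  structure(as_tibble(df),
            arrival_s = arrival_s, blood_hu = blood_hu,
            voxel_size_mm = voxel_size_mm,
            class = c("tic_curves", class(as_tibble(df))))
}

#' @rdname extract_tics
#' @param x A `"tic_curves"` object.
#' @export
arrival_time <- function(x) attr(x, "arrival_s")

#' Time-invariant (timing-invariant) CTA by maximum intensity projection
#'
#' Voxelwise maximum across all CTP frames, collapsing the 4D series into a
#' single 3D angiography-like volume that captures every vessel regardless of
#' its filling time.
#'
#' @param series A `ctp_series` with at least 2 frames.
#' @return 3D HU array.
#' @export
time_invariant_mip <- function(series) {
  stopifnot(inherits(series, "ctp_series"))
  nf <- dim(series$data)[4]
  if (nf < 2L)
    abort("MIP needs at least 2 frames.", class = "collateraltime_parameter_error")
  mip <- series$data[, , , 1]
  for (i in 2:nf) mip <- pmax(mip, series$data[, , , i])
  mip
}

#' Collateral ratio of the time-invariant MIP image
#'
#' Segments the MIP volume against the series baseline and computes the CR,
#' giving a single timing-invariant collateral score.
#'
#' @inheritParams extract_tics
#' @return CR in percent (`NA` if the contralateral MIP volume is empty).
#' @export
cr_mip <- function(series, regions, seg = segmentation_params()) {
  mip <- time_invariant_mip(series)
  baseline <- frame_baseline(series, seg)
  m_occ <- segment_vessels(mip, baseline, seg, regions$mca_occluded_mask)
  m_con <- segment_vessels(mip, baseline, seg, regions$mca_contralateral_mask)
  collateral_ratio(enhanced_vessel_volume(m_occ, series$voxel_size_mm),
                   enhanced_vessel_volume(m_con, series$voxel_size_mm), seg)
}

frame_baseline <- function(series, seg) {
  idx <- seg$baseline_frames
  idx <- idx[idx <= dim(series$data)[4]]
  if (!length(idx))
    abort("no valid baseline frames.", class = "collateraltime_parameter_error")
  b <- series$data[, , , idx[1]]
  if (length(idx) > 1L) {
    for (i in idx[-1]) b <- b + series$data[, , , i]
    b <- b / length(idx)
  }
  b
}
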