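# Continuous enhancement model and 4D phantom generation.

# Internal kinetic constants of the phantom, relative to the configured AIF:
# a slow recirculation/steady-state component shared by artery and vein, a
# venous first pass with the same peak lag but faster washout, and two vessel
# compartments per hemisphere (arterial-like, venous-like) with per-voxel
# amplitude weight w and onset dispersion tau. See the methods vignette.
phantom_kinetics <- function(config) {
  A <- config$aif_amplitude_hu
  t0 <- config$aif_t0_s
  d <- config$venous_delay_s
  recirc <- function(t) {
    dt <- pmax(t - t0, 0)
    0.2 * A * (1 - exp(-dt / 4)) * exp(-dt / 40)
  }
  list(
    arterial_excess = function(t)
      gamma_variate(t, t0, config$aif_alpha, config$aif_beta, A) + recirc(t),
    venous_excess = function(t)
      gamma_variate(t, t0 + d, config$aif_alpha * 1.5, config$aif_beta / 1.5, A) + recirc(t),
    vessel_excess = function(t, compartment, w, tau, fraction = 1, delay = 0) {
      te <- t - delay
      amp <- 1.4 * A
      base <- if (compartment == "arterial")
        gamma_variate(te, t0 + tau, 2, 2, amp)
      else
        gamma_variate(te, t0 + 0.6 * d + tau, 1.6, 5, amp)
      fraction * w * base
    }
  )
}

# Noise-free 3D volume of the continuous model at time t (seconds).
phantom_volume_at <- function(config, geom, kin, t) {
  n <- config$grid_shape
  vol <- array(0, n)
  vol[geom$brain] <- 30
  ves <- geom$vessels
  occl <- config$occlusion_side
  for (comp in c("arterial", "venous")) {
    for (sd_ in c("left", "right")) {
      sel <- ves$compartment == comp & ves$side == sd_
      if (!any(sel)) next
      v <- ves[sel, ]
      occluded <- sd_ == occl
      ex <- mapply(function(w, tau)
        kin$vessel_excess(t, comp, w, tau,
                          fraction = if (occluded) config$collateral_fraction else 1,
                          delay = if (occluded) config$collateral_delay_s else 0),
        v$w, v$tau)
      vol[cbind(v$x, v$y, v$z)] <- config$baseline_hu + ex
    }
  }
  rs <- geom$roi_struct$arterial
  vol[cbind(rs$x, rs$y, rs$z)] <- config$baseline_hu + kin$arterial_excess(t)
  rs <- geom$roi_struct$venous
  vol[cbind(rs$x, rs$y, rs$z)] <- config$baseline_hu + kin$venous_excess(t)
  vol
}

#' Ground-truth enhancement curves of a phantom configuration
#'
#' Evaluates the continuous (noise-free) arterial and venous ROI enhancement
#' model of the phantom at arbitrary times, together with the blood-subtracted
#' arteriovenous enhancement ratio. Useful as an analytic reference in tests
#' and for sampling mCTA acquisitions without building volumes.
#'
#' @param config A [phantom_config()].
#' @param times Numeric vector of times in seconds.
#' @return A tibble with columns `time_s`, `arterial_hu`, `venous_hu`,
#'   `av_ratio` (NA where venous enhancement has not exceeded the blood
#'   baseline).
#' @export
phantom_truth_curves <- function(config, times) {
  kin <- phantom_kinetics(config)
  a <- config$baseline_hu + kin$arterial_excess(times)
  v <- config$baseline_hu + kin$venous_excess(times)
  tibble(time_s = times, arterial_hu = a, venous_hu = v,
         av_ratio = av_ratio(a, v, config$baseline_hu))
}

#' Generate a 4D CTP phantom
#'
#' Builds a seeded synthetic CT perfusion series: mirrored tubular vessel
#' trees inside a brain ellipsoid, contralateral vessels following the
#' arterial bolus kinetics, occluded-side vessels scaled by
#' `collateral_fraction` and shifted by `collateral_delay_s`, arterial and
#' venous ROI structures, constant background tissue, and additive Gaussian
#' noise under the configured seed. Identical configurations (including the
#' seed) give bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return A list of class `"ctp_phantom"` with elements
#'   \describe{
#'     \item{series}{`ctp_series`: 4D array (`x, y, z, frame`), frame times,
#'       voxel size.}
#'     \item{regions}{[region_spec()]: MCA masks of both sides plus the
#'       arterial/venous spherical ROI definitions.}
#'     \item{truth}{ground-truth record: occlusion side, collateral fraction,
#'       configured contrast arrival, and (after [sample_mcta()]) the true
#'       mCTA timing.}
#'     \item{config}{the configuration, for downstream continuous-model
#'       evaluation.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(grid_shape = c(32, 32, 16),
#'                                       noise_sd_hu = 0))
#' dim(ph$series$data)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  geom <- phantom_geometry(config)
  kin <- phantom_kinetics(config)
  times <- phantom_frame_times(config)
  n <- config$grid_shape
  data <- array(0, c(n, length(times)))
  for (i in seq_along(times))
    data[, , , i] <- phantom_volume_at(config, geom, kin, times[i])
  if (config$noise_sd_hu > 0) {
    noise <- with_local_seed(config$seed,
                             rnorm(length(data), 0, config$noise_sd_hu))
    data <- data + array(noise, dim(data))
  }
  series <- new_ctp_series(data, times, config$voxel_size_mm)
  occl <- config$occlusion_side
  contra <- if (occl == "left") "right" else "left"
  regions <- region_spec(
    mca_occluded_mask = geom$mca[[occl]],
    mca_contralateral_mask = geom$mca[[contra]],
    arterial_roi = geom$roi$arterial,
    venous_roi = geom$roi$venous,
    occlusion_side = occl
  )
  truth <- list(
    occlusion_side = occl,
    collateral_fraction = config$collateral_fraction,
    true_arrival_s = config$aif_t0_s,
    true_mcta_offset_s = NA_real_,
    mcta_delays_s = NULL,
    covariates = NULL
  )
  structure(list(series = series, regions = regions, truth = truth,
                 config = config),
            class = "ctp_phantom")
}

#' @export
print.ctp_phantom <- function(x, ...) {
  cat("<ctp_phantom>\n")
  print(x$config)
  invisible(x)
}

#' CTP series container
#'
#' A minimal container for a dynamic CT series: a 4D array (`x, y, z, frame`)
#' in HU, strictly increasing per-frame acquisition times in seconds from the
#' first frame, and per-axis voxel size in mm.
#'
#' @param data 4D numeric array.
#' @param times_s Numeric vector, one acquisition time per frame.
#' @param voxel_size_mm Numeric vector of 3.
#' @return An object of class `"ctp_series"`.
#' @export
new_ctp_series <- function(data, times_s, voxel_size_mm) {
  if (length(dim(data)) != 4L)
    abort("`data` must be a 4D array.", class = "collateraltime_format_error")
  if (dim(data)[4] != length(times_s))
    abort("frame count does not match the number of acquisition times.",
          class = "collateraltime_format_error")
  if (any(diff(times_s) <= 0))
    abort("acquisition times must be strictly increasing.",
          class = "collateraltime_format_error")
  structure(list(data = data, times_s = as.numeric(times_s),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "ctp_series")
}

#' @export
print.ctp_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ctp_series> %dx%dx%d voxels, %d frames (%.0f-%.0f s), voxel %s mm\n",
              d[1], d[2], d[3], d[4], min(x$times_s), max(x$times_s),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Region specification for collateral scoring
#'
#' Holds the occluded and contralateral MCA region masks plus the arterial
#' and venous spherical ROI definitions used for enhancement measurement.
#' Masks must be non-empty, disjoint 3D logical arrays on the image grid;
#' ROI centers are 1-based voxel indices.
#'
#' @param mca_occluded_mask,mca_contralateral_mask 3D logical arrays.
#' @param arterial_roi,venous_roi Lists with `center` (integer voxel triplet)
#'   and `radius_mm`.
#' @param occlusion_side `"left"` or `"right"`.
#' @return An object of class `"region_spec"`.
#' @export
region_spec <- function(mca_occluded_mask, mca_contralateral_mask,
                        arterial_roi, venous_roi,
                        occlusion_side = c("left", "right")) {
  occlusion_side <- match.arg(occlusion_side)
  stop_reg <- function(msg) abort(msg, class = "collateraltime_region_error")
  for (m in list(mca_occluded_mask, mca_contralateral_mask))
    if (length(dim(m)) != 3L || !any(m)) stop_reg("MCA masks must be non-empty 3D arrays.")
  if (!identical(dim(mca_occluded_mask), dim(mca_contralateral_mask)))
    stop_reg("MCA masks must share a grid.")
  if (any(mca_occluded_mask & mca_contralateral_mask))
    stop_reg("MCA masks must be disjoint.")
  grid <- dim(mca_occluded_mask)
  for (roi in list(arterial_roi, venous_roi)) {
    if (!all(c("center", "radius_mm") %in% names(roi)))
      stop_reg("ROIs need `center` and `radius_mm`.")
    if (length(roi$center) != 3L || any(roi$center < 1) || any(roi$center > grid))
      stop_reg("ROI center must lie inside the image grid.")
  }
  structure(list(mca_occluded_mask = mca_occluded_mask,
                 mca_contralateral_mask = mca_contralateral_mask,
                 arterial_roi = arterial_roi, venous_roi = venous_roi,
                 occlusion_side = occlusion_side),
            class = "region_spec")
}

#' Sample multiphase CTA volumes from a phantom
#'
#' Evaluates the phantom's continuous, noise-free enhancement model at three
#' mCTA acquisition times: `offset_s`, `offset_s + delays_s[1]`,
#' `offset_s + delays_s[1] + delays_s[2]`. The true offset and delays are
#' recorded in the returned ground truth.
#'
#' @param phantom A `"ctp_phantom"` from [generate_phantom()].
#' @param offset_s Acquisition time of the first (baseline) mCTA volume on
#'   the CTP time axis, seconds.
#' @param delays_s Two inter-acquisition delays in seconds (default 8 s each,
#'   a typical mCTA protocol).
#' @return A list with `volumes` (three 3D arrays), `times_s` (three sample
#'   times) and `truth` (the phantom ground truth updated with
#'   `true_mcta_offset_s` and `mcta_delays_s`).
#' @export
sample_mcta <- function(phantom, offset_s, delays_s = c(8, 8)) {
  stopifnot(inherits(phantom, "ctp_phantom"))
  if (length(delays_s) != 2L || any(delays_s < 0))
    abort("`delays_s` must be two non-negative gaps.",
          class = "collateraltime_parameter_error")
  times <- offset_s + cumsum(c(0, delays_s))
  if (offset_s < 0 || max(times) > phantom$config$duration_s)
    abort("mCTA sampling extends beyond the CTP acquisition window.",
          class = "collateraltime_range_error")
  config <- phantom$config
  geom <- phantom_geometry(config)
  kin <- phantom_kinetics(config)
  volumes <- lapply(times, function(t) phantom_volume_at(config, geom, kin, t))
  truth <- phantom$truth
  truth$true_mcta_offset_s <- offset_s
  truth$mcta_delays_s <- as.numeric(delays_s)
  list(volumes = volumes, times_s = times, truth = truth)
}
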