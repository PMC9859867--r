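#' Phantom configuration
#'
#' Parameters of the synthetic contrast-enhancement phantom: a two-hemisphere
#' brain ellipsoid holding mirrored tubular vessel trees, a gamma-variate
#' arterial bolus with a delayed venous counterpart, and an occlusion-side
#' vessel tree whose filling is attenuated (`collateral_fraction`) and
#' delayed (`collateral_delay_s`) relative to the healthy side.
#'
#' Defaults emulate a stroke CTP protocol: 2 s frame interval over 58 s
#' (30 volumes), bolus arrival at 8 s, arterial peak 4.5 s later, venous
#' enhancement lagging the arterial curve by 6 s, and a blood baseline of
#' 40 HU.
#'
#' @param grid_shape Integer vector of 3, voxels per axis.
#' @param voxel_size_mm Numeric vector of 3, voxel edge lengths in mm.
#' @param frame_interval_s Seconds between CTP frames.
#' @param duration_s Total acquisition length in seconds; frames are placed
#'   at `0, frame_interval_s, ...` up to `duration_s`.
#' @param aif_t0_s Arterial bolus arrival time (seconds).
#' @param aif_alpha,aif_beta Gamma-variate shape/scale of the arterial curve;
#'   the arterial peak sits at `aif_t0_s + aif_alpha * aif_beta`.
#' @param aif_amplitude_hu Peak arterial enhancement above the blood baseline.
#' @param venous_delay_s Arterial-to-venous peak lag in seconds.
#' @param collateral_fraction Relative filling of occluded-side vessels, 0-1.
#' @param collateral_delay_s Extra filling lag on the occluded side (seconds).
#' @param noise_sd_hu SD of additive i.i.d. Gaussian voxel noise (HU).
#' @param baseline_hu Unenhanced blood density (HU).
#' @param occlusion_side `"left"` or `"right"`.
#' @param seed Integer seed; every stochastic draw in the generator is
#'   reproducible under it.
#'
#' @return A validated list of class `"phantom_config"`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 32L),
                           voxel_size_mm = c(3, 3, 3),
                           frame_interval_s = 2,
                           duration_s = 58,
                           aif_t0_s = 8,
                           aif_alpha = 3,
                           aif_beta = 1.5,
                           aif_amplitude_hu = 250,
                           venous_delay_s = 6,
                           collateral_fraction = 0.6,
                           collateral_delay_s = 3,
                           noise_sd_hu = 5,
                           baseline_hu = 40,
                           occlusion_side = c("left", "right"),
                           seed = 1L) {
  occlusion_side <- match.arg(occlusion_side)
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = as.numeric(voxel_size_mm),
    frame_interval_s = frame_interval_s, duration_s = duration_s,
    aif_t0_s = aif_t0_s, aif_alpha = aif_alpha, aif_beta = aif_beta,
    aif_amplitude_hu = aif_amplitude_hu, venous_delay_s = venous_delay_s,
    collateral_fraction = collateral_fraction, collateral_delay_s = collateral_delay_s,
    noise_sd_hu = noise_sd_hu, baseline_hu = baseline_hu,
    occlusion_side = occlusion_side, seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "collateraltime_config_error")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 16L))
    stop_cfg("`grid_shape` must be three integers, each >= 16.")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    stop_cfg("`voxel_size_mm` must be three positive numbers.")
  pos <- c("frame_interval_s", "duration_s", "aif_t0_s", "aif_alpha",
           "aif_beta", "aif_amplitude_hu", "venous_delay_s")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || !is.finite(cfg[[p]]) || cfg[[p]] <= 0)
      stop_cfg(sprintf("`%s` must be a single positive number.", p))
  if (cfg$collateral_delay_s < 0)
    stop_cfg("`collateral_delay_s` must be >= 0.")
  if (cfg$noise_sd_hu < 0)
    stop_cfg("`noise_sd_hu` must be >= 0.")
  if (cfg$collateral_fraction < 0 || cfg$collateral_fraction > 1)
    stop_cfg("`collateral_fraction` must lie in [0, 1].")
  n_frames <- floor(cfg$duration_s / cfg$frame_interval_s) + 1L
  if (n_frames < 20L)
    stop_cfg("`duration_s` / `frame_interval_s` must give at least 20 frames.")
  if (!is.finite(cfg$seed)) stop_cfg("`seed` must be a finite integer.")
  structure(cfg, class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  grid %s voxels @ %s mm, %d frames every %gs over %gs\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              length(phantom_frame_times(x)), x$frame_interval_s, x$duration_s))
  cat(sprintf("  bolus: t0 %gs, peak +%gs, amplitude %g HU, venous lag %gs\n",
              x$aif_t0_s, x$aif_alpha * x$aif_beta, x$aif_amplitude_hu, x$venous_delay_s))
  cat(sprintf("  collaterals: fraction %.2f, delay %gs, occlusion %s; noise sd %g HU; seed %d\n",
              x$collateral_fraction, x$collateral_delay_s, x$occlusion_side,
              x$noise_sd_hu, x$seed))
  invisible(x)
}

phantom_frame_times <- function(config) {
  seq(0, config$duration_s, by = config$frame_interval_s)
}

# Run code under a temporary RNG state so generators never disturb the
# caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
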