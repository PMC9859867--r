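#' Generate a synthetic cohort of CTP phantoms
#'
#' Draws per-subject collateral fractions and clinical-like covariates, and
#' returns one phantom specification per subject. The collateral fraction is
#' uniform on \[0.05, 1\]; covariates follow a linear-plus-noise link chosen
#' so the association stage has recoverable structure:
#' \itemize{
#'   \item ASPECTS-like = `round(4 + 6 * fraction + N(0, 1))`, clipped to 0-10
#'   \item NIHSS-like = `round(25 - 18 * fraction + N(0, 3))`, clipped to 0-42
#' }
#' mCTA timing emulates bolus tracking: the baseline acquisition lands about
#' 8 s after contrast arrival with ~1 s jitter, and the two inter-acquisition
#' delays are about 8 s each.
#'
#' Subjects are returned lazily as configurations plus ground truth; call
#' [generate_phantom()] (or [run_pipeline()]) to materialize the volumes, so
#' that cohorts of realistic size do not need simultaneous storage.
#'
#' @param n Number of subjects (>= 2).
#' @param base_config A [phantom_config()] supplying everything except the
#'   per-subject collateral fraction, occlusion side and seed.
#' @param seed Integer master seed; the whole cohort is reproducible under it.
#' @param covariate_noise_sd Length-2 numeric, SDs of the ASPECTS-like and
#'   NIHSS-like covariate noise. Zero makes covariates a deterministic
#'   monotone function of the collateral fraction.
#' @return A tibble with one row per subject: `subject`, `collateral_fraction`,
#'   `occlusion_side`, `aspects`, `nihss`, `mcta_offset_s`, `mcta_delay1_s`,
#'   `mcta_delay2_s`, `subject_seed`, and a `config` list-column of
#'   per-subject [phantom_config()] objects.
#' @examples
#' cohort <- generate_cohort(5, phantom_config(grid_shape = c(32, 32, 16)),
#'                           seed = 7)
#' cohort$collateral_fraction
#' @export
generate_cohort <- function(n, base_config = phantom_config(), seed = 1L,
                            covariate_noise_sd = c(1, 3)) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    abort("`n` must be a single number >= 2.",
          class = "collateraltime_parameter_error")
  stopifnot(inherits(base_config, "phantom_config"))
  n <- as.integer(n)
  with_local_seed(seed, {
    fraction <- runif(n, 0.05, 1)
    side <- sample(c("left", "right"), n, replace = TRUE)
    aspects <- pmin(pmax(round(4 + 6 * fraction + rnorm(n, 0, covariate_noise_sd[1])), 0), 10)
    nihss <- pmin(pmax(round(25 - 18 * fraction + rnorm(n, 0, covariate_noise_sd[2])), 0), 42)
    offset <- base_config$aif_t0_s + pmax(rnorm(n, 8, 1), 5)
    d1 <- pmin(pmax(rnorm(n, 8, 0.5), 6), 10)
    d2 <- pmin(pmax(rnorm(n, 8, 0.5), 6), 10)
    subject_seed <- sample.int(.Machine$integer.max %/% 2L, n)
    tibble(
      subject = seq_len(n),
      collateral_fraction = fraction,
      occlusion_side = side,
      aspects = as.integer(aspects),
      nihss = as.integer(nihss),
      mcta_offset_s = offset,
      mcta_delay1_s = d1,
      mcta_delay2_s = d2,
      subject_seed = subject_seed,
      config = purrr::pmap(
        list(fraction, side, subject_seed),
        function(f, s, sd_i) {
          cfg <- unclass(base_config)
          cfg$collateral_fraction <- f
          cfg$occlusion_side <- s
          cfg$seed <- sd_i
          validate_phantom_config(cfg)
        })
    )
  })
}
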