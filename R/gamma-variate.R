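#' Gamma-variate bolus enhancement curve
#'
#' The standard gamma-variate model of first-pass contrast enhancement,
#' parameterized so that the curve reaches its maximum `amplitude` exactly at
#' `t0 + alpha * beta`:
#' \deqn{e(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'   \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right), \quad t > t_0}
#' and 0 for `t <= t0`. Enhancement is expressed in Hounsfield units (HU)
#' above the unenhanced blood baseline.
#'
#' @param t Time(s) in seconds; vectorized.
#' @param t0 Bolus arrival time in seconds.
#' @param alpha Shape parameter (> 0), dimensionless.
#' @param beta Scale parameter (> 0), seconds.
#' @param amplitude Peak enhancement in HU above baseline.
#'
#' @return Numeric vector of enhancements (HU), same length as `t`.
#'
#' @examples
#' gamma_variate(8, t0 = 8, alpha = 3, beta = 1.5, amplitude = 250)   # 0
#' gamma_variate(12.5, t0 = 8, alpha = 3, beta = 1.5, amplitude = 250) # 250
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    abort("`alpha` must be a single positive number.", class = "collateraltime_parameter_error")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    abort("`beta` must be a single positive number.", class = "collateraltime_parameter_error")
  dt <- t - t0
  out <- numeric(length(t))
  up <- which(dt > 0)
  if (length(up))
    out[up] <- amplitude * (dt[up] / (alpha * beta))^alpha * exp(alpha - dt[up] / beta)
  out
}
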