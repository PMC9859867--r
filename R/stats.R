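#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged), with a two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom. Pairs
#' with a missing value in either vector are dropped (pairwise deletion).
#'
#' @param x,y Numeric vectors of equal length with at least 3 complete pairs.
#' @return A tibble with `r`, `p`, `n`. `r` is `NA` when either vector is
#'   constant after deletion.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    abort("need at least 3 complete pairs.",
          class = "collateraltime_parameter_error")
  if (sd(x) == 0 || sd(y) == 0)
    return(tibble(r = NA_real_, p = NA_real_, n = n))
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0
       else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  tibble(r = r, p = p, n = n)
}

#' Spearman correlation matrix of the cohort CR variables
#'
#' Pairwise Spearman correlations over the ten CR variables of a cohort
#' table, with pairwise deletion of missing values.
#'
#' @param table Cohort data frame with the [cr_variables()] columns (missing
#'   columns are skipped).
#' @param variables Which columns to correlate.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
cr_correlation_matrix <- function(table, variables = cr_variables()) {
  variables <- intersect(variables, names(table))
  if (nrow(table) < 3L)
    abort("need at least 3 subjects.", class = "collateraltime_parameter_error")
  k <- length(variables)
  m <- diag(1, k)
  dimnames(m) <- list(variables, variables)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- spearman_cor(table[[variables[i]]], table[[variables[j]]])$r
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Standardized simple linear regression
#'
#' Both variables are z-scored (complete cases) and an ordinary
#' least-squares line is fitted; the reported coefficient is the
#' standardized slope with its 95% confidence interval from the t
#' distribution on `n - 2` degrees of freedom. For simple regression the
#' standardized slope equals the Pearson correlation of the two variables.
#'
#' @param x Predictor values (e.g. a CR variable).
#' @param y Response values (e.g. an ASPECTS-like covariate).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"std_regression"`; use [tidy()] for a
#'   one-row tibble (`beta`, `conf_low`, `conf_high`, `p`, `n`).
#' @export
standardized_regression <- function(x, y, conf_level = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L)
    abort("need at least 4 complete pairs.",
          class = "collateraltime_parameter_error")
  if (sd(x) == 0 || sd(y) == 0)
    abort("constant input: regression is degenerate.",
          class = "collateraltime_degenerate_regression_error")
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  fit <- lm(zy ~ zx)
  beta <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  tcrit <- qt(1 - (1 - conf_level) / 2, n - 2)
  p <- summary(fit)$coefficients[2, 4]
  structure(list(beta = beta, conf_low = beta - tcrit * se,
                 conf_high = beta + tcrit * se, p = p, n = n,
                 conf_level = conf_level, fit = fit),
            class = "std_regression")
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("standardized beta = %.3f (%g%% CI %.3f, %.3f), p = %.3g, n = %d\n",
              x$beta, 100 * x$conf_level, x$conf_low, x$conf_high, x$p, x$n))
  invisible(x)
}

#' @export
tidy.std_regression <- function(x, ...) {
  tibble(beta = x$beta, conf_low = x$conf_low, conf_high = x$conf_high,
         p = x$p, n = x$n)
}

#' @export
glance.std_regression <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, n = x$n)
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention (type 7, the R
#' default): the p-th quantile interpolates linearly between the order
#' statistics at positions `1 + p (n - 1)`.
#'
#' @param values Numeric vector (missing values dropped).
#' @return A tibble with `median`, `q1`, `q3`, `n`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L)
    abort("need at least one value.", class = "collateraltime_parameter_error")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Cohort association statistics
#'
#' For each CR variable: Spearman correlation and standardized linear
#' regression against each covariate — the computational structure of a
#' CR-vs-clinical-score association table.
#'
#' @param table Cohort data frame.
#' @param covariates Names of covariate columns (default ASPECTS-like and
#'   NIHSS-like simulated scores).
#' @param variables CR variable columns to test.
#' @return A tibble with one row per CR variable x covariate:
#'   `cr_variable`, `covariate`, `spearman_r`, `spearman_p`, `beta`,
#'   `conf_low`, `conf_high`, `beta_p`, `n`.
#' @export
cohort_associations <- function(table, covariates = c("aspects", "nihss"),
                                variables = cr_variables()) {
  variables <- intersect(variables, names(table))
  covariates <- intersect(covariates, names(table))
  purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(covariates, function(cv) {
      sp <- spearman_cor(table[[v]], table[[cv]])
      reg <- tryCatch(tidy(standardized_regression(table[[v]], table[[cv]])),
                      error = function(e)
                        tibble(beta = NA_real_, conf_low = NA_real_,
                               conf_high = NA_real_, p = NA_real_,
                               n = sp$n))
      tibble(cr_variable = v, covariate = cv,
             spearman_r = sp$r, spearman_p = sp$p,
             beta = reg$beta, conf_low = reg$conf_low,
             conf_high = reg$conf_high, beta_p = reg$p, n = reg$n)
    })
  })
}

#' Median/IQR summary of the cohort CR variables
#'
#' @inheritParams cohort_associations
#' @return A tibble with one row per variable: `variable`, `median`, `q1`,
#'   `q3`, `n`.
#' @export
summarize_cr_table <- function(table, variables = cr_variables()) {
  variables <- intersect(variables, names(table))
  purrr::map_dfr(variables, function(v) {
    vals <- table[[v]]
    if (all(is.na(vals)))
      return(tibble(variable = v, median = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, n = 0L))
    dplyr::bind_cols(tibble(variable = v), median_iqr(vals))
  })
}
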