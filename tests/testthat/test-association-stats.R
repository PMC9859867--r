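test_that("spearman matches the rank-formula oracle on all permutations of n = 5", {
  x <- 1:5
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  expect_equal(nrow(perms), 120)
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    d2 <- sum((rank(x) - rank(y))^2)
    oracle <- 1 - 6 * d2 / (5 * (25 - 1))
    expect_equal(spearman_cor(x, y)$r, oracle, tolerance = 1e-12)
  }
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
})

test_that("spearman handles monotone transforms, reversal, ties and constants", {
  x <- c(0.3, 1.2, 2.5, 4.1, 9)
  expect_equal(spearman_cor(x, exp(x))$r, 1)
  expect_equal(spearman_cor(x, rev(x))$r, -1)
  expect_true(is.na(spearman_cor(x, rep(2, 5))$r))
  expect_error(spearman_cor(c(1, 2), c(3, 4)),
               class = "collateraltime_parameter_error")
  # p-value follows the t approximation
  y <- c(2, 1, 4, 3, 5)
  r <- spearman_cor(1:5, y)$r; n <- 5
  p_oracle <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(spearman_cor(1:5, y)$p, p_oracle, tolerance = 1e-12)
})

test_that("the correlation matrix is symmetric with unit diagonal and pairwise deletion", {
  set.seed(2)
  tab <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(300), 30)),
                                    cr_variables()))
  m <- cr_correlation_matrix(tab)
  expect_equal(dim(m), c(10, 10))
  expect_equal(sum(upper.tri(m)), 45)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 10))
  # duplicated variables correlate perfectly
  tab$cr_mip <- tab$cr_vol_max
  expect_equal(cr_correlation_matrix(tab)["cr_vol_max", "cr_mip"], 1)
  # a subject with all-missing CRs changes nothing
  tab2 <- dplyr::bind_rows(tab, tab[1, ] |>
                             dplyr::mutate(dplyr::across(dplyr::everything(),
                                                         ~NA_real_)))
  expect_equal(cr_correlation_matrix(tab2), cr_correlation_matrix(tab))
})

test_that("standardized beta equals the Pearson correlation with a t-based CI", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    fit <- standardized_regression(x, y)
    expect_equal(fit$beta, cor(x, y), tolerance = 1e-10)
    expect_true(fit$conf_low <= fit$beta && fit$beta <= fit$conf_high)
  }
  fit <- standardized_regression(1:10, 1:10 * 2 + 5)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_error(standardized_regression(rep(1, 10), rnorm(10)),
               class = "collateraltime_degenerate_regression_error")
  td <- tidy(standardized_regression(rnorm(20), rnorm(20)))
  expect_named(td, c("beta", "conf_low", "conf_high", "p", "n"))
})

test_that("median and quartiles follow the linear-interpolation convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5))$median, 3)
  mi <- median_iqr(c(1, 2, 3, 4))
  # type-7 oracle: quantile p interpolates at position 1 + p*(n-1)
  q7 <- function(x, p) {
    x <- sort(x); h <- 1 + p * (length(x) - 1)
    lo <- floor(h); x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(c(mi$q1, mi$median, mi$q3),
               c(q7(1:4, 0.25), q7(1:4, 0.5), q7(1:4, 0.75)))
  cc <- median_iqr(rep(7, 3))
  expect_equal(c(cc$median, cc$q1, cc$q3), c(7, 7, 7))
})

test_that("cohort association table covers every CR-covariate pair", {
  set.seed(4)
  tab <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(300), 30)),
                                    cr_variables()))
  tab$aspects <- rbinom(30, 10, 0.7)
  tab$nihss <- rbinom(30, 30, 0.4)
  assoc <- cohort_associations(tab)
  expect_equal(nrow(assoc), 20)
  expect_true(all(abs(assoc$spearman_r) <= 1, na.rm = TRUE))
  expect_true(all(assoc$conf_low <= assoc$beta & assoc$beta <= assoc$conf_high,
                  na.rm = TRUE))
})
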