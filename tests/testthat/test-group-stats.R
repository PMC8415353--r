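test_that("welch t matches hand computation and summary form", {
  wt <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(wt$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(wt$df, 4)
  x <- rnorm(10)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # summary form agrees with the sample form
  y <- rnorm(12, 1)
  a <- welch_t(x, y)
  b <- welch_t_summary(mean(x), sd(x), 10, mean(y), sd(y), 12)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$df, b$df, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("mann-whitney U counts pairwise wins with midranks", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3, 5), c(2, 4, 6))$U, 3)
  x <- c(1, 2, 2, 5)
  expect_equal(mann_whitney_u(x, x)$U, 8)  # identical multisets: n1*n2/2
  # exhaustive check against brute-force pair counting, 4-value alphabet
  vals <- 0:3
  grid <- expand.grid(a = vals, b = vals, c = vals)
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, ])
    j <- (i * 37) %% nrow(grid) + 1  # deterministic partner sample
    y <- as.numeric(grid[j, ])
    expect_equal(mann_whitney_u(x, y)$U, bf_u_stat(x, y))
  }
  # U1 + U2 = n1*n2 for tie-free data
  set.seed(81)
  for (k in 1:20) {
    x <- sample(1:100, 6); y <- sample(101:200, 8) - 50.5
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 48)
  }
})

test_that("effect sizes follow the pooled-SD and correction formulas", {
  expect_equal(cohens_d(2, 1, 3, 5, 1, 3), -3)
  expect_equal(cohens_d(1, 1, 5, 1, 1, 5), 0)
  expect_equal(hedges_g(1, 10), 1 - 3 / 31)
  expect_equal(hedges_g(0, 20), 0)
  ci <- d_confidence_interval(0, 34, 34)
  expect_equal(unname(ci[1]), -unname(ci[2]))
  ci <- d_confidence_interval(-0.70, 34, 34)
  expect_equal(unname(ci), c(-1.1897, -0.2103), tolerance = 1e-3)
  # widths shrink with n at fixed d
  w <- function(n) diff(d_confidence_interval(-0.7, n, n))
  expect_true(w(20) > w(40) && w(40) > w(80))
  # antisymmetry and |g| < |d|
  set.seed(91)
  for (k in 1:20) {
    x <- rnorm(8); y <- rnorm(9, 0.5)
    d1 <- cohens_d_samples(x, y); d2 <- cohens_d_samples(y, x)
    expect_equal(d1, -d2, tolerance = 1e-12)
    expect_equal(d1, bf_cohens_d(x, y), tolerance = 1e-12)
    if (abs(d1) > 0) expect_lt(abs(hedges_g(d1, 17)), abs(d1))
  }
  expect_error(cohens_d(1, 0, 5, 1, 0, 5), "pooled")
})

test_that("the normality gate routes by Shapiro-Wilk and extreme outliers", {
  set.seed(103)
  x <- rnorm(34); y <- rnorm(34)
  expect_equal(normality_gate(x, y), "welch_t")
  # an extreme outlier (beyond 3 IQR) forces the rank test
  x_out <- c(x[-1], quantile(x, 0.75) + 10 * (IQR(x)))
  expect_equal(normality_gate(x_out, y), "mann_whitney")
  expect_true(any(extreme_outliers(x_out)))
  expect_false(any(extreme_outliers(x)))
  expect_error(normality_gate(c(1, 2), y), "n >= 3")
  # heavy lognormal skew is detected essentially always
  routed <- vapply(1:50, function(i) {
    normality_gate(exp(rnorm(34, 0, 1.5)), rnorm(34))
  }, character(1))
  expect_gt(mean(routed == "mann_whitney"), 0.97)
})

test_that("spearman correlation uses midranks with a t-approximate p", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_true(is.na(spearman_corr(rep(1, 5), rnorm(5))$rho))
  # null p-values roughly uniform
  set.seed(113)
  ps <- vapply(1:200, function(i) spearman_corr(rnorm(68), rnorm(68))$p,
               numeric(1))
  # rank-based p-values are discrete, so tie warnings from ks.test are benign
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the regression layer reports correct dfs and exact fits", {
  set.seed(123)
  demo <- data.frame(
    group = rep(c("SSD", "HV"), each = 34),
    sex = sample(c("female", "male"), 68, replace = TRUE),
    age = runif(68, 15, 35),
    race = sample(c("a", "b", "c", "d"), 68, replace = TRUE)
  )
  r <- ols_regression(rnorm(68), demo)
  expect_equal(r$df1, 6)
  expect_equal(r$df2, 61)
  # exact linear response in age gives R^2 = 1
  r <- suppressWarnings(ols_regression(3 * demo$age - 1, demo,
                                       predictors = "age"))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # residuals orthogonal to every design column
  y <- rnorm(68)
  r <- ols_regression(y, demo)
  X <- stats::model.matrix(r$fit)
  expect_lt(max(abs(crossprod(X, stats::residuals(r$fit)))), 1e-8)
  # collinear design errors with the offending column named
  demo$age2 <- demo$age
  expect_error(ols_regression(y, demo, predictors = c("age", "age2")),
               "collinear")
  # null F p-values approximately uniform
  ps <- vapply(1:200, function(i) ols_regression(rnorm(68), demo)$p,
               numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("comparison table emits one gated row per feature with effect sizes", {
  set.seed(133)
  n <- 20
  feats <- data.frame(
    group = rep(c("SSD", "HV"), each = n),
    mean_S = c(rnorm(n, 78, 13), rnorm(n, 84, 10)),
    colorfulness = c(rnorm(n, 37, 7), rnorm(n, 42, 5)),
    follower_count = round(c(rlnorm(n, 5.8, 0.7), rlnorm(n, 6.1, 1.2))),
    follower_following_ratio = c(rlnorm(n, -0.2, 0.5), rep(NA, 2),
                                 rlnorm(n - 2, 0.1, 0.7))
  )
  tab <- build_comparison_table(feats)
  expect_equal(tab$feature,
               intersect(feature_dictionary()$feature, names(feats)))
  expect_true(all(tab$test_used %in% c("welch_t", "mann_whitney")))
  expect_true(all(is.na(tab$df) | tab$test_used == "welch_t"))
  expect_true(all(!is.na(tab$df[tab$test_used == "welch_t"])))
  expect_equal(tab$hedges_g,
               tab$cohens_d * (1 - 3 / (4 * (tab$n_ssd + tab$n_hv) - 9)),
               tolerance = 1e-12)
  expect_equal(tab$n_hv[tab$feature == "follower_following_ratio"], n - 2)
  # a feature entirely missing in one group is flagged, not fatal
  feats$mean_V <- c(rep(NA_real_, n), rnorm(n, 139, 12))
  tab <- build_comparison_table(feats)
  row <- tab[tab$feature == "mean_V", ]
  expect_match(row$note, "insufficient")
  expect_true(is.na(row$p))
  # identical groups: d = 0, and near-null effects are rarely large
  feats0 <- data.frame(group = rep(c("SSD", "HV"), each = n),
                       mean_S = rep(rnorm(n, 80, 10), 2))
  tab0 <- build_comparison_table(feats0)
  expect_equal(tab0$cohens_d, 0)
})
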