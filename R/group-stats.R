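#' Normality-gated group comparisons and effect sizes
#'
#' Features averaged per participant are compared between the SSD and HV
#' groups. Each feature is routed through a gate: when both group samples
#' pass Shapiro-Wilk at `alpha` and neither contains an extreme outlier
#' (beyond 3 interquartile ranges from the nearest quartile), a Welch t-test
#' is used; otherwise a Mann-Whitney U test. Cohen's d (pooled-SD, SSD - HV
#' sign convention), its normal-approximation 95% CI, and Hedges g accompany
#' every row.
#'
#' @name group-stats
NULL

#' Extreme-outlier indicator
#'
#' A point is an extreme outlier when it lies more than `k` interquartile
#' ranges below the first or above the third quartile (default `k = 3`).
#'
#' @param x numeric sample.
#' @param k IQR multiplier.
#' @return logical vector.
#' @export
extreme_outliers <- function(x, k = 3) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Choose the two-sample test for a feature
#'
#' @param x,y numeric samples (each `n >= 3`).
#' @param alpha Shapiro-Wilk significance level.
#' @return `"welch_t"` or `"mann_whitney"`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("normality gate requires n >= 3 in each sample")
  }
  sw_p <- function(v) {
    if (length(unique(v)) < 2L) return(0)  # degenerate: clearly non-normal
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }
  normal_ok <- sw_p(x) > alpha && sw_p(y) > alpha
  outlier_free <- !any(extreme_outliers(x)) && !any(extreme_outliers(y))
  if (normal_ok && outlier_free) "welch_t" else "mann_whitney"
}

#' Welch t-test
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of freedom,
#' from raw samples or directly from group summaries (mean, SD, n), which is
#' how published group tables are re-checked.
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (var(x) + var(y) <= 0) stop("both samples have zero variance")
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' @rdname welch_t
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summaries (sample SDs).
#' @export
welch_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
  se2 <- vx + vy
  if (se2 <= 0) stop("both samples have zero variance")
  t <- (mean_x - mean_y) / sqrt(se2)
  df <- se2^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' U is reported for the first sample (`U1 = R1 - n1(n1+1)/2` with midranks
#' for ties); by convention the clinical (SSD) group is listed first, so a U
#' far below `n1*n2/2` reflects lower case-group values. The p-value is from
#' exact enumeration when `n1*n2 <= 400` and the data are tie-free,
#' otherwise a tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) * length(y) <= 400 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d from group summaries
#'
#' `d = (mean_x - mean_y) / s_pooled` with the `(n-1)`-weighted pooled SD;
#' for equal group sizes this reduces to `sqrt((s1^2 + s2^2)/2)`. In
#' comparison tables the SSD group is `x`, so negative d means the clinical
#' group is lower.
#'
#' @param mean_x,sd_x,n_x summary of the first (case) group.
#' @param mean_y,sd_y,n_y summary of the second (control) group.
#' @return Cohen's d.
#' @export
cohens_d <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2)
  sp <- sqrt(((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean_x - mean_y) / sp
}

#' @rdname cohens_d
#' @param x,y raw samples (summaries computed with sample SDs).
#' @export
cohens_d_samples <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  cohens_d(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Hedges g small-sample correction
#'
#' `g = d * (1 - 3 / (4N - 9))` with `N` the total sample size.
#'
#' @param d Cohen's d.
#' @param n_total total sample size (>= 4).
#' @return Hedges g.
#' @export
hedges_g <- function(d, n_total) {
  stopifnot(n_total >= 4)
  d * (1 - 3 / (4 * n_total - 9))
}

#' Normal-approximation confidence interval for Cohen's d
#'
#' `d +/- z * SE` with
#' `SE = sqrt((n_x + n_y)/(n_x * n_y) + d^2 / (2 * (n_x + n_y)))`.
#'
#' @param d Cohen's d.
#' @param n_x,n_y group sizes.
#' @param level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
d_confidence_interval <- function(d, n_x, n_y, level = 0.95) {
  se <- sqrt((n_x + n_y) / (n_x * n_y) + d^2 / (2 * (n_x + n_y)))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = d - z * se, upper = d + z * se)
}

#' Spearman rank correlation
#'
#' Midrank-based rho with a two-sided p from the t approximation.
#'
#' @param x,y paired numeric samples (`n >= 3` complete pairs).
#' @return list with `rho` and `p`; `rho` is `NA` for constant input.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Multiple linear regression on group, sex, age and race
#'
#' Secondary analysis used when a feature shows a sex difference: ordinary
#' least squares of the feature on group, sex, age and race dummies, with
#' per-term t and p, the overall F with its degrees of freedom, and R^2.
#' With n = 68 and the default 6-column design the F degrees of freedom are
#' (6, 61).
#'
#' @param response numeric response, one value per participant.
#' @param data data frame with columns `group`, `sex`, `age`, `race`
#'   (categorical columns expanded to treatment-coded dummies).
#' @param predictors model terms.
#' @return list with `coefficients` (data frame: term, estimate, t, p), `F`,
#'   `df1`, `df2`, `p`, `r_squared`.
#' @export
ols_regression <- function(response, data,
                           predictors = c("group", "sex", "age", "race")) {
  df <- data[, predictors, drop = FALSE]
  for (cv in predictors) if (!is.numeric(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  df$.y <- response
  fit <- lm(.y ~ ., data = df)
  qrr <- qr(model.matrix(fit))
  if (qrr$rank < ncol(model.matrix(fit))) {
    aliased <- colnames(model.matrix(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "))
  }
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                      t = co[, 3], p = co[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  fst <- s$fstatistic
  list(coefficients = coefs,
       F = unname(fst[1]), df1 = unname(fst[2]), df2 = unname(fst[3]),
       p = pf(fst[1], fst[2], fst[3], lower.tail = FALSE),
       r_squared = s$r.squared,
       fit = fit)
}

#' Build the feature comparison table
#'
#' One row per feature: group means and SDs, the gated test with its
#' statistic (t with df, or U), two-sided p, Cohen's d (SSD - HV), its 95%
#' CI, and Hedges g. Missing values are dropped per group with a logged
#' count; a feature entirely missing in one group is flagged, not fatal.
#'
#' @param features per-participant feature data frame (one row per
#'   participant) including a group column.
#' @param group_col name of the group column.
#' @param case_level,control_level group labels; the case (clinical) group
#'   carries the first position in the d sign convention and the U statistic.
#' @param feature_cols feature columns to compare; defaults to the package
#'   feature dictionary intersected with `names(features)`.
#' @param alpha gate significance level.
#' @param bh if `TRUE`, append a Benjamini-Hochberg adjusted `q` column
#'   (off by default; the primary report is uncorrected).
#' @return data frame of class `comparison_table`.
#' @export
build_comparison_table <- function(features, group_col = "group",
                                   case_level = "SSD", control_level = "HV",
                                   feature_cols = NULL, alpha = 0.05,
                                   bh = FALSE) {
  dict <- feature_dictionary()
  if (is.null(feature_cols)) {
    feature_cols <- intersect(dict$feature, names(features))
  }
  g <- features[[group_col]]
  stopifnot(sum(g == case_level) >= 2, sum(g == control_level) >= 2)
  rows <- lapply(feature_cols, function(fc) {
    x <- features[[fc]][g == case_level]      # SSD
    y <- features[[fc]][g == control_level]   # HV
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    lab <- dict$label[match(fc, dict$feature)]
    row <- data.frame(
      feature = fc, label = ifelse(is.na(lab), fc, lab),
      n_ssd = length(x), n_hv = length(y),
      mean_hv = NA_real_, sd_hv = NA_real_,
      mean_ssd = NA_real_, sd_ssd = NA_real_,
      test_used = NA_character_, statistic = NA_real_, df = NA_real_,
      p = NA_real_, cohens_d = NA_real_, d_ci_lower = NA_real_,
      d_ci_upper = NA_real_, hedges_g = NA_real_,
      note = "", stringsAsFactors = FALSE
    )
    if (length(x) < 3L || length(y) < 3L) {
      row$note <- "insufficient non-missing data in a group"
      return(row)
    }
    row$mean_hv <- mean(y); row$sd_hv <- sd(y)
    row$mean_ssd <- mean(x); row$sd_ssd <- sd(x)
    if (sd(x) + sd(y) == 0) {
      row$note <- "feature constant in both groups"
      return(row)
    }
    gate <- normality_gate(x, y, alpha = alpha)
    row$test_used <- gate
    if (gate == "welch_t") {
      wt <- welch_t(x, y)
      row$statistic <- wt$t; row$df <- wt$df; row$p <- wt$p
    } else {
      mw <- mann_whitney_u(x, y)
      row$statistic <- mw$U; row$p <- mw$p
    }
    d <- cohens_d_samples(x, y)
    ci <- d_confidence_interval(d, length(x), length(y))
    row$cohens_d <- d
    row$d_ci_lower <- ci[["lower"]]; row$d_ci_upper <- ci[["upper"]]
    row$hedges_g <- hedges_g(d, length(x) + length(y))
    row
  })
  out <- do.call(rbind, rows)
  if (bh) out$q <- p.adjust(out$p, method = "BH")
  class(out) <- c("comparison_table", class(out))
  out
}

#' @importFrom stats p.adjust
#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
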