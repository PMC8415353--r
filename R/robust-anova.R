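#' Robust between-within ANOVA on trimmed means
#'
#' A mixed (split-plot) design with one between-subjects factor (group) and
#' one within-subjects factor (condition: time-of-day bins or weekdays) is
#' tested on 20%-trimmed means with winsorized covariances, using
#' Johansen-type approximate-df Q statistics. Trimming makes the tests
#' resistant to the non-normality and covariance heterogeneity typical of
#' posting-rate data, for which classical mixed ANOVA assumptions fail.
#'
#' For each independent group j with n_j subjects and K repeated conditions,
#' the trimmed mean vector uses h_j = n_j - 2*floor(trim*n_j) retained
#' observations per condition, and the covariance of the trimmed means is
#' estimated as (n_j - 1) * S_wj / (h_j * (h_j - 1)) with S_wj the
#' marginally winsorized sample covariance matrix. Effects are contrasts
#' C theta; the statistic T = (C theta)' (C V C')^{-1} (C theta) is referred
#' to F(q, q(q+2)/(3A)) after division by c = q + 2A - 6A/(q+2), where A is
#' Johansen's weighted trace term over groups and q the number of contrast
#' rows.
#'
#' @name robust-anova
NULL

win_values <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  lo <- xs[g + 1]; hi <- xs[n - g]
  pmin(pmax(x, lo), hi)
}

trimmed_mean <- function(x, trim) mean(x, trim = trim)

johansen_test <- function(cmat, theta, V, h, K) {
  q <- nrow(cmat)
  CV <- cmat %*% V %*% t(cmat)
  invc <- tryCatch(solve(CV), error = function(e) {
    stop("singular contrast covariance; the design needs more subjects per ",
         "group than within-subject conditions after trimming", call. = FALSE)
  })
  ct <- cmat %*% theta
  Tstat <- drop(t(ct) %*% invc %*% ct)
  R <- V %*% t(cmat) %*% invc %*% cmat
  A <- 0
  for (j in seq_along(h)) {
    sel <- (j - 1L) * K + seq_len(K)
    Rjj <- R[sel, sel, drop = FALSE]
    A <- A + (sum(diag(Rjj %*% Rjj)) + sum(diag(Rjj))^2) / (h[j] - 1)
  }
  A <- A / 2
  cc <- q + 2 * A - 6 * A / (q + 2)
  Q <- Tstat / cc
  df2 <- if (A > 0) q * (q + 2) / (3 * A) else Inf
  list(Q = Q, df1 = q, df2 = df2, p = pf(Q, q, df2, lower.tail = FALSE))
}

succ_diff_contrast <- function(m) {
  # (m-1) x m successive-difference rows: (1,-1,0,...), (0,1,-1,...)
  out <- matrix(0, m - 1L, m)
  for (i in seq_len(m - 1L)) { out[i, i] <- 1; out[i, i + 1L] <- -1 }
  out
}

#' Robust mixed factorial ANOVA
#'
#' @param data long-format data frame: one row per participant x condition.
#' @param value,id,group,condition column names of the response (e.g.
#'   posting rate in the bin), participant id, between-subjects group, and
#'   within-subjects condition. Conditions must be complete (balanced) for
#'   every participant; `condition` factor level order fixes the contrast
#'   ordering.
#' @param trim trimming proportion in `[0, 0.5)`; default 0.20.
#' @return data frame of class `robust_anova`: rows `condition`, `group`,
#'   `interaction` with columns `Q`, `df1`, `df2`, `p`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(id = 1:20, condition = c("a", "b", "c"))
#' d$group <- ifelse(d$id <= 10, "SSD", "HV")
#' d$value <- rnorm(nrow(d))
#' robust_mixed_anova(d)
#' @export
robust_mixed_anova <- function(data, value = "value", id = "id",
                               group = "group", condition = "condition",
                               trim = 0.20) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  cond <- factor(data[[condition]])
  grp <- data[[group]]
  ids <- data[[id]]
  K <- nlevels(cond)
  # wide matrix: participants x conditions
  tab <- tapply(data[[value]], list(ids, cond), function(v) v[1])
  if (anyNA(tab)) stop("unbalanced design: every participant needs every condition")
  pid <- rownames(tab)
  pgrp <- grp[match(pid, as.character(ids))]
  glev <- unique(pgrp)
  J <- length(glev)
  stopifnot(J >= 2, K >= 2)

  nj <- integer(J); h <- integer(J)
  theta <- numeric(J * K)
  V <- matrix(0, J * K, J * K)
  for (j in seq_len(J)) {
    Xj <- tab[pgrp == glev[j], , drop = FALSE]
    nj[j] <- nrow(Xj)
    gj <- floor(trim * nj[j])
    h[j] <- nj[j] - 2L * gj
    if (h[j] < 2L) stop("too few subjects in a group after trimming")
    sel <- (j - 1L) * K + seq_len(K)
    theta[sel] <- apply(Xj, 2, trimmed_mean, trim = trim)
    Wj <- apply(Xj, 2, win_values, trim = trim)
    Swj <- stats::cov(Wj)
    V[sel, sel] <- (nj[j] - 1) * Swj / (h[j] * (h[j] - 1))
  }

  cj <- succ_diff_contrast(J); ck <- succ_diff_contrast(K)
  ij <- matrix(1, 1, J); ik <- matrix(1, 1, K)
  effects <- list(
    condition = kronecker(ij, ck),
    group = kronecker(cj, ik),
    interaction = kronecker(cj, ck)
  )
  rows <- lapply(names(effects), function(nm) {
    res <- johansen_test(effects[[nm]], theta, V, h, K)
    data.frame(effect = nm, Q = res$Q, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "trim") <- trim
  attr(out, "n_per_group") <- setNames(nj, glev)
  class(out) <- c("robust_anova", class(out))
  out
}

#' @export
print.robust_anova <- function(x, ...) {
  cat(sprintf("Robust between-within ANOVA (trim = %.2f)\n", attr(x, "trim")))
  y <- as.data.frame(x)
  y$Q <- round(y$Q, 3); y$df2 <- round(y$df2, 2); y$p <- signif(y$p, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
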