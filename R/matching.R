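#' Case-control matching on propensity scores
#'
#' Each case is matched 1:1 without replacement to the control with the
#' nearest logistic-propensity logit, processing cases in descending
#' propensity (hard-to-match cases first), ties broken by input order. This
#' is a deliberately transparent greedy nearest-neighbour matcher: the
#' scientific content of a matched design is the covariate balance it
#' achieves, and the greedy algorithm is fully auditable and testable. It is
#' not a reimplementation of genetic or optimal matching.
#'
#' @name matching
NULL

match_design <- function(df, covariates) {
  out <- list()
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v)) {
      out[[cv]] <- v
    } else {
      v <- factor(v)
      lv <- levels(v)
      if (length(lv) < 2L) {
        out[[cv]] <- rep(0, length(v))
      } else {
        for (l in lv[-1]) out[[paste0(cv, "_", l)]] <- as.numeric(v == l)
      }
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Propensity-score matching
#'
#' @param cases,controls data frames of demographic records (one row per
#'   participant) containing `participant_id` and the matching covariates;
#'   `nrow(controls) >= nrow(cases)`.
#' @param covariates covariate columns; categorical covariates are expanded
#'   to treatment-coded dummies (e.g. 4 race levels give 3 dummies).
#' @param seed integer recorded in the result; the algorithm itself is
#'   deterministic given the inputs.
#' @return list with `pairs` (data frame `case_id`, `control_id`),
#'   `unmatched_controls` (ids), and `balance` (per-covariate standardized
#'   mean difference before and after matching, pooled-SD denominator from
#'   the pre-match samples).
#' @export
propensity_match <- function(cases, controls,
                             covariates = c("age", "sex", "race"),
                             seed = 1L) {
  stopifnot(nrow(controls) >= nrow(cases))
  all_df <- rbind(cases[, c("participant_id", covariates), drop = FALSE],
                  controls[, c("participant_id", covariates), drop = FALSE])
  if (anyNA(all_df[, covariates, drop = FALSE])) {
    stop("matching covariates must be complete (no missing values)")
  }
  X <- match_design(all_df, covariates)
  y <- c(rep(1L, nrow(cases)), rep(0L, nrow(controls)))
  fit_df <- cbind(case = y, X)
  # constant columns or perfect separation are tolerated: the logit is only
  # used as a 1-d distance, so a degenerate fit still yields a usable score
  fit <- suppressWarnings(glm(case ~ ., data = fit_df, family = binomial()))
  logit <- suppressWarnings(predict(fit, type = "link"))
  case_logit <- logit[seq_len(nrow(cases))]
  ctrl_logit <- logit[nrow(cases) + seq_len(nrow(controls))]

  case_order <- order(-case_logit, seq_along(case_logit))
  avail <- rep(TRUE, nrow(controls))
  pairs <- data.frame(case_id = character(nrow(cases)),
                      control_id = character(nrow(cases)),
                      stringsAsFactors = FALSE)
  for (k in seq_along(case_order)) {
    i <- case_order[k]
    dist <- abs(ctrl_logit - case_logit[i])
    dist[!avail] <- Inf
    j <- which.min(dist)  # ties broken by input order
    avail[j] <- FALSE
    pairs$case_id[k] <- cases$participant_id[i]
    pairs$control_id[k] <- controls$participant_id[j]
  }
  pairs <- pairs[order(match(pairs$case_id, cases$participant_id)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL

  Xc <- X[seq_len(nrow(cases)), , drop = FALSE]
  Xk <- X[nrow(cases) + seq_len(nrow(controls)), , drop = FALSE]
  matched_idx <- match(pairs$control_id, controls$participant_id)
  balance <- do.call(rbind, lapply(names(X), function(cv) {
    sdp <- sqrt((var(Xc[[cv]]) + var(Xk[[cv]])) / 2)
    smd <- function(a, b) {
      d <- mean(a) - mean(b)
      if (sdp == 0) return(if (abs(d) < 1e-12) 0 else NA_real_)
      d / sdp
    }
    data.frame(covariate = cv,
               smd_before = smd(Xc[[cv]], Xk[[cv]]),
               smd_after = smd(Xc[[cv]], Xk[[cv]][matched_idx]),
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs,
       unmatched_controls =
         setdiff(controls$participant_id, pairs$control_id),
       balance = balance,
       seed = as.integer(seed))
}
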