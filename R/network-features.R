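#' Social-connection statistics
#'
#' Three metric families per participant: absolute counts of each connection
#' type, counts normalized by usage duration in months, and relative metrics
#' (followers/following and requested/following ratios). The ratio metrics
#' are invariant to overall account scale, which is what makes the
#' follower/following ratio a less duration-biased popularity measure than
#' raw counts.
#'
#' @name network-features
NULL

#' Compute network features from connection lists
#'
#' @param conn a [connection_lists()] object.
#' @param usage_months usage duration in months (> 0).
#' @return one-row data frame: `<type>_count` for the seven types,
#'   `<type>_per_month` duration-normalized counts, and
#'   `follower_following_ratio` / `request_following_ratio`. Ratios are `NA`
#'   (missing, not 0 or infinite) when the following count is 0; such cases
#'   are dropped pairwise in group tests.
#' @examples
#' conn <- connection_lists(list(followers = as.character(1:100),
#'                               following = as.character(1:50)))
#' connection_stats(conn, usage_months = 12)$follower_following_ratio  # 2
#' @export
connection_stats <- function(conn, usage_months) {
  stopifnot(usage_months > 0)
  cnt <- conn$counts
  out <- data.frame(usage_months = usage_months)
  short <- c(followers = "follower", following = "following",
             requested = "request", hashtag_follows = "hashtag",
             blocked = "blocked", close_friends = "close",
             restricted = "restricted")
  for (ty in names(short)) {
    out[[paste0(short[[ty]], "_count")]] <- as.numeric(cnt[[ty]])
    out[[paste0(short[[ty]], "_per_month")]] <- cnt[[ty]] / usage_months
  }
  if (cnt[["following"]] > 0L) {
    out$follower_following_ratio <- cnt[["followers"]] / cnt[["following"]]
    out$request_following_ratio <- cnt[["requested"]] / cnt[["following"]]
  } else {
    message("following count is 0; ratio metrics recorded as missing")
    out$follower_following_ratio <- NA_real_
    out$request_following_ratio <- NA_real_
  }
  out
}
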