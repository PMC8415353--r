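#' Temporal posting features
#'
#' Posting rate and the distribution of posts over time-of-day bins and
#' weekdays. Day bins are half-open with the lower bound inclusive:
#' night \[0, 6), morning \[6, 12), afternoon \[12, 18), evening \[18, 24),
#' on the archive's recorded local clock. The weekday vector is ordered
#' Monday..Sunday (ISO convention).
#'
#' @name temporal-features
NULL

TIMEOFDAY_BINS <- c("night", "morning", "afternoon", "evening")
WEEKDAYS_ISO <- c("mon", "tue", "wed", "thu", "fri", "sat", "sun")

#' Time-of-day bin of a timestamp
#'
#' @param t POSIXct timestamp(s), resolved to local clock time.
#' @return character vector over `"night"`, `"morning"`, `"afternoon"`,
#'   `"evening"`.
#' @examples
#' time_of_day_bin(as.POSIXct("2019-05-04 13:30:00", tz = "UTC"))  # afternoon
#' @export
time_of_day_bin <- function(t) {
  hr <- as.POSIXlt(t, tz = "UTC")$hour
  TIMEOFDAY_BINS[findInterval(hr, c(0, 6, 12, 18))]
}

iso_weekday <- function(t) {
  # 1 = Monday ... 7 = Sunday
  as.integer(format(t, "%u", tz = "UTC"))
}

#' Temporal profile of a participant's posts
#'
#' @param posts posts data frame with a `timestamp` column (>= 2 posts so the
#'   span is defined).
#' @return one-row data frame: `usage_months`, `posts_per_month`, proportion
#'   columns `prop_night` .. `prop_evening` and `prop_mon` .. `prop_sun`
#'   (each block sums to 1), and posting *rates* per bin
#'   (`rate_night` .., `rate_mon` .., posts/month falling in the bin) used as
#'   the response of the robust between-within ANOVA.
#' @export
temporal_profile <- function(posts) {
  if (nrow(posts) < 2L) {
    stop("temporal profile requires at least 2 posts (span undefined)")
  }
  um <- usage_months(posts)
  n <- nrow(posts)
  out <- data.frame(usage_months = um, posts_per_month = n / um)
  tod <- factor(time_of_day_bin(posts$timestamp), levels = TIMEOFDAY_BINS)
  tod_n <- as.vector(table(tod))
  wd <- factor(WEEKDAYS_ISO[iso_weekday(posts$timestamp)],
               levels = WEEKDAYS_ISO)
  wd_n <- as.vector(table(wd))
  for (i in seq_along(TIMEOFDAY_BINS)) {
    out[[paste0("prop_", TIMEOFDAY_BINS[i])]] <- tod_n[i] / n
    out[[paste0("rate_", TIMEOFDAY_BINS[i])]] <- tod_n[i] / um
  }
  for (i in seq_along(WEEKDAYS_ISO)) {
    out[[paste0("prop_", WEEKDAYS_ISO[i])]] <- wd_n[i] / n
    out[[paste0("rate_", WEEKDAYS_ISO[i])]] <- wd_n[i] / um
  }
  out
}
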