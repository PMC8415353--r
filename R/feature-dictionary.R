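#' The participant feature dictionary
#'
#' All per-participant features compared between groups, in report order:
#' the image block (face count, dimensions, aspect ratio, RGB/HSV moments,
#' colorfulness), the connection block (absolute, duration-normalized and
#' relative counts) and the general-usage block.
#'
#' @return data frame with `feature` (internal key), `label` (report label),
#'   `block`.
#' @export
feature_dictionary <- function() {
  blk <- function(features, block) data.frame(
    feature = features, block = block, stringsAsFactors = FALSE)
  d <- rbind(
    blk(c("face_count", "width", "height", "aspect_ratio", "pct_nonsquare",
          "mean_R", "mean_G", "mean_B", "sd_R", "sd_G", "sd_B",
          "skew_R", "skew_G", "skew_B", "mean_H", "mean_S", "mean_V",
          "sd_S", "sd_V", "skew_S", "skew_V", "colorfulness"), "image"),
    blk(c("follower_count", "following_count", "request_count",
          "hashtag_count", "blocked_count", "close_count",
          "restricted_count", "blocked_per_month", "close_per_month",
          "follower_per_month", "following_per_month",
          "follower_following_ratio", "request_following_ratio"), "network"),
    blk(c("usage_months", "posts_per_month"), "usage")
  )
  ref <- reference_group_summaries()
  d$label <- ref$label[match(d$feature, ref$feature)]
  d$label[is.na(d$label)] <- d$feature[is.na(d$label)]
  d[, c("feature", "label", "block")]
}

#' Reference group summary statistics
#'
#' The bundled per-feature group summaries (mean, SD, n for the SSD and HV
#' groups) that parameterize the synthetic cohort generator and serve as
#' inputs for summary-level worked examples (recomputing t statistics and
#' effect sizes from published group tables).
#'
#' @return data frame with `feature`, `label`, `mean_hv`, `sd_hv`,
#'   `mean_ssd`, `sd_ssd`, `n_hv`, `n_ssd`.
#' @export
reference_group_summaries <- function() {
  read.csv(system.file("extdata", "reference_group_summaries.csv",
                       package = "instaphen"),
           stringsAsFactors = FALSE)
}

#' Assemble all features for one participant
#'
#' Runs image feature extraction over every readable post image, aggregates
#' to participant level, and appends network and temporal features plus
#' demographics. This is the per-participant unit of statistical analysis:
#' image metrics are averaged within participant before any group test.
#'
#' @param archive a `participant_archive` from [parse_archive()].
#' @param detector a [face_detector()]; the stub detector requires the
#'   archive to carry embedded ground-truth counts.
#' @param cutoff,tau aspect-ratio window and squareness tolerance, see
#'   [aspect_features()].
#' @return one-row data frame of demographics + all dictionary features +
#'   temporal proportion/rate columns; attribute `n_missing_images` counts
#'   unreadable images.
#' @export
participant_features <- function(archive, detector = face_detector("stub"),
                                 cutoff = as.POSIXct("2016-01-01", tz = "UTC"),
                                 tau = 0.005) {
  posts <- archive$posts
  stopifnot(nrow(posts) >= 2L)
  recs <- image_feature_table(archive, detector = detector,
                              cutoff = cutoff, tau = tau)
  agg <- aggregate_images(recs)
  um <- usage_months(posts)
  net <- connection_stats(archive$connections, um)
  tmp <- temporal_profile(posts)
  demo <- archive$demographics
  out <- cbind(
    data.frame(participant_id = demo$participant_id %||% NA_character_,
               group = demo$group,
               age = demo$age %||% NA_real_,
               sex = demo$sex %||% NA_character_,
               race = demo$race %||% NA_character_,
               ethnicity = demo$ethnicity %||% NA_character_,
               stringsAsFactors = FALSE),
    agg,
    net[, setdiff(names(net), "usage_months"), drop = FALSE],
    tmp
  )
  attr(out, "n_missing_images") <- sum(posts$missing_image)
  out
}
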