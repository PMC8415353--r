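#' Synthetic cohort generation
#'
#' Generates complete two-group cohorts -- archives with PNG images,
#' connection lists, demographics and timestamps -- whose statistical
#' structure mirrors the reference group summaries: HSV targets and face
#' rates offset between groups, heavy right-skewed (lognormal) follower and
#' following counts, weekend-elevated posting, and an evening-heavy
#' time-of-day profile. Every generative parameter is recorded per
#' participant in a ground-truth manifest so that recovery is testable, and
#' all randomness flows from the single seed in the config: the same config
#' always produces byte-identical cohorts.
#'
#' @name synthetic-data
NULL

# lognormal (meanlog, sdlog) with a given mean and SD on the natural scale
lognormal_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog2 <- log(1 + cv2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the reference study conditions: 34 participants per
#' group, 30-320 posts over 12-84 months each, per-group HSV and face-count
#' targets and between-participant spreads from the bundled group summaries,
#' lognormal follower/following counts fitted to the group means and SDs,
#' a modest weekend posting uplift and an evening-heavy day profile.
#'
#' @param n_per_group participants per group.
#' @param seed integer master seed; the only source of randomness.
#' @param posts_per_participant inclusive range of posts per participant.
#' @param months_span range of first-to-last post span in months.
#' @param hsv_means named list (`HV`, `SSD`) of target `c(H, S, V)` means.
#' @param hsv_between_sd per-group between-participant SDs of the targets.
#' @param hsv_within_sd per-pixel within-image SDs `c(H, S, V)`.
#' @param face_lambda per-group mean of the participant-level face rate.
#' @param face_between_sd per-group between-participant SD of the face rate.
#' @param weekend_uplift multiplicative posting-intensity factor applied to
#'   Saturdays and Sundays (1 = uniform week).
#' @param timeofday_weights sampling weights for night/morning/afternoon/
#'   evening.
#' @param image_size generated image `c(width, height)` in pixels.
#' @param face_size face-template side length in pixels.
#' @param group_levels group labels, case group first.
#' @param summaries reference summaries data frame used for connection-count
#'   and demographic parameterization.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 34L,
                          seed = 1L,
                          posts_per_participant = c(30L, 320L),
                          months_span = c(12, 84),
                          hsv_means = list(
                            HV = c(H = 30.98, S = 83.9, V = 138.82),
                            SSD = c(H = 25.30, S = 77.63, V = 132.06)),
                          hsv_between_sd = list(
                            HV = c(H = 14.66, S = 9.88, V = 12.26),
                            SSD = c(H = 15.79, S = 13.53, V = 17.78)),
                          hsv_within_sd = c(H = 10, S = 48, V = 60),
                          face_lambda = c(HV = 2.38, SSD = 1.46),
                          face_between_sd = c(HV = 1.01, SSD = 0.79),
                          weekend_uplift = 1.5,
                          timeofday_weights = c(night = 0.10, morning = 0.15,
                                                afternoon = 0.35,
                                                evening = 0.40),
                          image_size = c(64L, 64L),
                          face_size = 16L,
                          group_levels = c("SSD", "HV"),
                          summaries = reference_group_summaries()) {
  stopifnot(n_per_group >= 2, weekend_uplift > 0,
            all(timeofday_weights >= 0), face_size >= 8,
            all(unlist(hsv_between_sd) >= 0), all(hsv_within_sd >= 0),
            all(face_lambda >= 0), all(face_between_sd >= 0))
  structure(list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    posts_per_participant = posts_per_participant,
    months_span = months_span,
    hsv_means = hsv_means, hsv_between_sd = hsv_between_sd,
    hsv_within_sd = hsv_within_sd,
    face_lambda = face_lambda, face_between_sd = face_between_sd,
    weekend_uplift = weekend_uplift,
    timeofday_weights = timeofday_weights / sum(timeofday_weights),
    image_size = as.integer(image_size), face_size = as.integer(face_size),
    group_levels = group_levels,
    summaries = summaries
  ), class = "cohort_config")
}

#' Zero-effect variant of a config
#'
#' Both groups share the HV parameterization (HSV targets, face rate,
#' connection distributions), giving a null cohort for calibration.
#'
#' @param config a [cohort_config()].
#' @return modified config.
#' @export
null_config <- function(config = cohort_config()) {
  config$hsv_means$SSD <- config$hsv_means$HV
  config$hsv_between_sd$SSD <- config$hsv_between_sd$HV
  config$face_lambda[["SSD"]] <- config$face_lambda[["HV"]]
  config$face_between_sd[["SSD"]] <- config$face_between_sd[["HV"]]
  s <- config$summaries
  s$mean_ssd <- s$mean_hv
  s$sd_ssd <- s$sd_hv
  config$summaries <- s
  config
}

summary_row <- function(config, feature) {
  s <- config$summaries
  s[s$feature == feature, , drop = FALSE]
}

group_mean_sd <- function(config, feature, group) {
  r <- summary_row(config, feature)
  if (group == "HV") c(mean = r$mean_hv, sd = r$sd_hv)
  else c(mean = r$mean_ssd, sd = r$sd_ssd)
}

#' Generate one synthetic image
#'
#' Pixels are sampled in HSV space around the target (hue wrapped mod 180,
#' S and V clipped to `[0, 255]` -- clipping introduces a slight mean bias
#' near the range edges), converted to RGB with the standard hexcone
#' transform, and `n_faces` face templates are composited at non-overlapping
#' grid positions by overwriting the V channel with the template luminance
#' pattern (hue and saturation are preserved under the patch).
#'
#' @param target_hsv numeric `c(H, S, V)` target means.
#' @param jitter per-pixel SDs `c(H, S, V)`.
#' @param n_faces number of faces to composite.
#' @param size image `c(width, height)`; faces must fit, otherwise an error.
#' @param face_size template side length.
#' @return list with `img` (RGB array in `[0, 255]`) and `truth`
#'   (`target_hsv`, `n_faces`). Uses the current RNG state; seed externally.
#' @export
generate_image <- function(target_hsv, jitter = c(H = 10, S = 48, V = 60),
                           n_faces = 0L, size = c(64L, 64L),
                           face_size = 16L) {
  w <- size[1]; h <- size[2]
  npx <- w * h
  H <- (rnorm(npx, target_hsv[[1]], jitter[[1]])) %% 180
  S <- pmin(pmax(rnorm(npx, target_hsv[[2]], jitter[[2]]), 0), 255)
  V <- pmin(pmax(rnorm(npx, target_hsv[[3]], jitter[[3]]), 0), 255)
  Hm <- matrix(H, h, w); Sm <- matrix(S, h, w); Vm <- matrix(V, h, w)
  if (n_faces > 0L) {
    tmpl <- face_template(face_size) * 255
    cells_r <- floor(h / face_size); cells_c <- floor(w / face_size)
    capacity <- cells_r * cells_c
    if (n_faces > capacity) {
      stop(sprintf("%d faces do not fit in a %dx%d image (capacity %d)",
                   n_faces, w, h, capacity))
    }
    cells <- sample.int(capacity, n_faces)
    for (cl in cells) {
      ri <- ((cl - 1L) %/% cells_c) * face_size + 1L
      ci <- ((cl - 1L) %% cells_c) * face_size + 1L
      Vm[ri:(ri + face_size - 1L), ci:(ci + face_size - 1L)] <- tmpl
    }
  }
  cols <- grDevices::hsv(h = as.vector(Hm) / 180 * (179.999 / 180),
                         s = as.vector(Sm) / 255, v = as.vector(Vm) / 255)
  rgb <- grDevices::col2rgb(cols)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- matrix(rgb[1, ], h, w)
  img[, , 2] <- matrix(rgb[2, ], h, w)
  img[, , 3] <- matrix(rgb[3, ], h, w)
  list(img = img,
       truth = list(target_hsv = target_hsv, n_faces = as.integer(n_faces)))
}

# weekday sampling probabilities implied by the weekly intensity:
# weekend days carry `uplift` times the weekday intensity
weekday_probs <- function(uplift) {
  w <- c(rep(1, 5), rep(uplift, 2))
  w / sum(w)
}

sample_post_timestamps <- function(n_posts, span_days, config,
                                   anchor = as.POSIXct("2020-10-01 00:00:00",
                                                       tz = "UTC")) {
  start <- anchor - span_days * 86400
  all_days <- 0:floor(span_days)
  day_wd <- as.integer(format(start + all_days * 86400, "%u", tz = "UTC"))
  w <- ifelse(day_wd >= 6L, config$weekend_uplift, 1)
  days <- sample(all_days, n_posts, replace = TRUE, prob = w)
  # pin the first and last day so the configured span is realized exactly
  days[1] <- 0L
  days[n_posts] <- max(all_days)
  bin <- sample.int(4L, n_posts, replace = TRUE,
                    prob = config$timeofday_weights)
  hour <- (bin - 1L) * 6L + sample.int(6L, n_posts, replace = TRUE) - 1L
  minute <- sample.int(60L, n_posts, replace = TRUE) - 1L
  sort(start + days * 86400 + hour * 3600 + minute * 60)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

sample_connections <- function(group, config) {
  draw_ln <- function(feature) {
    ms <- group_mean_sd(config, feature, group)
    p <- lognormal_params(ms[["mean"]], ms[["sd"]])
    max(0L, round(rlnorm(1, p$meanlog, p$sdlog)))
  }
  draw_pois <- function(feature) {
    ms <- group_mean_sd(config, feature, group)
    rpois(1, ms[["mean"]])
  }
  connection_lists(list(
    followers = draw_ln("follower_count"),
    following = max(1L, draw_ln("following_count")),
    requested = draw_pois("request_count"),
    hashtag_follows = draw_pois("hashtag_count"),
    blocked = draw_pois("blocked_count"),
    close_friends = draw_pois("close_count"),
    restricted = draw_pois("restricted_count")
  ))
}

sample_demographics <- function(pid, group, config) {
  sex_p_female <- if (group == "HV") 16 / 34 else 12 / 34
  race_p <- if (group == "HV") c(7, 10, 3, 14) / 34 else c(15, 6, 3, 10) / 34
  eth_p_hisp <- if (group == "HV") 5 / 34 else 4 / 34
  races <- c("african_american", "native_american", "other_mixed", "white")
  list(participant_id = pid, group = group,
       age = round(rnorm_trunc(1, 23.6, 4.1, 15, 35), 1),
       sex = if (runif(1) < sex_p_female) "female" else "male",
       race = sample(races, 1, prob = race_p),
       ethnicity = if (runif(1) < eth_p_hisp) "hispanic" else "non_hispanic")
}

#' Generate one participant archive on disk
#'
#' Draws the participant's generative truth (HSV targets, face rate, span,
#' post count, connection counts, demographics), renders every post image as
#' a PNG, and writes the canonical-dialect archive including a
#' `ground_truth.json` sidecar with the per-post face counts and all
#' generative parameters. Uses the current RNG state.
#'
#' @param pid participant id (also the directory name).
#' @param group group label.
#' @param config a [cohort_config()].
#' @param dir parent directory.
#' @param write_images if `FALSE`, PNG rendering is skipped (metadata-only
#'   archive for tests that never read pixels).
#' @return participant truth record (list), invisibly; archive at
#'   `file.path(dir, pid)`.
#' @export
generate_participant <- function(pid, group, config, dir,
                                 write_images = TRUE) {
  root <- file.path(dir, pid)
  dir.create(file.path(root, "media"), recursive = TRUE,
             showWarnings = FALSE)
  demo <- sample_demographics(pid, group, config)
  n_posts <- sample(config$posts_per_participant[1]:
                      config$posts_per_participant[2], 1)
  span_days <- runif(1, config$months_span[1], config$months_span[2]) *
    DAYS_PER_MONTH
  ts <- sample_post_timestamps(n_posts, span_days, config)

  mu <- config$hsv_means[[group]]
  bsd <- config$hsv_between_sd[[group]]
  target <- c(H = (rnorm(1, mu[["H"]], bsd[["H"]])) %% 180,
              S = rnorm_trunc(1, mu[["S"]], bsd[["S"]], 0, 255),
              V = rnorm_trunc(1, mu[["V"]], bsd[["V"]], 0, 255))
  face_rate <- rnorm_trunc(1, config$face_lambda[[group]],
                           config$face_between_sd[[group]], 0, Inf)
  capacity <- prod(floor(config$image_size / config$face_size))
  n_faces <- pmin(rpois(n_posts, face_rate), capacity)

  files <- sprintf("media/img%04d.png", seq_len(n_posts))
  for (i in seq_len(n_posts)) {
    im <- generate_image(target, config$hsv_within_sd, n_faces[i],
                         size = config$image_size,
                         face_size = config$face_size)
    if (write_images) {
      png::writePNG(im$img / 255, file.path(root, files[i]))
    }
  }
  posts <- data.frame(
    post_id = sprintf("%s_p%04d", pid, seq_len(n_posts)),
    timestamp = ts, file = files,
    width = config$image_size[1], height = config$image_size[2],
    stringsAsFactors = FALSE
  )
  conn <- sample_connections(group, config)
  truth <- list(
    participant_id = pid, group = group,
    target_hsv = as.list(target), face_rate = face_rate,
    n_posts = n_posts, span_days = span_days,
    posts = data.frame(post_id = posts$post_id, n_faces = n_faces,
                       stringsAsFactors = FALSE)
  )
  write_archive_metadata(root, demo, posts, conn, truth = truth)
  invisible(truth)
}

#' Generate a complete synthetic cohort
#'
#' @param config a [cohort_config()]; `config$seed` fixes everything.
#' @param dir output directory; one archive per participant plus
#'   `manifest.csv` recording the generative truth.
#' @param write_images if `FALSE`, metadata-only archives.
#' @return data frame manifest (participant_id, group, generative
#'   parameters), invisibly.
#' @export
generate_cohort <- function(config, dir, write_images = TRUE) {
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (group in config$group_levels) {
    for (i in seq_len(config$n_per_group)) {
      pid <- sprintf("%s%03d", group, i)
      tr <- generate_participant(pid, group, config, dir,
                                 write_images = write_images)
      rows[[pid]] <- data.frame(
        participant_id = pid, group = group,
        target_H = tr$target_hsv$H, target_S = tr$target_hsv$S,
        target_V = tr$target_hsv$V, face_rate = tr$face_rate,
        n_posts = tr$n_posts, span_days = tr$span_days,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Sample participant-level features directly
#'
#' Draws the per-participant feature values implied by the generator's
#' statistical model without rendering archives: image-feature means are
#' normal with the group target mean and between-participant SD, face-count
#' means are Poisson-averaged around a truncated-normal participant rate,
#' follower/following counts are lognormal, small connection counts Poisson.
#' This is the model used for calibration and power simulations, where
#' thousands of cohorts are needed.
#'
#' @param config a [cohort_config()].
#' @param features feature keys to draw (default: the testable dictionary
#'   features the model parameterizes).
#' @return data frame: `participant_id`, `group`, one column per feature.
#'   Uses the current RNG state; seed externally.
#' @export
sample_cohort_features <- function(config,
                                   features = c("mean_S", "mean_V",
                                                "colorfulness", "face_count",
                                                "follower_count",
                                                "following_count",
                                                "follower_following_ratio")) {
  n <- config$n_per_group
  rows <- lapply(config$group_levels, function(group) {
    out <- data.frame(
      participant_id = sprintf("%s%03d", group, seq_len(n)),
      group = group, stringsAsFactors = FALSE)
    post_n <- sample(config$posts_per_participant[1]:
                       config$posts_per_participant[2], n, replace = TRUE)
    for (f in features) {
      if (f == "face_count") {
        rate <- rnorm_trunc(n, config$face_lambda[[group]],
                            config$face_between_sd[[group]], 0, Inf)
        out[[f]] <- vapply(seq_len(n), function(i) {
          mean(rpois(post_n[i], rate[i]))
        }, numeric(1))
      } else if (f %in% c("follower_count", "following_count")) {
        ms <- group_mean_sd(config, f, group)
        p <- lognormal_params(ms[["mean"]], ms[["sd"]])
        out[[f]] <- pmax(round(rlnorm(n, p$meanlog, p$sdlog)),
                         if (f == "following_count") 1 else 0)
      } else if (f == "follower_following_ratio") {
        next  # derived below
      } else if (f == "mean_S") {
        out[[f]] <- rnorm_trunc(n, config$hsv_means[[group]][["S"]],
                                config$hsv_between_sd[[group]][["S"]], 0, 255)
      } else if (f == "mean_V") {
        out[[f]] <- rnorm_trunc(n, config$hsv_means[[group]][["V"]],
                                config$hsv_between_sd[[group]][["V"]], 0, 255)
      } else {
        ms <- group_mean_sd(config, f, group)
        out[[f]] <- rnorm(n, ms[["mean"]], ms[["sd"]])
      }
    }
    if ("follower_following_ratio" %in% features &&
        all(c("follower_count", "following_count") %in% names(out))) {
      out$follower_following_ratio <- out$follower_count / out$following_count
    }
    out
  })
  do.call(rbind, rows)
}

#' Sample per-participant temporal posting rates
#'
#' Draws posting-rate vectors (posts per month in each time-of-day bin or
#' weekday) from the generator's weekly-intensity model: bin counts are
#' multinomial with the configured weights (weekend days carry
#' `weekend_uplift` times the weekday intensity), divided by the
#' participant's usage months. Long-format output feeds
#' [robust_mixed_anova()].
#'
#' @param config a [cohort_config()].
#' @param design `"timeofday"` (K = 4) or `"weekday"` (K = 7).
#' @return long data frame: `id`, `group`, `condition`, `value`.
#'   Uses the current RNG state; seed externally.
#' @export
sample_temporal_rates <- function(config, design = c("timeofday", "weekday")) {
  design <- match.arg(design)
  if (design == "timeofday") {
    probs <- config$timeofday_weights
    conds <- TIMEOFDAY_BINS
  } else {
    probs <- weekday_probs(config$weekend_uplift)
    conds <- WEEKDAYS_ISO
  }
  n <- config$n_per_group
  rows <- lapply(config$group_levels, function(group) {
    post_n <- sample(config$posts_per_participant[1]:
                       config$posts_per_participant[2], n, replace = TRUE)
    months <- runif(n, config$months_span[1], config$months_span[2])
    counts <- vapply(seq_len(n),
                     function(i) rmultinom(1, post_n[i], probs)[, 1],
                     numeric(length(conds)))
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(id = sprintf("%s%03d", group, i), group = group,
                 condition = factor(conds, levels = conds),
                 value = counts[, i] / months[i],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
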