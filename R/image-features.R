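#' Image colorimetry and composition features
#'
#' Per-image features cover dimensions and aspect ratio, RGB and HSV channel
#' moments (mean, standard deviation, skewness), the circular mean of hue,
#' the Hasler-Suesstrunk colorfulness score, and a face count. Features are
#' computed at the stored image resolution; width and height are themselves
#' features, so no resizing is performed.
#'
#' @name image-features
NULL

#' Construct an image matrix from an RGB array
#'
#' An image is represented as an `H x W x 3` numeric array with channel values
#' in `[0, 255]` (double precision; no 8-bit rounding is imposed on computed
#' quantities).
#'
#' @param x numeric array `H x W x 3` with values in `[0, 255]`, or an
#'   `H x W x 3` (or `H x W x 4`, alpha dropped) array in `[0, 1]` such as
#'   returned by [png::readPNG()] when `scale01 = TRUE`.
#' @param scale01 logical; if `TRUE`, `x` is in `[0, 1]` and is rescaled.
#' @return numeric array `H x W x 3` in `[0, 255]`.
#' @export
as_image <- function(x, scale01 = FALSE) {
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  stopifnot(length(dim(x)) == 3L, dim(x)[3] >= 3L)
  x <- x[, , 1:3, drop = FALSE]
  if (scale01) x <- x * 255
  if (any(x < -1e-9) || any(x > 255 + 1e-9)) {
    stop("image channel values outside [0, 255]")
  }
  x
}

#' Read a PNG image as an image matrix
#'
#' @param path path to a PNG file.
#' @return image array in `[0, 255]`, or `NULL` (with a warning) if the file
#'   cannot be decoded; unreadable images are recorded as missing, not fatal.
#' @export
read_image <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e) NULL)
  if (is.null(img)) {
    warning(sprintf("unreadable image: %s", path), call. = FALSE)
    return(NULL)
  }
  as_image(img, scale01 = TRUE)
}

# HSV channels on the OpenCV-style scale: H in [0, 180), S and V in [0, 255].
# Conversion uses the standard hexcone formulas via grDevices::rgb2hsv.
image_hsv <- function(img) {
  d <- dim(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  hsv <- rgb2hsv(r, g, b, maxColorValue = 255)
  list(
    H = matrix(hsv[1, ] * 180, d[1], d[2]),
    S = matrix(hsv[2, ] * 255, d[1], d[2]),
    V = matrix(hsv[3, ] * 255, d[1], d[2])
  )
}

channel_values <- function(img, channel) {
  switch(channel,
    R = as.vector(img[, , 1]),
    G = as.vector(img[, , 2]),
    B = as.vector(img[, , 3]),
    H = as.vector(image_hsv(img)$H),
    S = as.vector(image_hsv(img)$S),
    V = as.vector(image_hsv(img)$V),
    stop("unknown channel: ", channel)
  )
}

#' Channel moments: mean, population SD, population skewness
#'
#' The pixel set of one image is treated as a complete population, so the
#' standard deviation uses the `1/n` variance and the skewness is the third
#' standardized population moment `m3 / m2^(3/2)`. A zero-variance (flat)
#' channel has skewness 0 by convention, so flat images yield no missing
#' values.
#'
#' @param img image array (see [as_image()]).
#' @param channel one of `"R"`, `"G"`, `"B"`, `"S"`, `"V"`.
#' @return named numeric vector `c(mean, sd, skew)`.
#' @examples
#' img <- as_image(array(100, dim = c(2, 2, 3)))
#' channel_moments(img, "R")  # mean 100, sd 0, skew 0
#' @export
channel_moments <- function(img, channel = c("R", "G", "B", "S", "V")) {
  channel <- match.arg(channel)
  x <- channel_values(img, channel)
  moments_pop(x)
}

moments_pop <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  if (m2 <= 0) return(c(mean = m, sd = 0, skew = 0))
  m3 <- sum(d^3) / n
  c(mean = m, sd = sqrt(m2), skew = m3 / m2^1.5)
}

#' Circular mean of hue
#'
#' Hue is an angular quantity on the 0-179 scale (half-degrees), so high hues
#' are close to low hues and an arithmetic mean is meaningless near the wrap
#' point. Each hue `h` is mapped to the angle `2h` degrees, the mean resultant
#' vector is computed, and its angle is halved back to hue units. When the
#' resultant length is numerically zero (e.g. exactly antipodal mass) the mean
#' direction is undefined and `NA` is returned.
#'
#' @param img image array, or a bare numeric vector of hues in `[0, 180)` via
#'   [circular_mean()].
#' @param eps resultant-length threshold below which the mean is undefined.
#' @return mean hue in `[0, 180)`, or `NA_real_`.
#' @export
circular_hue_mean <- function(img, eps = 1e-8) {
  circular_mean(as.vector(image_hsv(img)$H), eps = eps)
}

#' @rdname circular_hue_mean
#' @param hues numeric vector of hues in `[0, 180)`; `NA`s are dropped.
#' @param weights optional non-negative weights.
#' @export
circular_mean <- function(hues, weights = NULL, eps = 1e-8) {
  hues <- hues[!is.na(hues)]
  if (length(hues) == 0L) return(NA_real_)
  ang <- 2 * hues * pi / 180
  if (is.null(weights)) weights <- rep(1, length(ang))
  w <- weights / sum(weights)
  cbar <- sum(w * cos(ang)); sbar <- sum(w * sin(ang))
  if (sqrt(cbar^2 + sbar^2) < eps) return(NA_real_)
  mean_ang <- atan2(sbar, cbar) %% (2 * pi)
  (mean_ang * 180 / pi / 2) %% 180
}

#' Hasler-Suesstrunk colorfulness
#'
#' Opponent components are computed per pixel, `rg = R - G` and
#' `yb = (R + G) / 2 - B`; the score is
#' `sqrt(sd(rg)^2 + sd(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)`
#' with population standard deviations. A uniform gray image scores exactly 0.
#'
#' @param img image array.
#' @return non-negative colorfulness score.
#' @examples
#' gray <- as_image(array(128, dim = c(4, 4, 3)))
#' colorfulness(gray)  # 0
#' @export
colorfulness <- function(img) {
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  rg <- r - g
  yb <- (r + g) / 2 - b
  n <- length(rg)
  mu_rg <- mean(rg); mu_yb <- mean(yb)
  sd_rg <- sqrt(sum((rg - mu_rg)^2) / n)
  sd_yb <- sqrt(sum((yb - mu_yb)^2) / n)
  sqrt(sd_rg^2 + sd_yb^2) + 0.3 * sqrt(mu_rg^2 + mu_yb^2)
}

#' Aspect-ratio features with an analysis-window cutoff
#'
#' Non-default aspect ratios only became possible on the platform in mid 2015,
#' so posts before the cutoff date (default 2016-01-01) are excluded from
#' aspect-ratio aggregation. A post is "non-square" when its width/height
#' ratio differs from 1 by more than `tau` (default 0.005, absorbing 1-pixel
#' rounding at typical resolutions).
#'
#' @param width,height positive pixel dimensions.
#' @param timestamp POSIXct timestamp of the post.
#' @param cutoff posts timestamped before this date are flagged out-of-window.
#' @param tau tolerance on `|aspect_ratio - 1|` for squareness.
#' @return list with `aspect_ratio`, `is_nonsquare`, `in_aspect_window`.
#' @export
aspect_features <- function(width, height, timestamp,
                            cutoff = as.POSIXct("2016-01-01", tz = "UTC"),
                            tau = 0.005) {
  if (is.na(height) || height <= 0) stop("zero or invalid image height")
  ar <- width / height
  list(
    aspect_ratio = ar,
    is_nonsquare = abs(ar - 1) > tau,
    in_aspect_window = as.numeric(timestamp) >= as.numeric(cutoff)
  )
}

IMAGE_FEATURE_NAMES <- c(
  "width", "height", "aspect_ratio", "is_nonsquare",
  "mean_R", "mean_G", "mean_B", "sd_R", "sd_G", "sd_B",
  "skew_R", "skew_G", "skew_B",
  "mean_H", "mean_S", "mean_V", "sd_S", "sd_V", "skew_S", "skew_V",
  "colorfulness", "face_count"
)

#' Compute the full per-image feature record
#'
#' @param img image array, or `NULL` for an unreadable image (all pixel
#'   features `NA`, dimension features taken from the post metadata).
#' @param post one-row data frame or list with `post_id`, `timestamp`,
#'   `width`, `height`, and optionally `n_faces_truth`.
#' @param detector a face detector from [face_detector()].
#' @param cutoff,tau passed to [aspect_features()].
#' @return one-row data frame of all image features plus `post_id` and
#'   `post_timestamp`.
#' @export
image_feature_record <- function(img, post, detector = face_detector("stub"),
                                 cutoff = as.POSIXct("2016-01-01", tz = "UTC"),
                                 tau = 0.005) {
  asp <- aspect_features(post$width, post$height, post$timestamp,
                         cutoff = cutoff, tau = tau)
  rec <- data.frame(
    post_id = as.character(post$post_id),
    post_timestamp = post$timestamp,
    width = as.numeric(post$width),
    height = as.numeric(post$height),
    aspect_ratio = asp$aspect_ratio,
    is_nonsquare = asp$is_nonsquare,
    in_aspect_window = asp$in_aspect_window,
    stringsAsFactors = FALSE
  )
  pix_cols <- c("mean_R", "mean_G", "mean_B", "sd_R", "sd_G", "sd_B",
                "skew_R", "skew_G", "skew_B", "mean_H", "mean_S", "mean_V",
                "sd_S", "sd_V", "skew_S", "skew_V", "colorfulness",
                "face_count")
  for (cn in pix_cols) rec[[cn]] <- NA_real_
  if (is.null(img)) return(rec)
  for (ch in c("R", "G", "B")) {
    m <- channel_moments(img, ch)
    rec[[paste0("mean_", ch)]] <- m[["mean"]]
    rec[[paste0("sd_", ch)]] <- m[["sd"]]
    rec[[paste0("skew_", ch)]] <- m[["skew"]]
  }
  hsv <- image_hsv(img)
  for (ch in c("S", "V")) {
    m <- moments_pop(as.vector(hsv[[ch]]))
    rec[[paste0("mean_", ch)]] <- m[["mean"]]
    rec[[paste0("sd_", ch)]] <- m[["sd"]]
    rec[[paste0("skew_", ch)]] <- m[["skew"]]
  }
  rec$mean_H <- circular_mean(as.vector(hsv$H))
  rec$colorfulness <- colorfulness(img)
  rec$face_count <- count_faces(img, detector, truth = post$n_faces_truth %||% NA)
  rec
}

#' Aggregate per-image records to participant level
#'
#' Every feature is the arithmetic mean over the participant's images, with
#' two exceptions: mean hue is aggregated by the circular mean of the per-image
#' circular means, and aspect-ratio features (`aspect_ratio`,
#' `pct_nonsquare`) are averaged only over posts inside the aspect analysis
#' window. When no post falls in the window the aspect features are `NA` and
#' all other features are still computed.
#'
#' @param records data frame of per-image rows from [image_feature_record()].
#' @return one-row data frame of participant-level image features, including
#'   `pct_nonsquare` in `[0, 100]` and `n_images` / `n_images_aspect` counts.
#' @export
aggregate_images <- function(records) {
  stopifnot(nrow(records) >= 1L)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- data.frame(n_images = nrow(records))
  plain <- c("width", "height", "mean_R", "mean_G", "mean_B",
             "sd_R", "sd_G", "sd_B", "skew_R", "skew_G", "skew_B",
             "mean_S", "mean_V", "sd_S", "sd_V", "skew_S", "skew_V",
             "colorfulness", "face_count")
  for (cn in plain) out[[cn]] <- mean_na(records[[cn]])
  out$mean_H <- circular_mean(records$mean_H)
  win <- records[records$in_aspect_window, , drop = FALSE]
  out$n_images_aspect <- nrow(win)
  if (nrow(win) > 0L) {
    out$aspect_ratio <- mean_na(win$aspect_ratio)
    out$pct_nonsquare <- 100 * mean_na(as.numeric(win$is_nonsquare))
  } else {
    out$aspect_ratio <- NA_real_
    out$pct_nonsquare <- NA_real_
  }
  out
}
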