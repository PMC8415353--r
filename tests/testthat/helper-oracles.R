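# Brute-force oracles and fixture builders. Every oracle is a plain loop or
# direct enumeration, independent of the implementation path it checks.

bf_moments <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  m2 <- 0; m3 <- 0
  for (v in x) {
    m2 <- m2 + (v - m)^2 / n
    m3 <- m3 + (v - m)^3 / n
  }
  c(mean = m, sd = sqrt(m2), skew = if (m2 > 0) m3 / m2^1.5 else 0)
}

bf_colorfulness <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rg <- c(); yb <- c()
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rg <- c(rg, img[i, j, 1] - img[i, j, 2])
    yb <- c(yb, (img[i, j, 1] + img[i, j, 2]) / 2 - img[i, j, 3])
  }
  mrg <- bf_moments(rg); myb <- bf_moments(yb)
  sqrt(mrg[["sd"]]^2 + myb[["sd"]]^2) +
    0.3 * sqrt(mrg[["mean"]]^2 + myb[["mean"]]^2)
}

bf_circular_mean_hue <- function(hues) {
  cs <- 0; sn <- 0
  for (h in hues) {
    a <- 2 * h * pi / 180
    cs <- cs + cos(a); sn <- sn + sin(a)
  }
  r <- sqrt(cs^2 + sn^2) / length(hues)
  if (r < 1e-8) return(NA_real_)
  ang <- atan2(sn, cs) %% (2 * pi)
  (ang * 180 / pi / 2) %% 180
}

# U statistic for sample x by direct pairwise-win counting (ties count 1/2)
bf_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

bf_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

random_image <- function(h, w) {
  as_image(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

uniform_image <- function(r, g, b, h = 4, w = 4) {
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  as_image(img)
}

# image with every pixel at a given HSV triple (package-scale H 0-180,
# S/V 0-255), built through the inverse hexcone transform
hsv_uniform_image <- function(H, S, V, h = 4, w = 4) {
  col <- grDevices::col2rgb(grDevices::hsv(H / 180, S / 255, V / 255))
  uniform_image(col[1], col[2], col[3], h, w)
}

# minimal canonical-dialect archive with uniform-colored PNG posts
write_fixture_archive <- function(root, pid = "P001", group = "HV",
                                  timestamps, widths = NULL, heights = NULL,
                                  connections = list(
                                    followers = sprintf("f%03d", 1:10),
                                    following = sprintf("g%03d", 1:5),
                                    blocked = 2L),
                                  corrupt = integer(0)) {
  n <- length(timestamps)
  widths <- widths %||% rep(32L, n)
  heights <- heights %||% rep(32L, n)
  dir.create(file.path(root, "media"), recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("media/img%02d.png", seq_len(n))
  for (i in seq_len(n)) {
    if (i %in% corrupt) {
      writeLines("this is not a png", file.path(root, files[i]))
    } else {
      img <- array(runif(widths[i] * heights[i] * 3), dim = c(heights[i], widths[i], 3))
      png::writePNG(img, file.path(root, files[i]))
    }
  }
  posts <- data.frame(post_id = sprintf("%s_p%02d", pid, seq_len(n)),
                      timestamp = timestamps, file = files,
                      width = widths, height = heights,
                      stringsAsFactors = FALSE)
  demo <- list(participant_id = pid, group = group, age = 24, sex = "female",
               race = "white", ethnicity = "non_hispanic")
  write_archive_metadata(root, demo, posts, connection_lists(connections))
  root
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ts_seq <- function(from, by_days, n) {
  as.POSIXct(from, tz = "UTC") + (seq_len(n) - 1) * by_days * 86400
}

tiny_cohort_config <- function(seed = 42, n = 4) {
  cohort_config(n_per_group = n, seed = seed,
                posts_per_participant = c(8L, 12L),
                months_span = c(4, 10),
                image_size = c(48L, 48L))
}

gated_p <- function(x, y, alpha = 0.05) {
  if (normality_gate(x, y, alpha) == "welch_t") welch_t(x, y)$p
  else mann_whitney_u(x, y)$p
}
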