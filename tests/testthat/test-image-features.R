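test_that("channel moments match closed forms and handle degenerate input", {
  img <- uniform_image(100, 100, 100)
  expect_equal(unname(channel_moments(img, "R")), c(100, 0, 0))
  # 4 pixels {0,0,0,255}: binomial closed form (1-2p)/sqrt(p(1-p)), p = 1/4
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- 255
  m <- channel_moments(as_image(img), "G")
  expect_equal(m[["mean"]], 63.75)
  expect_equal(m[["sd"]], sqrt(3 * 63.75^2 / 4 + 191.25^2 / 4), tolerance = 1e-10)
  expect_equal(m[["skew"]], (1 - 2 * 0.25) / sqrt(0.25 * 0.75), tolerance = 1e-10)
  # symmetry about 128
  img <- array(rep(c(28, 228, 128, 128), 3), dim = c(2, 2, 3))
  expect_equal(channel_moments(as_image(img), "B")[["skew"]], 0)
})

test_that("channel moments equal a brute-force pixel loop on random images", {
  set.seed(101)
  for (k in 1:20) {
    img <- random_image(sample(1:8, 1), sample(1:8, 1))
    for (ch in c("R", "G", "B", "S", "V")) {
      expect_equal(channel_moments(img, ch),
                   bf_moments(instaphen:::channel_values(img, ch)),
                   tolerance = 1e-12)
    }
  }
})

test_that("circular hue mean wraps correctly and degrades to NA", {
  expect_equal(circular_mean(c(10, 10, 10)), 10)
  expect_equal(circular_mean(c(170, 10)), 0, tolerance = 1e-9)
  expect_true(is.na(circular_mean(c(0, 90))))
  # agreement with the arithmetic mean within a 45-degree hue arc: exact only
  # in the zero-dispersion limit, so allow a small dispersion-driven gap
  set.seed(7)
  for (k in 1:25) {
    base <- runif(1, 0, 135)
    hues <- runif(20, base, base + 22.5)
    expect_lt(abs(circular_mean(hues) - mean(hues)), 0.2)
    tight <- runif(20, base, base + 2)
    expect_lt(abs(circular_mean(tight) - mean(tight)), 0.005)
  }
  # oracle equivalence on arbitrary hue sets
  for (k in 1:25) {
    hues <- runif(15, 0, 180)
    expect_equal(circular_mean(hues), bf_circular_mean_hue(hues),
                 tolerance = 1e-9)
  }
})

test_that("colorfulness matches direct evaluation and is permutation invariant", {
  expect_equal(colorfulness(uniform_image(128, 128, 128)), 0)
  expect_equal(colorfulness(uniform_image(37, 37, 37)), 0)
  half <- array(0, dim = c(2, 2, 3))
  half[, 1, 1] <- 255  # left column pure red
  half[, 2, 2] <- 255  # right column pure green
  expect_equal(colorfulness(as_image(half)), 293.25)
  expect_equal(colorfulness(uniform_image(0, 0, 255)), 76.5)
  set.seed(11)
  for (k in 1:10) {
    img <- random_image(6, 6)
    expect_equal(colorfulness(img), bf_colorfulness(img), tolerance = 1e-10)
    perm <- sample(36)
    shuffled <- img
    for (c in 1:3) shuffled[, , c] <- matrix(as.vector(img[, , c])[perm], 6, 6)
    expect_equal(colorfulness(shuffled), colorfulness(img), tolerance = 1e-10)
  }
})

test_that("aspect features honour the ratio, tolerance and date window", {
  t2017 <- as.POSIXct("2017-05-01", tz = "UTC")
  a <- aspect_features(1080, 1080, t2017)
  expect_equal(a$aspect_ratio, 1)
  expect_false(a$is_nonsquare)
  expect_true(a$in_aspect_window)
  a <- aspect_features(1080, 1350, t2017)
  expect_equal(a$aspect_ratio, 0.8)
  expect_true(a$is_nonsquare)
  a <- aspect_features(1080, 1350, as.POSIXct("2015-06-01", tz = "UTC"))
  expect_false(a$in_aspect_window)
  expect_error(aspect_features(100, 0, t2017), "height")
})

test_that("HSV outputs stay in range and mean_S is monotone in saturation", {
  set.seed(21)
  for (k in 1:10) {
    img <- random_image(5, 5)
    H <- instaphen:::channel_values(img, "H")
    S <- instaphen:::channel_values(img, "S")
    V <- instaphen:::channel_values(img, "V")
    expect_true(all(H >= 0 & H < 180))
    expect_true(all(S >= 0 & S <= 255))
    expect_true(all(V >= 0 & V <= 255))
  }
  # scaling the S channel by k < 1 strictly decreases mean_S
  img <- hsv_uniform_image(60, 200, 220, 4, 4)
  for (k in c(0.3, 0.6, 0.9)) {
    scaled <- hsv_uniform_image(60, 200 * k, 220, 4, 4)
    expect_lt(channel_moments(scaled, "S")[["mean"]],
              channel_moments(img, "S")[["mean"]])
  }
})

test_that("participant aggregation averages features and respects the window", {
  rec <- function(colorf, faces, ar, nonsq, win, hue) {
    data.frame(width = 100, height = 100, aspect_ratio = ar,
               is_nonsquare = nonsq, in_aspect_window = win,
               mean_R = 1, mean_G = 1, mean_B = 1, sd_R = 0, sd_G = 0,
               sd_B = 0, skew_R = 0, skew_G = 0, skew_B = 0,
               mean_H = hue, mean_S = 10, mean_V = 10, sd_S = 0, sd_V = 0,
               skew_S = 0, skew_V = 0, colorfulness = colorf,
               face_count = faces)
  }
  recs <- rbind(rec(10, 1, 1.0, FALSE, TRUE, 170),
                rec(30, 2, 0.8, TRUE, TRUE, 10),
                rec(20, 3, 0.8, TRUE, TRUE, 170),
                rec(20, 2, 0.9, TRUE, TRUE, 10))
  agg <- aggregate_images(recs)
  expect_equal(agg$colorfulness, 20)
  expect_equal(agg$face_count, 2)
  expect_equal(agg$pct_nonsquare, 75)
  expect_equal(agg$mean_H, 0, tolerance = 1e-9)  # circular, not arithmetic
  # aspect features only over in-window records; missing when none in window
  recs$in_aspect_window <- c(FALSE, FALSE, TRUE, TRUE)
  agg <- aggregate_images(recs)
  expect_equal(agg$pct_nonsquare, 100)
  expect_equal(agg$aspect_ratio, 0.85)
  recs$in_aspect_window <- FALSE
  agg <- aggregate_images(recs)
  expect_true(is.na(agg$aspect_ratio) && is.na(agg$pct_nonsquare))
  expect_equal(agg$colorfulness, 20)
})
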