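test_that("generated images recover their HSV targets and embed face truth", {
  set.seed(173)
  im <- generate_image(c(H = 40, S = 80, V = 140),
                       jitter = c(H = 0, S = 0, V = 0), n_faces = 0L,
                       size = c(32L, 32L))
  img <- as_image(im$img)
  # jitter-free target survives the HSV->RGB->HSV round trip within
  # 8-bit quantization
  expect_equal(channel_moments(img, "S")[["mean"]], 80, tolerance = 1)
  expect_equal(channel_moments(img, "V")[["mean"]], 140, tolerance = 1)
  expect_equal(circular_hue_mean(img), 40, tolerance = 1)
  expect_equal(im$truth$n_faces, 0L)
  expect_error(generate_image(c(H = 0, S = 0, V = 100), n_faces = 50L,
                              size = c(32L, 32L)), "fit")
})

test_that("image generation is deterministic for a fixed seed", {
  gen <- function() {
    set.seed(183)
    im <- generate_image(c(H = 20, S = 90, V = 150), n_faces = 2L,
                         size = c(48L, 48L))
    f <- tempfile(fileext = ".png")
    png::writePNG(im$img / 255, f)
    readBin(f, "raw", file.size(f))
  }
  expect_identical(gen(), gen())
})

test_that("weekend uplift shapes weekday proportions as the intensity implies", {
  cfg1 <- cohort_config(weekend_uplift = 1)
  cfg3 <- cohort_config(weekend_uplift = 3)
  set.seed(193)
  ts <- instaphen:::sample_post_timestamps(4000, 700, cfg1)
  wd <- as.integer(format(ts, "%u", tz = "UTC"))
  props <- tabulate(wd, 7) / length(wd)
  expect_equal(props, rep(1 / 7, 7), tolerance = 0.03)
  ts <- instaphen:::sample_post_timestamps(4000, 700, cfg3)
  wd <- as.integer(format(ts, "%u", tz = "UTC"))
  expect_equal(mean(wd >= 6), 6 / 11, tolerance = 0.03)
})

test_that("cohorts are deterministic, parseable, and pass inclusion", {
  cfg <- tiny_cohort_config(seed = 17)
  d1 <- tempfile("coh"); d2 <- tempfile("coh")
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)
  expect_equal(m1, m2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  sig <- function(root, files) unname(tools::md5sum(file.path(root, files)))
  expect_identical(sig(d1, f1), sig(d2, f1))
  expect_equal(nrow(m1), 2 * cfg$n_per_group)
  for (root in list.dirs(d1, recursive = FALSE)) {
    a <- parse_archive(root)
    expect_true(inclusion_filter(a)$included)
    # stub detector always equals the embedded ground truth
    expect_false(anyNA(a$posts$n_faces_truth))
  }
})

test_that("written archives re-parse to identical field values", {
  root <- tempfile("arch")
  ts <- ts_seq("2017-02-01 09:30:00", by_days = 45, n = 5)
  demo <- list(participant_id = "X1", group = "SSD", age = 29.5,
               sex = "male", race = "other_mixed", ethnicity = "hispanic")
  posts <- data.frame(post_id = paste0("x", 1:5), timestamp = ts,
                      file = sprintf("media/img%02d.png", 1:5),
                      width = 108L, height = 135L, stringsAsFactors = FALSE)
  dir.create(file.path(root, "media"), recursive = TRUE)
  for (f in posts$file) {
    png::writePNG(array(0.5, dim = c(4, 4, 3)), file.path(root, f))
  }
  conn <- connection_lists(list(followers = c("a", "b", "c"),
                                following = c("d", "e"),
                                requested = 4L, restricted = 1L))
  write_archive_metadata(root, demo, posts, conn)
  a <- parse_archive(root)
  expect_equal(a$demographics[names(demo)], demo)
  expect_equal(a$posts$post_id, posts$post_id)
  expect_equal(a$posts$timestamp, posts$timestamp)
  expect_equal(a$posts$width, rep(108L, 5))
  expect_equal(a$posts$height, rep(135L, 5))
  expect_equal(a$connections$counts, conn$counts)
  expect_equal(a$connections$members$followers, c("a", "b", "c"))
})

test_that("feature-level sampling converges to the configured group targets", {
  cfg <- cohort_config(n_per_group = 400)
  set.seed(203)
  f <- sample_cohort_features(cfg, features = c("mean_S", "face_count",
                                                "follower_count"))
  for (g in c("SSD", "HV")) {
    fs <- f[f$group == g, ]
    expect_equal(mean(fs$mean_S), cfg$hsv_means[[g]][["S"]], tolerance = 2)
    expect_equal(mean(fs$face_count), cfg$face_lambda[[g]], tolerance = 0.15)
    target_fol <- instaphen:::group_mean_sd(cfg, "follower_count", g)[["mean"]]
    expect_equal(mean(fs$follower_count), target_fol,
                 tolerance = 0.2 * target_fol)
  }
})
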