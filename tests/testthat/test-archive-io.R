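test_that("fixture archive round-trips through parse_archive", {
  root <- withr::local_tempdir()
  ts <- ts_seq("2018-03-01 10:00:00", by_days = 30, n = 6)
  write_fixture_archive(root, timestamps = ts)
  a <- parse_archive(root)
  expect_s3_class(a, "participant_archive")
  expect_equal(nrow(a$posts), 6L)
  expect_equal(a$connections$counts[["followers"]], 10L)
  expect_equal(a$connections$counts[["following"]], 5L)
  expect_equal(a$connections$counts[["blocked"]], 2L)
  expect_false(any(a$posts$missing_image))
  expect_equal(a$posts$timestamp, sort(ts))
  expect_equal(a$demographics$group, "HV")
})

test_that("a corrupt image is flagged missing, not fatal", {
  root <- withr::local_tempdir()
  ts <- ts_seq("2018-03-01 10:00:00", by_days = 30, n = 6)
  write_fixture_archive(root, timestamps = ts, corrupt = 3L)
  a <- parse_archive(root)
  expect_equal(nrow(a$posts), 6L)
  expect_equal(sum(a$posts$missing_image), 1L)
})

test_that("missing metadata and bad records raise informative errors", {
  root <- withr::local_tempdir()
  expect_error(parse_archive(root), "demographics.json")
  ts <- ts_seq("2018-03-01 10:00:00", by_days = 30, n = 3)
  write_fixture_archive(root, timestamps = ts)
  media <- jsonlite::read_json(file.path(root, "media.json"),
                               simplifyVector = TRUE)
  media$timestamp[2] <- "not-a-time"
  jsonlite::write_json(media, file.path(root, "media.json"), digits = NA)
  expect_error(parse_archive(root), "P001_p02")
  expect_error(parse_archive(root, dialect = "v2018"), "dialect")
})

test_that("inclusion filter applies post-count and span thresholds", {
  mk <- function(n, span_days) {
    root <- tempfile("arch")
    ts <- as.POSIXct("2019-01-01", tz = "UTC") +
      round(seq(0, span_days, length.out = n)) * 86400
    write_fixture_archive(root, timestamps = ts)
    parse_archive(root)
  }
  f <- inclusion_filter(mk(5, 120))
  expect_true(f$included)
  f <- inclusion_filter(mk(4, 400))
  expect_false(f$included)
  expect_match(f$reason, "post count")
  f <- inclusion_filter(mk(10, 89))
  expect_false(f$included)
  expect_match(f$reason, "span")
  empty <- list(posts = data.frame())
  f <- inclusion_filter(empty)
  expect_false(f$included)
  expect_equal(f$reason, "no posts")
})

test_that("inclusion is monotone in added posts and partitions a cohort", {
  root <- withr::local_tempdir()
  ts <- ts_seq("2019-01-01", by_days = 25, n = 5)  # 100-day span, included
  write_fixture_archive(root, timestamps = ts)
  a <- parse_archive(root)
  expect_true(inclusion_filter(a)$included)
  # appending any post can only increase count and span
  for (extra_days in c(-10, 5, 200)) {
    b <- a
    new_post <- b$posts[1, ]
    new_post$post_id <- "extra"
    new_post$timestamp <- min(b$posts$timestamp) + extra_days * 86400
    b$posts <- rbind(b$posts, new_post)
    expect_true(inclusion_filter(b)$included)
  }
  # partition: included + excluded = total over a generated cohort
  cfg <- cohort_config(n_per_group = 3, seed = 5,
                       posts_per_participant = c(5L, 8L),
                       months_span = c(2, 6))
  dir <- withr::local_tempdir()
  generate_cohort(cfg, dir, write_images = FALSE)
  roots <- list.dirs(dir, recursive = FALSE)
  res <- vapply(roots, function(r) inclusion_filter(parse_archive(r))$included,
                logical(1))
  expect_equal(sum(res) + sum(!res), length(roots))
})

test_that("usage months follow the 30.44-day month convention", {
  posts <- data.frame(timestamp = as.POSIXct("2019-01-01", tz = "UTC") +
                        c(0, 152.2) * 86400)
  expect_equal(usage_months(posts), 5, tolerance = 1e-10)
})
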