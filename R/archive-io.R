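#' Archive parsing and the inclusion filter
#'
#' One participant's data-export archive is a directory in the *canonical
#' dialect*:
#'
#' ```
#' <root>/
#'   demographics.json   participant_id, group, age, sex, race, ethnicity
#'   media.json          array of {post_id, timestamp, file, width, height}
#'   connections.json    member lists / counts for the seven connection types
#'   media/*.png         image files referenced by media.json
#'   ground_truth.json   optional sidecar manifest written by the synthetic
#'                       generator (per-post face counts, generative targets)
#' ```
#'
#' Timestamps are stored as local `"%Y-%m-%dT%H:%M:%S"` strings; parsing
#' resolves them in UTC and an optional fixed offset (hours) can be applied.
#' Real export dialects changed schema repeatedly; the canonical dialect is
#' the one documented layout shipped here, and `parse_archive()` dispatches on
#' the dialect name so adapters for other layouts can be registered.
#'
#' @name archive-io
NULL

CONNECTION_TYPES <- c("followers", "following", "requested",
                      "hashtag_follows", "blocked", "close_friends",
                      "restricted")

TIMESTAMP_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_timestamp <- function(x, tz_offset_hours = 0) {
  t <- as.POSIXct(x, format = TIMESTAMP_FMT, tz = "UTC")
  t + tz_offset_hours * 3600
}

format_timestamp <- function(t) format(t, TIMESTAMP_FMT, tz = "UTC")

png_signature_ok <- function(path) {
  if (!file.exists(path)) return(FALSE)
  sig <- readBin(path, "raw", n = 8L)
  length(sig) == 8L &&
    identical(sig, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
}

#' Parse a participant archive
#'
#' @param root archive directory.
#' @param dialect archive dialect name; only `"canonical"` is bundled.
#' @param tz_offset_hours fixed offset (hours) applied to recorded local
#'   timestamps.
#' @param age_window eligibility window in years for the demographic record.
#' @return a `participant_archive`: list with `demographics` (list), `posts`
#'   (data frame sorted ascending by timestamp, one row per image with
#'   `post_id`, `timestamp`, `image_path`, `width`, `height`,
#'   `missing_image`, `n_faces_truth`), and `connections` (see
#'   [connection_lists()]).
#' @export
parse_archive <- function(root, dialect = "canonical", tz_offset_hours = 0,
                          age_window = c(15, 35)) {
  if (!identical(dialect, "canonical")) {
    stop(sprintf("unknown archive dialect '%s'; only 'canonical' is bundled",
                 dialect))
  }
  for (f in c("demographics.json", "media.json", "connections.json")) {
    if (!file.exists(file.path(root, f))) {
      stop(sprintf("missing metadata document: %s", file.path(root, f)))
    }
  }
  demo <- jsonlite::read_json(file.path(root, "demographics.json"))
  if (is.null(demo$group) || !nzchar(demo$group)) {
    stop("demographics record has no group label")
  }
  if (!is.null(demo$age) &&
      (demo$age < age_window[1] || demo$age > age_window[2])) {
    stop(sprintf("participant %s: age %s outside eligibility window [%s, %s]",
                 demo$participant_id, demo$age, age_window[1], age_window[2]))
  }
  media <- jsonlite::read_json(file.path(root, "media.json"),
                               simplifyVector = TRUE)
  truth <- NULL
  tf <- file.path(root, "ground_truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)

  posts <- data.frame(post_id = character(), stringsAsFactors = FALSE)
  if (length(media) > 0L) {
    ts <- parse_timestamp(media$timestamp, tz_offset_hours)
    if (anyNA(ts)) {
      bad <- media$post_id[is.na(ts)]
      stop(sprintf("unparseable timestamp for post(s): %s",
                   paste(bad, collapse = ", ")))
    }
    posts <- data.frame(
      post_id = as.character(media$post_id),
      timestamp = ts,
      image_path = file.path(root, media$file),
      width = as.integer(media$width),
      height = as.integer(media$height),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(posts$post_id)) stop("duplicate post_id in media.json")
    if (any(posts$width < 1L | posts$height < 1L)) {
      stop("post with non-positive width or height")
    }
    posts$missing_image <- !vapply(posts$image_path, png_signature_ok,
                                   logical(1))
    posts$n_faces_truth <- NA_integer_
    if (!is.null(truth$posts)) {
      idx <- match(posts$post_id, truth$posts$post_id)
      posts$n_faces_truth <- as.integer(truth$posts$n_faces[idx])
    }
    posts <- posts[order(posts$timestamp, posts$post_id), , drop = FALSE]
    rownames(posts) <- NULL
  }

  conn_raw <- jsonlite::read_json(file.path(root, "connections.json"),
                                  simplifyVector = TRUE)
  conn <- connection_lists(conn_raw)

  structure(
    list(demographics = demo, posts = posts, connections = conn,
         truth = truth, root = normalizePath(root), dialect = dialect),
    class = "participant_archive"
  )
}

#' Build a connection-lists object
#'
#' Each of the seven connection types may be given as a member vector (count
#' is its length) or as a bare non-negative count.
#'
#' @param x named list with entries among `followers`, `following`,
#'   `requested`, `hashtag_follows`, `blocked`, `close_friends`,
#'   `restricted`.
#' @return list with `counts` (named integer vector over all seven types) and
#'   `members` (named list of member vectors, possibly empty).
#' @export
connection_lists <- function(x = list()) {
  counts <- setNames(integer(length(CONNECTION_TYPES)), CONNECTION_TYPES)
  members <- setNames(vector("list", length(CONNECTION_TYPES)),
                      CONNECTION_TYPES)
  for (ty in CONNECTION_TYPES) {
    v <- x[[ty]]
    if (is.null(v)) next
    if (is.character(v)) {
      members[[ty]] <- v
      counts[[ty]] <- length(v)
    } else {
      if (length(v) != 1L || is.na(v) || v < 0) {
        stop(sprintf("invalid count for connection type '%s'", ty))
      }
      counts[[ty]] <- as.integer(v)
    }
  }
  list(counts = counts, members = members)
}

#' @export
print.participant_archive <- function(x, ...) {
  cat(sprintf("<participant_archive> %s [%s]: %d posts, %d followers / %d following\n",
              x$demographics$participant_id %||% "?",
              x$demographics$group %||% "?",
              nrow(x$posts),
              x$connections$counts[["followers"]],
              x$connections$counts[["following"]]))
  invisible(x)
}

#' Write archive metadata in the canonical dialect
#'
#' Writes `demographics.json`, `media.json`, `connections.json` and (when
#' `truth` is given) `ground_truth.json` under `root`. Image files are the
#' caller's responsibility; `posts$file` names them relative to `root`.
#'
#' @param root target directory (created if absent).
#' @param demographics named list.
#' @param posts data frame with `post_id`, `timestamp` (POSIXct), `file`,
#'   `width`, `height`.
#' @param connections a [connection_lists()] object.
#' @param truth optional ground-truth manifest (list).
#' @return `root`, invisibly.
#' @export
write_archive_metadata <- function(root, demographics, posts, connections,
                                   truth = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(root, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wj(demographics, "demographics.json")
  media <- data.frame(
    post_id = posts$post_id,
    timestamp = format_timestamp(posts$timestamp),
    file = posts$file,
    width = posts$width,
    height = posts$height,
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(media, file.path(root, "media.json"), digits = NA,
                       pretty = TRUE)
  conn <- list()
  for (ty in CONNECTION_TYPES) {
    if (!is.null(connections$members[[ty]]) &&
        length(connections$members[[ty]]) == connections$counts[[ty]] &&
        connections$counts[[ty]] > 0L) {
      conn[[ty]] <- connections$members[[ty]]
    } else {
      conn[[ty]] <- connections$counts[[ty]]
    }
  }
  wj(conn, "connections.json")
  if (!is.null(truth)) wj(truth, "ground_truth.json")
  invisible(root)
}

#' Study inclusion filter
#'
#' A participant is included when the archive holds at least `min_posts`
#' posts and the span between the first and last post is at least
#' `min_span_days` days ("at least 5 posts over at least 3 months",
#' operationalized as 90 days since calendar-month arithmetic is ambiguous).
#'
#' @param archive a `participant_archive`.
#' @param min_posts minimum number of posts.
#' @param min_span_days minimum first-to-last post span in days.
#' @return list with `included` (logical) and `reason` (`"ok"`, `"no posts"`,
#'   `"post count below minimum"`, `"posting span below minimum"`).
#' @export
inclusion_filter <- function(archive, min_posts = 5, min_span_days = 90) {
  posts <- archive$posts
  if (nrow(posts) == 0L) {
    return(list(included = FALSE, reason = "no posts"))
  }
  if (nrow(posts) < min_posts) {
    return(list(included = FALSE, reason = "post count below minimum"))
  }
  span <- as.numeric(difftime(max(posts$timestamp), min(posts$timestamp),
                              units = "days"))
  if (span < min_span_days) {
    return(list(included = FALSE, reason = "posting span below minimum"))
  }
  list(included = TRUE, reason = "ok")
}

#' Posting span of an archive in months
#'
#' Months are the span in days divided by 30.44 (mean calendar-month length).
#'
#' @param posts posts data frame (or a `participant_archive`).
#' @return usage duration in months (0 for fewer than 2 posts).
#' @export
usage_months <- function(posts) {
  if (inherits(posts, "participant_archive")) posts <- posts$posts
  if (nrow(posts) < 2L) return(0)
  as.numeric(difftime(max(posts$timestamp), min(posts$timestamp),
                      units = "days")) / DAYS_PER_MONTH
}
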