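#' Face counting
#'
#' Two detectors are provided behind one interface: a template-matching
#' detector that scans the image's V (brightness) channel with a normalized
#' cross-correlation against the bundled synthetic frontal-face luminance
#' template, and a ground-truth stub that reads the face count embedded in a
#' synthetic archive's manifest. The template detector is deterministic for a
#' fixed image and parameter set; the stub makes pipeline tests exact.
#'
#' @name face-detection
NULL

#' The bundled synthetic frontal-face template
#'
#' A deterministic luminance pattern (oval face, two eye patches, mouth bar)
#' used both by the synthetic image generator, which composites it into
#' images, and by the template detector, which correlates against it. Values
#' lie in `[0, 1]`.
#'
#' @param size side length in pixels (default 16).
#' @return `size x size` numeric matrix in `[0, 1]`.
#' @export
face_template <- function(size = 16L) {
  size <- as.integer(size)
  stopifnot(size >= 8L)
  cx <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), size), size, size)            # row (y)
  ys <- t(xs)                                                   # col (x)
  tmpl <- matrix(0.25, size, size)
  # face oval
  inside <- ((xs - cx) / (0.46 * size))^2 + ((ys - cx) / (0.36 * size))^2 <= 1
  tmpl[inside] <- 0.78
  # eyes
  eye_y <- cx - 0.18 * size
  for (ex in c(cx - 0.17 * size, cx + 0.17 * size)) {
    eye <- (xs - eye_y)^2 + (ys - ex)^2 <= (0.08 * size)^2
    tmpl[eye & inside] <- 0.15
  }
  # mouth bar
  mouth <- abs(xs - (cx + 0.22 * size)) <= 0.05 * size &
    abs(ys - cx) <= 0.16 * size
  tmpl[mouth & inside] <- 0.2
  tmpl
}

#' Construct a face detector
#'
#' @param type `"template"` for normalized cross-correlation template
#'   matching on the V channel, or `"stub"` for the ground-truth stub that
#'   returns the embedded synthetic face count.
#' @param threshold correlation threshold for an accepted detection
#'   (template detector).
#' @param template luminance template matrix in `[0, 1]`.
#' @return a `face_detector` object for [count_faces()].
#' @export
face_detector <- function(type = c("template", "stub"), threshold = 0.8,
                          template = face_template()) {
  type <- match.arg(type)
  structure(list(type = type, threshold = threshold, template = template),
            class = "face_detector")
}

#' Count faces in an image
#'
#' @param img image array (see [as_image()]); ignored by the stub detector.
#' @param detector a [face_detector()].
#' @param truth embedded ground-truth count (stub detector only).
#' @return non-negative integer face count.
#' @export
count_faces <- function(img, detector = face_detector("stub"), truth = NA) {
  if (!inherits(detector, "face_detector")) {
    stop("`detector` must be created with face_detector()")
  }
  if (detector$type == "stub") {
    if (is.null(truth) || is.na(truth)) {
      stop("stub detector requires an embedded ground-truth face count")
    }
    return(as.integer(truth))
  }
  v <- image_hsv(img)$V / 255
  nrow(detect_template(v, detector$template, detector$threshold))
}

# Normalized cross-correlation scan with greedy non-maximum suppression.
# Returns a data frame of accepted detections (row, col of top-left corner,
# score), ordered by decreasing score. Windows with zero variance score 0.
detect_template <- function(v, tmpl, threshold = 0.8) {
  m <- nrow(tmpl); n <- ncol(tmpl)
  t0 <- tmpl - mean(tmpl)
  st <- sqrt(sum(t0^2))
  stopifnot(st > 0)
  H <- nrow(v); W <- ncol(v)
  empty <- data.frame(row = integer(), col = integer(), score = numeric())
  if (H < m || W < n) return(empty)
  nr <- H - m + 1L; nc <- W - n + 1L
  scores <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      w <- v[i:(i + m - 1L), j:(j + n - 1L)]
      w0 <- w - mean(w)
      sw <- sqrt(sum(w0^2))
      if (sw > 0) scores[i, j] <- sum(w0 * t0) / (sw * st)
    }
  }
  cand <- which(scores >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  sc <- scores[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  acc <- empty
  for (k in seq_len(nrow(cand))) {
    ri <- cand[k, 1]; ci <- cand[k, 2]
    if (nrow(acc) == 0L ||
        all(abs(acc$row - ri) >= 0.75 * m | abs(acc$col - ci) >= 0.75 * n)) {
      acc <- rbind(acc, data.frame(row = ri, col = ci, score = sc[k]))
    }
  }
  acc
}
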