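#' Empty object-label table
#'
#' Landmark-as-object labels are plain data frames with columns
#' `class_id` (integer 0-9 in [landet_classes()] order), normalised box
#' centre `bx`, `by` and size `bw`, `bh`. All coordinates are normalised by
#' the **maximum** image dimension, so values lie in `[0, 1]` on the long
#' axis and `[0, short/long]` on the short axis. Detections carry an
#' additional `confidence` column.
#'
#' @param confidence Include a `confidence` column.
#' @return A zero-row data frame with the label schema.
#' @export
empty_labels <- function(confidence = FALSE) {
  d <- data.frame(class_id = integer(), bx = numeric(), by = numeric(),
                  bw = numeric(), bh = numeric())
  if (confidence) d$confidence <- numeric()
  d
}

#' Build object labels from a landmark set
#'
#' Converts each landmark into a small square bounding-box object centred
#' on it. Spine-landmark boxes have side `spine_frac` (default 5%) of the
#' maximum image dimension; femoral-head boxes have side equal to the
#' fitted head diameter. All coordinates are then normalised by the
#' maximum image dimension.
#'
#' @param lm A [landmark_set()] with femoral-head radii.
#' @param image_w,image_h Image size in pixels.
#' @param spine_frac Spine box side as a fraction of `max(image_w, image_h)`.
#' @param strict Error (instead of clamp + warn) when a landmark centre
#'   falls outside the image.
#' @return Label data frame (one row per present landmark, sorted by
#'   `class_id`).
#' @export
boxes_from_landmarks <- function(lm, image_w, image_h, spine_frac = 0.05,
                                 strict = FALSE) {
  stopifnot(inherits(lm, "landmark_set"))
  S <- max(image_w, image_h)
  cls <- landet_classes()
  rows <- list()
  for (i in seq_along(cls)) {
    p <- lm$points[cls[i], ]
    if (anyNA(p)) next
    side <- if (i <= 2) {
      r <- lm$fh_radius[i]
      if (is.na(r)) stop("femoral-head radius missing for ", cls[i])
      2 * r
    } else spine_frac * S
    x <- p[1]; y <- p[2]
    if (x < 0 || x > image_w || y < 0 || y > image_h) {
      if (strict) stop("landmark ", cls[i], " outside the image")
      warning("landmark ", cls[i], " outside the image; centre clamped")
      x <- min(max(x, 0), image_w); y <- min(max(y, 0), image_h)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = i - 1L, bx = x / S, by = y / S, bw = side / S, bh = side / S)
  }
  if (!length(rows)) return(empty_labels())
  out <- do.call(rbind, rows)
  out[order(out$class_id), , drop = FALSE]
}

#' Read / write object labels as one-object-per-line text
#'
#' The label dialect is `class bx by bw bh` (plus a sixth `confidence`
#' field for detections), space-separated, six-decimal fixed precision,
#' one object per line, lines sorted by class id on write. This is the
#' dominant plain-text convention for detection labels, so external
#' tooling can read the fixtures directly.
#'
#' @param path File path.
#' @param confidence Expect/write the sixth confidence field.
#' @return `read_labels` returns a label data frame; `write_labels`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path, confidence = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nfield <- if (confidence) 6L else 5L
  if (!length(lines)) return(empty_labels(confidence))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) != nfield)
      stop(sprintf("label parse error at line %d: expected %d fields, got %d",
                   i, nfield, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("label parse error at line %d: non-numeric field", i))
    if (v[1] != floor(v[1]) || v[1] < 0 || v[1] > 9)
      stop(sprintf("label parse error at line %d: class id %s outside 0-9",
                   i, f[1]))
    v
  })
  m <- do.call(rbind, rows)
  out <- data.frame(class_id = as.integer(m[, 1]), bx = m[, 2], by = m[, 3],
                    bw = m[, 4], bh = m[, 5])
  if (confidence) out$confidence <- m[, 6]
  out
}

#' @rdname read_labels
#' @param labels Label data frame.
#' @export
write_labels <- function(labels, path, confidence = FALSE) {
  labels <- labels[order(labels$class_id), , drop = FALSE]
  fmt <- if (confidence) "%d %.6f %.6f %.6f %.6f %.6f" else
    "%d %.6f %.6f %.6f %.6f"
  lines <- if (nrow(labels)) {
    if (confidence)
      sprintf(fmt, labels$class_id, labels$bx, labels$by, labels$bw,
              labels$bh, labels$confidence)
    else
      sprintf(fmt, labels$class_id, labels$bx, labels$by, labels$bw,
              labels$bh)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Reduce detections to a landmark set
#'
#' For each of the ten landmark classes, the centre of the
#' highest-confidence detection becomes that landmark (denormalised back to
#' pixels); femoral-head radii are recovered from the box width. Classes
#' with no detection are reported missing rather than raising an error, so
#' downstream measures fail only per-measure.
#'
#' @param dets Detection data frame (see [empty_labels()]).
#' @param image_w,image_h Image size in pixels.
#' @return List with `landmarks` (a [landmark_set()], `NA` rows for missing
#'   classes) and `report` (data frame: class_id, name, confidence,
#'   detected).
#' @export
select_landmarks <- function(dets, image_w, image_h) {
  S <- max(image_w, image_h)
  cls <- landet_classes()
  pts <- matrix(NA_real_, 10, 2, dimnames = list(cls, c("x", "y")))
  rad <- c(NA_real_, NA_real_)
  conf <- rep(NA_real_, 10)
  if (is.null(dets$confidence)) dets$confidence <- 1
  for (i in 0:9) {
    sub <- dets[dets$class_id == i, , drop = FALSE]
    if (!nrow(sub)) next
    best <- sub[which.max(sub$confidence), ]
    pts[i + 1L, ] <- c(best$bx * S, best$by * S)
    conf[i + 1L] <- best$confidence
    if (i < 2) rad[i + 1L] <- best$bw * S / 2
  }
  lm <- landmark_set(pts, rad)
  list(landmarks = lm,
       report = data.frame(class_id = 0:9, name = cls, confidence = conf,
                           detected = !is.na(conf)))
}
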