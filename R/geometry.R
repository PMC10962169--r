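#' @useDynLib landet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor pt qnorm
#' @importFrom utils read.csv write.csv head
NULL

#' Landmark class names in canonical order
#'
#' The ten anatomical landmark classes used throughout the package, in the
#' fixed class-index order (index 0 to 9): the two femoral-head centres
#' (disambiguated by x-order, smaller x first), the posterior/anterior
#' corners of the S1 superior endplate, the L5 inferior endplate, the L1
#' superior endplate, and the C7 superior endplate.
#'
#' @return Character vector of length 10.
#' @export
landet_classes <- function() {
  c("fh1", "fh2", "s1_post", "s1_ant", "l5_post", "l5_ant",
    "l1_post", "l1_ant", "c7_post", "c7_ant")
}

#' Construct a landmark set
#'
#' A landmark set holds the 2-D pixel coordinates of the ten anatomical
#' landmarks on a lateral radiograph (image coordinates: origin top-left,
#' x rightward, y downward, so "superior" means smaller y), together with
#' the two femoral-head radii and the facing direction of the patient.
#'
#' @param points Numeric 10 x 2 matrix of (x, y) pixel coordinates with rows
#'   in [landet_classes()] order (row names optional; if present they are
#'   checked). Rows may be `NA` for missing landmarks.
#' @param fh_radius Numeric length-2 vector of femoral-head radii in pixels.
#' @param facing `+1` when the patient's anterior side is towards +x,
#'   `-1` otherwise. Defaults to the sign of `s1_ant.x - s1_post.x`.
#' @return Object of class `"landmark_set"`.
#' @export
landmark_set <- function(points, fh_radius = c(NA_real_, NA_real_),
                         facing = NULL) {
  cls <- landet_classes()
  points <- as.matrix(points)
  if (nrow(points) != 10L || ncol(points) != 2L)
    stop("`points` must be a 10 x 2 matrix in landet_classes() order")
  if (!is.null(rownames(points)) && !identical(rownames(points), cls))
    points <- points[cls, , drop = FALSE]
  rownames(points) <- cls
  colnames(points) <- c("x", "y")
  fh_radius <- as.numeric(fh_radius)
  if (length(fh_radius) != 2L) stop("`fh_radius` must have length 2")
  if (any(!is.na(fh_radius) & fh_radius <= 0))
    stop("femoral-head radii must be positive")
  if (is.null(facing)) {
    dx <- points["s1_ant", "x"] - points["s1_post", "x"]
    facing <- if (is.na(dx) || dx == 0) 1 else sign(dx)
  }
  if (!facing %in% c(-1, 1)) stop("`facing` must be +1 or -1")
  structure(list(points = points, fh_radius = fh_radius,
                 facing = as.numeric(facing)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set (10 classes, image coordinates, y down)\n")
  cat(sprintf("  facing: %+d (anterior towards %s)\n", as.integer(x$facing),
              if (x$facing > 0) "+x" else "-x"))
  cat(sprintf("  femoral-head radii: %.2f, %.2f px\n",
              x$fh_radius[1], x$fh_radius[2]))
  print(round(x$points, 2))
  invisible(x)
}

lm_point <- function(lm, name) {
  p <- lm$points[name, ]
  if (anyNA(p)) NULL else as.numeric(p)
}

#' Circumscribed circle through three points
#'
#' Recovers the centre and radius of the circle through three non-collinear
#' points. Used to turn three clicked points on a femoral-head rim into the
#' head centre and radius.
#'
#' @param p1,p2,p3 Numeric (x, y) points.
#' @param tol Collinearity tolerance on twice the triangle area (pixels^2).
#' @return List with `center` (numeric xy) and `radius`.
#' @export
circumcircle <- function(p1, p2, p3, tol = 1e-9) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < tol * max(1, abs(ax), abs(ay), abs(bx), abs(by)))
    stop("circumcircle: points are (nearly) collinear")
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Hip axis (centre of pelvic rotation)
#'
#' Midpoint of the two projected femoral-head centres on the lateral view.
#'
#' @param fh1,fh2 Numeric (x, y) femoral-head centres.
#' @return Numeric (x, y) midpoint.
#' @export
hip_axis <- function(fh1, fh2) (fh1 + fh2) / 2

#' Signed inclination of an endplate line
#'
#' Angle of the posterior-to-anterior endplate line above/below the
#' horizontal, computed in the facing-corrected (anterior, superior) frame.
#' Positive when the endplate descends anteriorly (the anterior point is
#' inferior, i.e. larger y), which is the orientation of the sacral
#' endplate in normal sagittal anatomy and the polarity under which
#' pelvic incidence equals pelvic tilt plus sacral slope as a signed
#' identity. Result is normalised to (-90, 90] degrees.
#'
#' @param post,ant Numeric (x, y) posterior and anterior endplate corners.
#' @param facing +1 or -1, see [landmark_set()].
#' @return Angle in degrees.
#' @export
signed_inclination <- function(post, ant, facing = 1) {
  dx <- unname(facing * (ant[1] - post[1]))
  dy <- unname(ant[2] - post[2])  # y grows downward: positive = ant inferior
  if (dx == 0 && dy == 0) stop("signed_inclination: coincident points")
  a <- atan2(dy, dx) * 180 / pi
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' Sacral slope (SS)
#'
#' Angle between the S1 superior endplate line and the horizontal.
#'
#' @param lm A [landmark_set()].
#' @return Degrees, or `NA` if an S1 corner is missing.
#' @export
sacral_slope <- function(lm) {
  p <- lm_point(lm, "s1_post"); a <- lm_point(lm, "s1_ant")
  if (is.null(p) || is.null(a)) return(NA_real_)
  signed_inclination(p, a, lm$facing)
}

#' Pelvic tilt (PT)
#'
#' Signed angle at the hip axis between the vertical and the line to the S1
#' superior-endplate midpoint; positive when the S1 midpoint lies posterior
#' to the hip axis (the normal standing posture).
#'
#' @param lm A [landmark_set()].
#' @return Degrees, or `NA` when femoral heads or S1 corners are missing.
#' @export
pelvic_tilt <- function(lm) {
  g <- pelvis_frame(lm)
  if (is.null(g)) return(NA_real_)
  g$pt
}

# Shared pelvic construction: hip axis H, S1 midpoint M, PT and the
# endplate-normal angle. Returns NULL when a required landmark is missing.
pelvis_frame <- function(lm) {
  fh1 <- lm_point(lm, "fh1"); fh2 <- lm_point(lm, "fh2")
  sp <- lm_point(lm, "s1_post"); sa <- lm_point(lm, "s1_ant")
  if (is.null(fh1) || is.null(fh2) || is.null(sp) || is.null(sa)) return(NULL)
  H <- hip_axis(fh1, fh2)
  M <- (sp + sa) / 2
  v <- H - M                      # S1 midpoint -> hip axis
  if (all(v == 0)) stop("pelvic geometry degenerate: S1 midpoint at hip axis")
  f <- lm$facing
  # angle of M->H from the straight-down vertical, anterior positive
  a_mh <- atan2(f * v[1], v[2]) * 180 / pi
  e <- sa - sp                    # endplate direction, posterior -> anterior
  if (all(e == 0)) stop("pelvic geometry degenerate: S1 endplate collapsed")
  # endplate perpendicular oriented to the inferior side of the plate (the
  # hip-axis side in physiologic posture); its signed angle from vertical
  # is minus the endplate inclination, which makes PI = PT + SS an exact
  # signed identity for any landmark configuration
  a_n <- -signed_inclination(sp, sa, f)
  list(H = H, M = M, pt = a_mh, a_n = a_n)
}

#' Pelvic incidence (PI)
#'
#' Angle between the perpendicular to the S1 superior endplate at its
#' midpoint (oriented to the inferior side of the plate, towards the hip
#' axis in physiologic posture) and the line from that midpoint to the hip
#' axis, both measured as signed angles from the vertical in the
#' facing-corrected frame. A morphologic constant of the pelvis: under the
#' package's signed conventions it satisfies `PI = PT + SS` exactly.
#'
#' @param lm A [landmark_set()].
#' @return Degrees (signed; positive in normal anatomy), `NA` if landmarks
#'   are missing.
#' @export
pelvic_incidence <- function(lm) {
  g <- pelvis_frame(lm)
  if (is.null(g)) return(NA_real_)
  a <- g$pt - g$a_n
  if (a > 180) a <- a - 360
  if (a <= -180) a <- a + 360
  a
}

#' Lumbar lordosis (LL)
#'
#' Angle between the L5 inferior endplate line and the L1 superior endplate
#' line, as the absolute difference of their signed inclinations, in
#' [0, 180).
#'
#' @param lm A [landmark_set()].
#' @return Degrees, or `NA` when a corner is missing.
#' @export
lumbar_lordosis <- function(lm) {
  l5p <- lm_point(lm, "l5_post"); l5a <- lm_point(lm, "l5_ant")
  l1p <- lm_point(lm, "l1_post"); l1a <- lm_point(lm, "l1_ant")
  if (is.null(l5p) || is.null(l5a) || is.null(l1p) || is.null(l1a))
    return(NA_real_)
  a <- abs(signed_inclination(l1p, l1a, lm$facing) -
             signed_inclination(l5p, l5a, lm$facing))
  if (a >= 180) a <- a - 180
  a
}

#' Sagittal vertical axis (SVA)
#'
#' Horizontal offset between the C7 vertebral midpoint (midpoint of the C7
#' superior-endplate corners) and the posterior-superior corner of S1.
#' Reported in pixels, or in millimetres when a calibration is given. The
#' signed variant is positive when C7 lies anterior to the S1 corner.
#'
#' @param lm A [landmark_set()].
#' @param mm_per_pixel Optional calibration (> 0), mm per pixel.
#' @return List with `sva` (magnitude) and `sva_signed`, or `NA`s.
#' @export
sagittal_vertical_axis <- function(lm, mm_per_pixel = NULL) {
  cp <- lm_point(lm, "c7_post"); ca <- lm_point(lm, "c7_ant")
  sp <- lm_point(lm, "s1_post")
  if (is.null(cp) || is.null(ca) || is.null(sp))
    return(list(sva = NA_real_, sva_signed = NA_real_))
  scale <- 1
  if (!is.null(mm_per_pixel)) {
    if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0)
      stop("`mm_per_pixel` must be a positive number")
    scale <- mm_per_pixel
  }
  c7m <- (cp + ca) / 2
  s <- lm$facing * (c7m[1] - sp[1]) * scale
  list(sva = abs(s), sva_signed = s)
}

#' Compute all five spinopelvic measures
#'
#' Aggregates sacral slope, pelvic tilt, pelvic incidence, lumbar lordosis
#' and sagittal vertical axis from a landmark set. Measures whose landmarks
#' are missing are returned as `NA` (or, with `strict = TRUE`, raise an
#' error naming the first absent landmark class). When all pelvic landmarks
#' are present the signed identity `PI = PT + SS` is checked and a warning
#' is issued if it is violated beyond `angle_tol` (this flags internally
#' inconsistent landmark configurations, e.g. noisy predictions).
#'
#' @param lm A [landmark_set()].
#' @param mm_per_pixel Optional calibration for SVA, mm per pixel.
#' @param strict Error on missing landmarks instead of returning `NA`.
#' @param angle_tol Tolerance (degrees) for the PI identity warning.
#' @return Object of class `"spinopelvic_measures"`: a list with `ss_deg`,
#'   `pt_deg`, `pi_deg`, `ll_deg`, `sva`, `sva_signed`, `units`.
#' @export
compute_measures <- function(lm, mm_per_pixel = NULL, strict = FALSE,
                             angle_tol = 0.5) {
  stopifnot(inherits(lm, "landmark_set"))
  if (strict) {
    missing <- landet_classes()[apply(is.na(lm$points), 1, any)]
    if (length(missing))
      stop("missing landmark(s): ", paste(missing, collapse = ", "))
  }
  ss <- sacral_slope(lm)
  ptilt <- pelvic_tilt(lm)
  pinc <- pelvic_incidence(lm)
  ll <- lumbar_lordosis(lm)
  sva <- sagittal_vertical_axis(lm, mm_per_pixel)
  if (!is.na(pinc) && !is.na(ptilt) && !is.na(ss) &&
      abs(pinc - (ptilt + ss)) > angle_tol)
    warning(sprintf(
      "PI deviates from PT + SS by %.3f deg (inconsistent landmarks?)",
      pinc - (ptilt + ss)))
  structure(list(ss_deg = ss, pt_deg = ptilt, pi_deg = pinc, ll_deg = ll,
                 sva = sva$sva, sva_signed = sva$sva_signed,
                 units = if (is.null(mm_per_pixel)) "px" else "mm"),
            class = "spinopelvic_measures")
}

#' @export
print.spinopelvic_measures <- function(x, ...) {
  cat("Spinopelvic measures\n")
  cat(sprintf("  SS  %7.2f deg\n", x$ss_deg))
  cat(sprintf("  PT  %7.2f deg\n", x$pt_deg))
  cat(sprintf("  PI  %7.2f deg\n", x$pi_deg))
  cat(sprintf("  LL  %7.2f deg\n", x$ll_deg))
  cat(sprintf("  SVA %7.2f %s (signed %+.2f)\n", x$sva, x$units,
              x$sva_signed))
  invisible(x)
}

#' @export
as.data.frame.spinopelvic_measures <- function(x, ...) {
  data.frame(ss_deg = x$ss_deg, pt_deg = x$pt_deg, pi_deg = x$pi_deg,
             ll_deg = x$ll_deg, sva = x$sva, sva_signed = x$sva_signed,
             units = x$units, stringsAsFactors = FALSE)
}

#' Read / write a landmark set as CSV
#'
#' One row per landmark with columns `name,x,y,radius` (radius filled for
#' the femoral heads, empty otherwise), UTF-8, rows in class order.
#'
#' @param path File path.
#' @return `read_landmarks` returns a [landmark_set()];
#'   `write_landmarks` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns name,x,y(,radius)")
  cls <- landet_classes()
  pts <- matrix(NA_real_, 10, 2, dimnames = list(cls, c("x", "y")))
  idx <- match(d$name, cls)
  if (anyNA(idx)) stop("unknown landmark name(s): ",
                       paste(d$name[is.na(idx)], collapse = ", "))
  pts[idx, 1] <- d$x; pts[idx, 2] <- d$y
  rad <- c(NA_real_, NA_real_)
  if ("radius" %in% names(d)) {
    r <- suppressWarnings(as.numeric(d$radius))
    rad <- c(r[match("fh1", d$name)], r[match("fh2", d$name)])
  }
  landmark_set(pts, rad)
}

#' @rdname read_landmarks
#' @param lm A [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  d <- data.frame(name = landet_classes(),
                  x = lm$points[, "x"], y = lm$points[, "y"],
                  radius = c(lm$fh_radius, rep(NA_real_, 8)),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

# Rigid/affine helpers used by augmentation and the invariance tests.
transform_landmarks <- function(lm, fun, facing = lm$facing,
                                radius_scale = 1) {
  pts <- lm$points
  ok <- !apply(is.na(pts), 1, any)
  pts[ok, ] <- t(apply(pts[ok, , drop = FALSE], 1, fun))
  landmark_set(pts, lm$fh_radius * radius_scale, facing)
}

#' Mirror a landmark set horizontally
#'
#' Reflects all landmarks about the vertical image midline and flips the
#' facing sign, so all five measures are unchanged. Femoral heads are
#' re-ordered to keep the smaller-x-first convention.
#'
#' @param lm A [landmark_set()].
#' @param image_w Image width in pixels.
#' @return A mirrored [landmark_set()].
#' @export
mirror_landmarks <- function(lm, image_w) {
  out <- transform_landmarks(lm, function(p) c(image_w - p[1], p[2]),
                             facing = -lm$facing)
  if (!anyNA(out$points[c("fh1", "fh2"), "x"]) &&
      out$points["fh1", "x"] > out$points["fh2", "x"]) {
    out$points[c("fh1", "fh2"), ] <- out$points[c("fh2", "fh1"), ]
    out$fh_radius <- out$fh_radius[c(2, 1)]
  }
  out
}
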