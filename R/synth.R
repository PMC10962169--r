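#' Named anatomy populations
#'
#' Population distributions of the five spinopelvic measures used by the
#' synthetic generator. Two named populations are provided, matching the
#' ground-truth means and standard deviations of the two clinical cohorts
#' the method was developed on: `"ds1"` (ordinary X-ray device cohort:
#' SS 38.9 (10.3) deg, PT 19.3 (9.4) deg, LL 46.2 (16.2) deg, SVA
#' 34.9 (3.2) px) and `"ds2"` (biplanar slot-scanner cohort: SS 30.5
#' (10.4), PT 22.1 (19.5), LL 37.1 (17.8), SVA 29.8 (2.1)). Pelvic
#' incidence is never sampled: it is the derived identity `PI = PT + SS`.
#' Sampling is truncated-normal at broad physiologic bounds
#' (SS in [5, 70], PT in [-10, 50], LL in [0, 90], SVA in [-50, 150]).
#'
#' @param population `"ds1"`, `"ds2"`, or a list with numeric length-4
#'   vectors `mean` and `sd` named `ss`, `pt`, `ll`, `sva`.
#' @return List with `mean`, `sd`, `lower`, `upper` (each named length-4).
#' @export
landet_population <- function(population = "ds1") {
  lower <- c(ss = 5, pt = -10, ll = 0, sva = -50)
  upper <- c(ss = 70, pt = 50, ll = 90, sva = 150)
  if (is.character(population)) {
    pop <- switch(tolower(population),
      ds1 = list(mean = c(ss = 38.9, pt = 19.3, ll = 46.2, sva = 34.9),
                 sd   = c(ss = 10.3, pt = 9.4,  ll = 16.2, sva = 3.2)),
      ds2 = list(mean = c(ss = 30.5, pt = 22.1, ll = 37.1, sva = 29.8),
                 sd   = c(ss = 10.4, pt = 19.5, ll = 17.8, sva = 2.1)),
      stop("unknown population '", population, "' (use ds1, ds2 or custom)"))
  } else if (is.list(population) && all(c("mean", "sd") %in%
                                        names(population))) {
    pop <- list(mean = population$mean[c("ss", "pt", "ll", "sva")],
                sd = population$sd[c("ss", "pt", "ll", "sva")])
    if (anyNA(pop$mean) || anyNA(pop$sd) || any(pop$sd < 0))
      stop("invalid custom population spec")
  } else stop("invalid population spec")
  c(pop, list(lower = lower, upper = upper))
}

# Truncated-normal draw by inverse-CDF; exact and vectorised. With sd = 0
# every draw equals the mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample anatomy parameters
#'
#' Draws generative parameter vectors (one per row) from a population of
#' spinopelvic measures plus mild proportional jitter on the skeletal
#' dimensions. All lengths are in pixels of the target canvas; skeletal
#' dimensions scale with the canvas so the same population can be rendered
#' at any resolution.
#'
#' @param n Number of anatomies.
#' @param population See [landet_population()].
#' @param image_size Canvas `c(width, height)` in pixels.
#' @param jitter Relative jitter (uniform, +/-) on skeletal dimensions and
#'   the hip-axis anchor; 0 gives the deterministic archetype.
#' @return Data frame of class `"anatomy_params"`, one row per anatomy:
#'   `ss_deg, pt_deg, ll_deg, sva_px, pelvic_radius_px, s1_width_px,
#'   vertebra_width_px, fh_radius_px, fh_separation_px, anchor_x, anchor_y,
#'   facing, image_w, image_h` (and derived `pi_deg = pt_deg + ss_deg`).
#' @export
sample_anatomy <- function(n = 1, population = "ds1",
                           image_size = c(128, 128), jitter = 0.05) {
  pop <- landet_population(population)
  w <- image_size[1]; h <- image_size[2]; S <- max(w, h)
  draw <- function(k) rtruncnorm(n, pop$mean[[k]], pop$sd[[k]],
                                 pop$lower[[k]], pop$upper[[k]])
  jit <- function(base) base * stats::runif(n, 1 - jitter, 1 + jitter)
  d <- data.frame(
    ss_deg = draw("ss"), pt_deg = draw("pt"), ll_deg = draw("ll"),
    sva_px = draw("sva") * S / 128,
    pelvic_radius_px = jit(0.17 * S),
    s1_width_px = jit(0.16 * S),
    vertebra_width_px = jit(0.14 * S),
    fh_radius_px = jit(0.055 * S),
    fh_separation_px = jit(0.07 * S),
    anchor_x = 0.42 * w + stats::runif(n, -jitter, jitter) * w,
    anchor_y = 0.76 * h + stats::runif(n, -jitter, jitter) * h,
    facing = rep(1, n),
    image_w = rep(w, n), image_h = rep(h, n))
  d$pi_deg <- d$pt_deg + d$ss_deg
  class(d) <- c("anatomy_params", "data.frame")
  d
}

deg2rad <- function(a) a * pi / 180

#' Construct exact landmarks from anatomy parameters
#'
#' The constructive inverse of the measure definitions: places the hip
#' axis at the configured anchor, splits the femoral heads symmetrically
#' about it, puts the S1 endplate midpoint at the pelvic radius along the
#' direction tilted `pt_deg` posterior of vertical, tilts the S1 endplate
#' by `ss_deg`, stacks the L5 inferior and L1 superior endplates along a
#' smooth lumbar arc whose inclinations differ by `ll_deg`, and positions
#' the C7 endplate midpoint so the signed SVA equals `sva_px`. By
#' construction [compute_measures()] on the result reproduces
#' (ss, pt, ss + pt, ll, |sva|) to machine precision.
#'
#' @param p One row of [sample_anatomy()] (or a list with the same fields).
#' @param strict Error if any landmark falls outside the canvas.
#' @return A [landmark_set()].
#' @export
landmarks_from_params <- function(p, strict = FALSE) {
  p <- as.list(p)
  f <- p$facing
  S <- max(p$image_w, p$image_h)
  H <- c(p$anchor_x, p$anchor_y)
  dy <- 0.012 * S   # projection-parallax vertical offset between heads
  sep <- p$fh_separation_px
  fh1 <- H + c(-sep / 2, -dy)
  fh2 <- H + c(sep / 2, dy)
  pt <- deg2rad(p$pt_deg); ss <- deg2rad(p$ss_deg)
  # S1 midpoint: pelvic radius along the direction tilted pt posterior of
  # vertical (posterior = -facing x, superior = -y)
  M <- H + p$pelvic_radius_px * c(-f * sin(pt), -cos(pt))
  edir <- function(theta) c(f * cos(theta), sin(theta))  # post -> ant
  nup <- function(theta) c(f * sin(theta), -cos(theta))  # away from hip
  e1 <- edir(ss)
  s1_post <- M - (p$s1_width_px / 2) * e1
  s1_ant <- M + (p$s1_width_px / 2) * e1
  # lumbar endplates: inclinations differing by ll along a smooth arc
  th5 <- ss - 0.2 * deg2rad(p$ll_deg)
  th1 <- th5 - deg2rad(p$ll_deg)
  m5 <- M + c(-f * 0.015 * S, -0.065 * S)
  m1 <- m5 + c(-f * 0.03 * S, -0.30 * S)
  wv <- p$vertebra_width_px
  l5_post <- m5 - (wv / 2) * edir(th5); l5_ant <- m5 + (wv / 2) * edir(th5)
  l1_post <- m1 - (wv / 2) * edir(th1); l1_ant <- m1 + (wv / 2) * edir(th1)
  # C7: midpoint fixed by the signed SVA relative to the S1 posterior corner
  thc <- 0.4 * th1
  c7m <- c(s1_post[1] + f * p$sva_px, 0.10 * p$image_h)
  wc <- 0.8 * wv
  c7_post <- c7m - (wc / 2) * edir(thc); c7_ant <- c7m + (wc / 2) * edir(thc)
  pts <- rbind(fh1 = fh1, fh2 = fh2, s1_post = s1_post, s1_ant = s1_ant,
               l5_post = l5_post, l5_ant = l5_ant, l1_post = l1_post,
               l1_ant = l1_ant, c7_post = c7_post, c7_ant = c7_ant)
  if (strict) {
    out <- pts[, 1] < 0 | pts[, 1] > p$image_w |
      pts[, 2] < 0 | pts[, 2] > p$image_h
    if (any(out))
      stop("landmarks outside canvas: ",
           paste(rownames(pts)[out], collapse = ", "))
  }
  landmark_set(pts, c(p$fh_radius_px, p$fh_radius_px), facing = f)
}

# --- rendering helpers -----------------------------------------------------

# Fill a convex polygon (vertices in order) on an image matrix [h, w].
# Pixel (r, c) has centre (c - 0.5, r - 0.5).
fill_convex_poly <- function(img, xs, ys, value) {
  h <- nrow(img); w <- ncol(img)
  c0 <- max(1L, floor(min(xs))); c1 <- min(w, ceiling(max(xs)))
  r0 <- max(1L, floor(min(ys))); r1 <- min(h, ceiling(max(ys)))
  if (c0 > c1 || r0 > r1) return(img)
  cx <- (c0:c1) - 0.5; cy <- (r0:r1) - 0.5
  px <- matrix(cx, length(cy), length(cx), byrow = TRUE)
  py <- matrix(cy, length(cy), length(cx))
  nv <- length(xs)
  inside <- NULL
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cr <- (xs[j] - xs[i]) * (py - ys[i]) - (ys[j] - ys[i]) * (px - xs[i])
    s <- cr >= 0
    inside <- if (is.null(inside)) s else inside & s
  }
  # vertices may be ordered either way; accept the other orientation too
  if (!any(inside)) {
    inside2 <- NULL
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      cr <- (xs[j] - xs[i]) * (py - ys[i]) - (ys[j] - ys[i]) * (px - xs[i])
      s <- cr <= 0
      inside2 <- if (is.null(inside2)) s else inside2 & s
    }
    inside <- inside2
  }
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[inside] <- value
  img[r0:r1, c0:c1] <- sub
  img
}

fill_circle <- function(img, cx, cy, r, value) {
  h <- nrow(img); w <- ncol(img)
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  if (c0 > c1 || r0 > r1) return(img)
  px <- matrix((c0:c1) - 0.5, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  py <- matrix((r0:r1) - 0.5, r1 - r0 + 1, c1 - c0 + 1)
  inside <- (px - cx)^2 + (py - cy)^2 <= r^2
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[inside] <- value
  img[r0:r1, c0:c1] <- sub
  img
}

# thin bright band along an endplate line (cortical rim)
draw_rim <- function(img, centre, half_w, e, n, S, value = 0.88) {
  q <- quad_about(centre, half_w, 0.009 * S, e, n)
  fill_convex_poly(img, q$xs, q$ys, value)
}

quad_about <- function(centre, half_w, half_h, e, n) {
  list(xs = c(centre[1] - half_w * e[1] - half_h * n[1],
              centre[1] + half_w * e[1] - half_h * n[1],
              centre[1] + half_w * e[1] + half_h * n[1],
              centre[1] - half_w * e[1] + half_h * n[1]),
       ys = c(centre[2] - half_w * e[2] - half_h * n[2],
              centre[2] + half_w * e[2] - half_h * n[2],
              centre[2] + half_w * e[2] + half_h * n[2],
              centre[2] - half_w * e[2] + half_h * n[2]))
}

#' Render a synthetic lateral radiograph
#'
#' Produces a grayscale intensity image (values in `[0, 1]`, matrix indexed
#' `[y, x]`) from a landmark set: soft-tissue background gradient,
#' vertebral bodies as bright quadrilaterals spanning the labelled
#' endplates (with interpolated mid-lumbar bodies for visual context), a
#' sacrum wedge, femoral heads as bright circles of the stored radii,
#' additive Gaussian plus signal-dependent noise, and optional
#' degradations. Degradations never move landmarks; they only occlude:
#' `"cutoff"` blanks a border band to a constant fill, `"occlusion"`
#' places an opaque rectangle in the hip region, `"implant"` draws
#' high-intensity rods along the lumbar arc.
#'
#' @param lm A [landmark_set()].
#' @param p Matching anatomy parameters (one row of [sample_anatomy()]).
#' @param degradations Character subset of
#'   `c("cutoff", "occlusion", "implant")`.
#' @param noise_sd Gaussian noise standard deviation (0 disables noise).
#' @return Numeric `image_h x image_w` matrix in `[0, 1]`.
#' @export
render_radiograph <- function(lm, p, degradations = character(),
                              noise_sd = 0.03) {
  p <- as.list(p)
  w <- p$image_w; h <- p$image_h; S <- max(w, h); f <- p$facing
  img <- matrix(rep(seq(0.22, 0.40, length.out = h), w), h, w)
  pts <- lm$points
  e_of <- function(a, b) {
    v <- pts[b, ] - pts[a, ]; v / sqrt(sum(v^2))
  }
  up_normal <- function(e) { n <- c(e[2], -e[1]); if (n[2] > 0) -n else n }
  # sacrum wedge
  M <- (pts["s1_post", ] + pts["s1_ant", ]) / 2
  apex <- M + c(-f * 0.06 * S, 0.20 * S)
  img <- fill_convex_poly(img, c(pts["s1_post", 1], pts["s1_ant", 1],
                                 apex[1]),
                          c(pts["s1_post", 2], pts["s1_ant", 2], apex[2]),
                          0.60)
  es1 <- e_of("s1_post", "s1_ant")
  img <- draw_rim(img, M, sqrt(sum((pts["s1_ant", ] - pts["s1_post", ])^2)) / 2,
                  es1, up_normal(es1), S, value = 0.84)
  hv <- 0.10 * S
  # L5 body above its inferior endplate, with a cortical rim on the
  # labelled (inferior) endplate line
  e5 <- e_of("l5_post", "l5_ant"); n5 <- up_normal(e5)
  m5i <- (pts["l5_post", ] + pts["l5_ant", ]) / 2
  hw5 <- sqrt(sum((pts["l5_ant", ] - pts["l5_post", ])^2)) / 2
  q <- quad_about(m5i + n5 * hv / 2, hw5, hv / 2, e5, n5)
  img <- fill_convex_poly(img, q$xs, q$ys, 0.70)
  img <- draw_rim(img, m5i, hw5, e5, n5, S)
  # L1 body below its superior endplate, rim on the labelled line
  e1 <- e_of("l1_post", "l1_ant"); n1 <- up_normal(e1)
  m1 <- (pts["l1_post", ] + pts["l1_ant", ]) / 2
  hw1 <- sqrt(sum((pts["l1_ant", ] - pts["l1_post", ])^2)) / 2
  q <- quad_about(m1 - n1 * hv / 2, hw1, hv / 2, e1, n1)
  img <- fill_convex_poly(img, q$xs, q$ys, 0.70)
  img <- draw_rim(img, m1, hw1, e1, n1, S)
  # interpolated mid-lumbar bodies (context only; carry no landmarks)
  m5 <- m5i
  wv2 <- 0.45 * sqrt(sum((pts["l5_ant", ] - pts["l5_post", ])^2))
  for (t in c(0.3, 0.55, 0.8)) {
    ct <- m5 + t * (m1 - m5)
    et <- (1 - t) * e5 + t * e1; et <- et / sqrt(sum(et^2))
    q <- quad_about(ct, wv2, 0.38 * hv, et, up_normal(et))
    img <- fill_convex_poly(img, q$xs, q$ys, 0.66)
  }
  # C7 body below its superior endplate, rim on the labelled line
  ec <- e_of("c7_post", "c7_ant"); nc <- up_normal(ec)
  mc <- (pts["c7_post", ] + pts["c7_ant", ]) / 2
  hwc <- sqrt(sum((pts["c7_ant", ] - pts["c7_post", ])^2)) / 2
  q <- quad_about(mc - nc * 0.04 * S, hwc, 0.04 * S, ec, nc)
  img <- fill_convex_poly(img, q$xs, q$ys, 0.72)
  img <- draw_rim(img, mc, hwc, ec, nc, S)
  # femoral heads
  img <- fill_circle(img, pts["fh1", 1], pts["fh1", 2], lm$fh_radius[1], 0.85)
  img <- fill_circle(img, pts["fh2", 1], pts["fh2", 2], lm$fh_radius[2], 0.82)
  if ("implant" %in% degradations) {
    # pedicle-screw-like rods along the lumbar arc
    for (t in c(0.15, 0.45, 0.75)) {
      ct <- m5 + t * (m1 - m5)
      et <- (1 - t) * e5 + t * e1; et <- et / sqrt(sum(et^2))
      q <- quad_about(ct, 0.55 * wv2, 0.012 * S, et, up_normal(et))
      img <- fill_convex_poly(img, q$xs, q$ys, 0.98)
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w) +
      sqrt(pmax(img, 0)) * matrix(stats::rnorm(h * w, 0, noise_sd / 2), h, w)
  }
  if ("occlusion" %in% degradations) {
    # opaque obstacle in the hip region
    cx <- p$anchor_x + stats::runif(1, -0.05, 0.05) * w
    cy <- p$anchor_y + stats::runif(1, -0.03, 0.08) * h
    hw <- stats::runif(1, 0.06, 0.12) * w; hh <- stats::runif(1, 0.05, 0.1) * h
    img <- fill_convex_poly(img, c(cx - hw, cx + hw, cx + hw, cx - hw),
                            c(cy - hh, cy - hh, cy + hh, cy + hh), 0.04)
  }
  if ("cutoff" %in% degradations) {
    frac <- stats::runif(1, 0.1, 0.3)
    side <- sample(c("top", "bottom", "left", "right"), 1)
    k <- switch(side, top = , bottom = max(1L, round(frac * h)),
                max(1L, round(frac * w)))
    switch(side,
           top = { img[seq_len(k), ] <- 0.08 },
           bottom = { img[(h - k + 1):h, ] <- 0.08 },
           left = { img[, seq_len(k)] <- 0.08 },
           right = { img[, (w - k + 1):w] <- 0.08 })
  }
  pmin(pmax(img, 0), 1)
}

#' Generate synthetic samples in memory
#'
#' Draws anatomies from a population, constructs exact landmarks and
#' labels, renders images, and applies degradations at the configured
#' prevalence (defaults: 5% low-quality — a cutoff or an occlusion — and
#' 15% implants, matching the prevalence reported for the clinical
#' cohorts).
#'
#' @param n Number of samples.
#' @param seed RNG seed (all randomness in the call derives from it).
#' @param population See [landet_population()].
#' @param image_size Canvas `c(width, height)`.
#' @param degradation_rates Named numeric: `lowq`, `implant`.
#' @param noise_sd Rendering noise level.
#' @return List of samples; each is a list with `image`, `landmarks`,
#'   `labels`, `params` (one-row data frame), `degradations`.
#' @export
generate_samples <- function(n, seed = 1, population = "ds1",
                             image_size = c(128, 128),
                             degradation_rates = c(lowq = 0.05,
                                                   implant = 0.15),
                             noise_sd = 0.03) {
  set.seed(seed)
  params <- sample_anatomy(n, population, image_size)
  lowq <- stats::runif(n) < degradation_rates[["lowq"]]
  impl <- stats::runif(n) < degradation_rates[["implant"]]
  lowq_kind <- sample(c("cutoff", "occlusion"), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    p <- params[i, ]
    lm <- landmarks_from_params(p)
    deg <- character()
    if (impl[i]) deg <- c(deg, "implant")
    if (lowq[i]) deg <- c(deg, lowq_kind[i])
    img <- render_radiograph(lm, p, deg, noise_sd)
    list(image = img, landmarks = lm,
         labels = boxes_from_landmarks(lm, p$image_w, p$image_h),
         params = p, degradations = deg)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/NNNN.png`, `labels/NNNN.txt`, `params.csv` and
#' `manifest.csv` under `dir`, with a deterministic seeded-shuffle split
#' into train/val/test fractions (default 80/10/10).
#'
#' @inheritParams generate_samples
#' @param dir Output directory (created if needed).
#' @param split Length-3 fractions summing to 1.
#' @return The manifest data frame (`image`, `label`, `split`), invisibly;
#'   also written as `manifest.csv`.
#' @export
generate_dataset <- function(dir, n, seed = 1, split = c(0.8, 0.1, 0.1),
                             population = "ds1", image_size = c(128, 128),
                             degradation_rates = c(lowq = 0.05,
                                                   implant = 0.15),
                             noise_sd = 0.03) {
  if (n < 10) stop("`n` must be at least 10")
  if (abs(sum(split) - 1) > 1e-8) stop("`split` must sum to 1")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  samples <- generate_samples(n, seed, population, image_size,
                              degradation_rates, noise_sd)
  stem <- sprintf("%04d", seq_len(n))
  n_train <- round(split[1] * n); n_val <- round(split[2] * n)
  ord <- sample(n)   # continues the generate_samples RNG stream
  role <- character(n)
  role[ord[seq_len(n_train)]] <- "train"
  role[ord[n_train + seq_len(n_val)]] <- "val"
  role[role == ""] <- "test"
  for (i in seq_len(n)) {
    png::writePNG(samples[[i]]$image,
                  file.path(dir, "images", paste0(stem[i], ".png")))
    write_labels(samples[[i]]$labels,
                 file.path(dir, "labels", paste0(stem[i], ".txt")))
  }
  params <- do.call(rbind, lapply(samples, `[[`, "params"))
  params$degradations <- vapply(samples, function(s)
    paste(s$degradations, collapse = "+"), character(1))
  params$id <- stem
  utils::write.csv(params, file.path(dir, "params.csv"), row.names = FALSE)
  manifest <- data.frame(
    image = file.path("images", paste0(stem, ".png")),
    label = file.path("labels", paste0(stem, ".txt")),
    split = role, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# --- augmentations ---------------------------------------------------------

resize_nn <- function(img, new_h, new_w) {
  r <- pmin(nrow(img), pmax(1L, ceiling(seq_len(new_h) * nrow(img) / new_h)))
  c <- pmin(ncol(img), pmax(1L, ceiling(seq_len(new_w) * ncol(img) / new_w)))
  img[r, c, drop = FALSE]
}

rebuild_sample <- function(img, lm, p) {
  list(image = img, landmarks = lm,
       labels = suppressWarnings(
         boxes_from_landmarks(lm, p$image_w, p$image_h)),
       params = p, degradations = character())
}

#' Augment a synthetic sample
#'
#' The four training-time augmentations: `"flip"` (horizontal mirror;
#' updates the facing direction, so measures are unchanged), `"crop"`
#' (random uniform-scale window resized back to the original canvas),
#' `"rotate"` (rotation about the image centre), and `"mosaic"` (combines
#' four samples into the quadrants of one canvas; label-level only, since
#' a mosaic holds several instances per class). Labels are always
#' re-derived from the transformed landmark centres, with box sizes per
#' the 5%-of-image / femoral-head-diameter rules, and landmarks whose
#' centres leave the canvas are dropped.
#'
#' @param sample A sample from [generate_samples()].
#' @param op One of `"flip"`, `"crop"`, `"rotate"`, `"mosaic"`.
#' @param others List of 3 further samples (mosaic only).
#' @param angle Rotation angle in degrees (rotate only); default random in
#'   +/- 15.
#' @param scale Crop scale (crop only); default random in \[0.65, 0.95\].
#' @return A transformed sample. For `"mosaic"` the `landmarks` element is
#'   `NULL` and only `labels` is populated.
#' @export
augment_sample <- function(sample, op, others = NULL, angle = NULL,
                           scale = NULL) {
  p <- sample$params
  w <- p$image_w; h <- p$image_h
  switch(op,
    flip = {
      img <- sample$image[, ncol(sample$image):1, drop = FALSE]
      lm <- mirror_landmarks(sample$landmarks, w)
      rebuild_sample(img, lm, p)
    },
    crop = {
      if (is.null(scale)) scale <- stats::runif(1, 0.65, 0.95)
      cw <- max(8L, round(scale * w)); ch <- max(8L, round(scale * h))
      x0 <- sample.int(w - cw + 1L, 1) - 1L
      y0 <- sample.int(h - ch + 1L, 1) - 1L
      win <- sample$image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw),
                          drop = FALSE]
      img <- resize_nn(win, h, w)
      sx <- w / cw; sy <- h / ch
      pts <- sample$landmarks$points
      pts[, 1] <- (pts[, 1] - x0) * sx
      pts[, 2] <- (pts[, 2] - y0) * sy
      out <- pts[, 1] < 0 | pts[, 1] > w | pts[, 2] < 0 | pts[, 2] > h
      pts[out, ] <- NA_real_
      lm <- landmark_set(pts, sample$landmarks$fh_radius * sqrt(sx * sy),
                         sample$landmarks$facing)
      s <- rebuild_sample(img, lm, p)
      if (!nrow(s$labels)) warning("crop excluded all landmarks")
      s
    },
    rotate = {
      if (is.null(angle)) angle <- stats::runif(1, -15, 15)
      th <- deg2rad(angle)
      cx <- w / 2; cy <- h / 2
      # inverse map destination pixel centres back into the source
      dst_x <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE) - cx
      dst_y <- matrix(seq_len(h) - 0.5, h, w) - cy
      src_x <- cos(th) * dst_x + sin(th) * dst_y + cx
      src_y <- -sin(th) * dst_x + cos(th) * dst_y + cy
      ci <- round(src_x + 0.5); ri <- round(src_y + 0.5)
      ok <- ci >= 1 & ci <= w & ri >= 1 & ri <= h
      img <- matrix(0.08, h, w)
      img[ok] <- sample$image[cbind(ri[ok], ci[ok])]
      pts <- sample$landmarks$points
      px <- pts[, 1] - cx; py <- pts[, 2] - cy
      pts[, 1] <- cos(th) * px - sin(th) * py + cx
      pts[, 2] <- sin(th) * px + cos(th) * py + cy
      out <- pts[, 1] < 0 | pts[, 1] > w | pts[, 2] < 0 | pts[, 2] > h
      pts[out, ] <- NA_real_
      lm <- landmark_set(pts, sample$landmarks$fh_radius,
                         sample$landmarks$facing)
      rebuild_sample(img, lm, p)
    },
    mosaic = {
      if (length(others) != 3) stop("mosaic needs 3 further samples")
      srcs <- c(list(sample), others)
      img <- matrix(0.08, h, w)
      hw <- floor(w / 2); hh <- floor(h / 2)
      offs <- list(c(0, 0), c(hw, 0), c(0, hh), c(hw, hh))
      labs <- list()
      for (k in 1:4) {
        sk <- srcs[[k]]
        small <- resize_nn(sk$image, hh, hw)
        ox <- offs[[k]][1]; oy <- offs[[k]][2]
        img[(oy + 1):(oy + hh), (ox + 1):(ox + hw)] <- small
        lk <- sk$labels
        if (!nrow(lk)) next
        S_src <- max(sk$params$image_w, sk$params$image_h)
        S_dst <- max(w, h)
        # centres map into the quadrant; sizes halve with the resize
        lk$bx <- (lk$bx * S_src * (hw / sk$params$image_w) + ox) / S_dst
        lk$by <- (lk$by * S_src * (hh / sk$params$image_h) + oy) / S_dst
        lk$bw <- lk$bw * S_src * (hw / sk$params$image_w) / S_dst
        lk$bh <- lk$bh * S_src * (hh / sk$params$image_h) / S_dst
        keep <- lk$bx * S_dst >= ox & lk$bx * S_dst <= ox + hw &
          lk$by * S_dst >= oy & lk$by * S_dst <= oy + hh
        labs[[k]] <- lk[keep, , drop = FALSE]
      }
      labels <- if (length(labs)) do.call(rbind, labs) else empty_labels()
      list(image = img, landmarks = NULL, labels = labels, params = p,
           degradations = character())
    },
    stop("unknown augmentation '", op, "'"))
}
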