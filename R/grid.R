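#' Multi-scale detection grid specification
#'
#' The detector predicts on three dense grids at strides 8, 16 and 32.
#' A grid at stride `n` has shape `(h/n) x (w/n) x N_a x N_o` with
#' `N_a` anchors per level and `N_o = 5 + num_classes` output channels per
#' anchor (4 box offsets, 1 objectness, class scores).
#'
#' @param image_w,image_h Input size in pixels (each divisible by 32).
#' @param anchors List of three `N_a x 2` matrices of anchor (w, h) in
#'   pixels, one per stride; defaults to [default_anchors()].
#' @param num_classes Number of object classes.
#' @param ratio_tolerance Anchor-match size-ratio tolerance.
#' @return Object of class `"grid_spec"`.
#' @export
grid_spec <- function(image_w, image_h, anchors = NULL, num_classes = 10,
                      ratio_tolerance = 4) {
  if (image_w %% 32 != 0 || image_h %% 32 != 0)
    stop("image size must be divisible by 32")
  strides <- c(8L, 16L, 32L)
  if (is.null(anchors)) anchors <- default_anchors(image_w, image_h)
  stopifnot(length(anchors) == 3)
  na <- nrow(anchors[[1]])
  structure(list(
    image_w = as.integer(image_w), image_h = as.integer(image_h),
    strides = strides, anchors = anchors, num_classes = as.integer(num_classes),
    n_anchor = na, n_out = 5L + as.integer(num_classes),
    grid_w = as.integer(image_w / strides),
    grid_h = as.integer(image_h / strides),
    ratio_tolerance = ratio_tolerance), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Detection grid spec for %dx%d input\n", x$image_w, x$image_h))
  for (l in 1:3)
    cat(sprintf("  stride %2d: %2d x %2d cells, anchors (px): %s\n",
                x$strides[l], x$grid_w[l], x$grid_h[l],
                paste(sprintf("%.1fx%.1f", x$anchors[[l]][, 1],
                              x$anchors[[l]][, 2]), collapse = ", ")))
  invisible(x)
}

#' Default anchor boxes
#'
#' Eight of the ten landmark classes share one box size (5% of the
#' maximum image dimension), so the default anchors are square multiples
#' `{0.6, 1.0, 1.6}` of that nominal side, scaled with the stride so
#' coarser grids carry larger priors (femoral-head boxes, whose side is
#' the head diameter, match the coarser levels). Small spine boxes are
#' deliberately matched on more than one level: the redundancy lets grids
#' of different receptive fields compete, and the objectness target
#' (the IoU of the decoded box) calibrates which level wins at selection
#' time.
#'
#' @param image_w,image_h Image size in pixels.
#' @param spine_frac Nominal spine-box side as a fraction of the max
#'   dimension.
#' @return List of three 3 x 2 matrices (anchor w, h in pixels).
#' @export
default_anchors <- function(image_w, image_h, spine_frac = 0.05) {
  S <- max(image_w, image_h)
  base <- spine_frac * S
  lapply(c(1, 2, 4), function(m) {
    s <- base * m * c(0.6, 1.0, 1.6)
    cbind(w = s, h = s)
  })
}

#' Responsible grid cell for an object centre
#'
#' Cells are half-open `[n*i, n*(i+1))` so a centre on an exact boundary
#' belongs to the higher-index cell; centres on the far image edge clamp
#' to the last cell.
#'
#' @param cx_px,cy_px Centre in pixels.
#' @param stride Grid stride.
#' @param grid_w,grid_h Grid dimensions in cells.
#' @return Integer `c(ix, iy)` (0-based).
#' @export
responsible_cell <- function(cx_px, cy_px, stride, grid_w, grid_h) {
  c(min(floor(cx_px / stride), grid_w - 1L),
    min(floor(cy_px / stride), grid_h - 1L))
}

#' Tolerance-based anchor matching
#'
#' An anchor matches a box when the worst of the four side ratios
#' (box/anchor and anchor/box, per axis) is strictly below the tolerance.
#'
#' @param bw_px,bh_px Box size in pixels.
#' @param anchors `N_a x 2` anchor matrix (pixels).
#' @param ratio_tolerance Tolerance (default 4).
#' @return Integer vector of matching anchor indices (possibly empty).
#' @export
match_anchors <- function(bw_px, bh_px, anchors, ratio_tolerance = 4) {
  r <- pmax(bw_px / anchors[, 1], anchors[, 1] / bw_px,
            bh_px / anchors[, 2], anchors[, 2] / bh_px)
  which(r < ratio_tolerance)
}

logit <- function(p) log(p / (1 - p))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Encode a box (pixels) relative to a cell/anchor into raw logits under the
# bounded decode transform: centre = (2*sigmoid(t) - 0.5 + cell) * stride,
# size = (2*sigmoid(t))^2 * anchor.
encode_box <- function(bx_px, by_px, bw_px, bh_px, ix, iy, stride, anchor) {
  eps <- 1e-9
  fx <- (bx_px / stride - ix + 0.5) / 2
  fy <- (by_px / stride - iy + 0.5) / 2
  sw <- sqrt(bw_px / anchor[1]) / 2
  sh <- sqrt(bh_px / anchor[2]) / 2
  clamp <- function(v) pmin(pmax(v, eps), 1 - eps)
  c(tx = logit(clamp(fx)), ty = logit(clamp(fy)),
    tw = logit(clamp(sw)), th = logit(clamp(sh)))
}

decode_box <- function(tx, ty, tw, th, ix, iy, stride, anchor) {
  anchor <- unname(anchor)
  c(bx = (2 * sigmoid(tx) - 0.5 + ix) * stride,
    by = (2 * sigmoid(ty) - 0.5 + iy) * stride,
    bw = (2 * sigmoid(tw))^2 * anchor[1],
    bh = (2 * sigmoid(th))^2 * anchor[2])
}

#' Build dense training targets from labels
#'
#' Assigns every label to its responsible cell plus the two nearest side
#' neighbours (by sub-cell centre offset; ties broken towards the
#' higher-index cell) on every level whose anchors pass the size-ratio
#' match. A label matching no anchor anywhere falls back to the single
#' best-ratio anchor. When two objects claim the same (level, cell,
#' anchor), the one whose centre is nearest the cell centre wins.
#'
#' @param labels Label data frame (normalised by `max(w, h)`).
#' @param spec A [grid_spec()].
#' @return Object of class `"target_grids"`: list with `assignments` (one
#'   data frame per level: cell/anchor indices, class, encoded and pixel
#'   box targets, `primary` flag) and `labels` (the input, with pixel
#'   centres).
#' @export
build_targets <- function(labels, spec) {
  S <- max(spec$image_w, spec$image_h)
  per_level <- vector("list", 3)
  if (nrow(labels)) {
    # anchor matching across levels, with global best-ratio fallback
    match_lv <- vector("list", nrow(labels))
    for (o in seq_len(nrow(labels))) {
      bw <- labels$bw[o] * S; bh <- labels$bh[o] * S
      ml <- lapply(1:3, function(l)
        match_anchors(bw, bh, spec$anchors[[l]], spec$ratio_tolerance))
      if (!any(lengths(ml) > 0)) {
        ratios <- sapply(1:3, function(l) {
          a <- spec$anchors[[l]]
          min(pmax(bw / a[, 1], a[, 1] / bw, bh / a[, 2], a[, 2] / bh))
        })
        lbest <- which.min(ratios)
        abest <- which.min(pmax(bw / spec$anchors[[lbest]][, 1],
                                spec$anchors[[lbest]][, 1] / bw,
                                bh / spec$anchors[[lbest]][, 2],
                                spec$anchors[[lbest]][, 2] / bh))
        ml[[lbest]] <- abest
      }
      match_lv[[o]] <- ml
    }
    for (l in 1:3) {
      n <- spec$strides[l]; gw <- spec$grid_w[l]; gh <- spec$grid_h[l]
      rows <- list()
      for (o in seq_len(nrow(labels))) {
        aidx <- match_lv[[o]][[l]]
        if (!length(aidx)) next
        bx <- labels$bx[o] * S; by <- labels$by[o] * S
        bw <- labels$bw[o] * S; bh <- labels$bh[o] * S
        cell <- responsible_cell(bx, by, n, gw, gh)
        fx <- bx / n - cell[1]; fy <- by / n - cell[2]
        cands <- list(c(cell, TRUE))
        nx <- cell[1] + if (fx < 0.5) -1L else 1L
        ny <- cell[2] + if (fy < 0.5) -1L else 1L
        if (nx >= 0 && nx < gw) cands <- c(cands, list(c(nx, cell[2], FALSE)))
        if (ny >= 0 && ny < gh) cands <- c(cands, list(c(cell[1], ny, FALSE)))
        for (cc in cands) for (a in aidx) {
          tv <- encode_box(bx, by, bw, bh, cc[1], cc[2], n,
                           spec$anchors[[l]][a, ])
          rows[[length(rows) + 1L]] <- data.frame(
            ix = cc[1], iy = cc[2], anchor = a,
            class_id = labels$class_id[o], obj = o,
            bx_px = bx, by_px = by, bw_px = bw, bh_px = bh,
            tx = tv[1], ty = tv[2], tw = tv[3], th = tv[4],
            primary = as.logical(cc[3]),
            off2 = (fx - 0.5)^2 + (fy - 0.5)^2)
        }
      }
      if (length(rows)) {
        d <- do.call(rbind, rows)
        # nearest-centre wins on (cell, anchor) conflicts
        ord <- order(d$off2)
        d <- d[ord, , drop = FALSE]
        key <- paste(d$ix, d$iy, d$anchor)
        d <- d[!duplicated(key), , drop = FALSE]
        rownames(d) <- NULL
        per_level[[l]] <- d
      } else per_level[[l]] <- NULL
    }
  }
  lab <- labels
  if (nrow(lab)) { lab$cx_px <- lab$bx * S; lab$cy_px <- lab$by * S }
  # plain-vector views used by the training inner loop
  nrP <- spec$n_anchor * spec$n_out
  fast <- lapply(1:3, function(l) {
    A <- per_level[[l]]
    if (is.null(A)) return(NULL)
    cols <- A$ix * spec$grid_h[l] + A$iy + 1L
    base <- (A$anchor - 1L) * spec$n_out
    lin0 <- (cols - 1L) * nrP + base
    tgtc <- matrix(0, spec$num_classes, nrow(A))
    tgtc[cbind(A$class_id + 1L, seq_len(nrow(A)))] <- 1
    list(n = nrow(A), cols = cols, anchor = A$anchor, lin0 = lin0,
         tgtc = tgtc,
         clin = outer(5L + seq_len(spec$num_classes), lin0, "+"),
         ix = A$ix, iy = A$iy, class_id = A$class_id,
         Aw = spec$anchors[[l]][A$anchor, 1],
         Ah = spec$anchors[[l]][A$anchor, 2],
         bx = A$bx_px, by = A$by_px, bw = A$bw_px, bh = A$bh_px)
  })
  ct <- constraint_targets(labels)
  structure(list(assignments = per_level, labels = lab, spec = spec,
                 fast = fast, ct = ct),
            class = "target_grids")
}

# Column index (1-based) of cell (ix, iy) in a head matrix whose columns
# are ordered b*(gw*gh) + ix*gh + iy.
cell_col <- function(ix, iy, gh) ix * gh + iy + 1L

# Channel rows for anchor a (1-based): 15 rows per anchor:
# tx, ty, tw, th, obj, cls1..cls10.
anchor_rows <- function(a, n_out) (a - 1L) * n_out + seq_len(n_out)

#' Decode prediction grids into detections
#'
#' Applies the bounded anchor transform to every cell/anchor, computes
#' confidence as `sigmoid(objectness) * max(sigmoid(class scores))`, and
#' keeps detections with confidence strictly above the threshold.
#'
#' @param preds List of three head matrices (`N_a*N_o` rows,
#'   `grid_w*grid_h` columns each) of raw logits for one image.
#' @param spec A [grid_spec()].
#' @param conf_threshold Confidence threshold (default 0.25).
#' @return Detection data frame (normalised coordinates + `confidence`).
#' @export
decode_predictions <- function(preds, spec, conf_threshold = 0.25) {
  S <- max(spec$image_w, spec$image_h)
  no <- spec$n_out
  out <- list()
  for (l in 1:3) {
    P <- preds[[l]]
    gh <- spec$grid_h[l]; gw <- spec$grid_w[l]; n <- spec$strides[l]
    if (ncol(P) != gh * gw || nrow(P) != spec$n_anchor * no)
      stop("prediction grid shape mismatch at stride ", n)
    cols <- 0:(gh * gw - 1L)
    ix <- cols %/% gh; iy <- cols %% gh
    for (a in seq_len(spec$n_anchor)) {
      r <- anchor_rows(a, no)
      tx <- P[r[1], ]; ty <- P[r[2], ]; tw <- P[r[3], ]; th <- P[r[4], ]
      obj <- sigmoid(P[r[5], ])
      cl <- sigmoid(P[r[6:no], , drop = FALSE])
      best <- max.col(t(cl))
      conf <- obj * cl[cbind(best, seq_along(cols))]
      keep <- which(conf > conf_threshold)
      if (!length(keep)) next
      A <- spec$anchors[[l]][a, ]
      out[[length(out) + 1L]] <- data.frame(
        class_id = best[keep] - 1L,
        bx = ((2 * sigmoid(tx[keep]) - 0.5 + ix[keep]) * n) / S,
        by = ((2 * sigmoid(ty[keep]) - 0.5 + iy[keep]) * n) / S,
        bw = (2 * sigmoid(tw[keep]))^2 * A[1] / S,
        bh = (2 * sigmoid(th[keep]))^2 * A[2] / S,
        confidence = conf[keep])
    }
  }
  if (!length(out)) return(empty_labels(confidence = TRUE))
  d <- do.call(rbind, out)
  d[order(-d$confidence), , drop = FALSE]
}

#' Non-maximum suppression
#'
#' Greedy descending-confidence suppression at the given IoU threshold,
#' within each class by default.
#'
#' @param dets Detection data frame.
#' @param iou_threshold Suppression IoU threshold (default 0.45).
#' @param per_class Suppress only within the same class.
#' @return Filtered detections, sorted by confidence.
#' @export
nms <- function(dets, iou_threshold = 0.45, per_class = TRUE) {
  if (!nrow(dets)) return(dets)
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  keep <- logical(nrow(dets))
  active <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!active[i]) next
    keep[i] <- TRUE
    if (i == nrow(dets)) break
    j <- (i + 1):nrow(dets)
    j <- j[active[j]]
    if (per_class) j <- j[dets$class_id[j] == dets$class_id[i]]
    if (!length(j)) next
    ious <- vapply(j, function(k) box_iou(
      c(dets$bx[i], dets$by[i], dets$bw[i], dets$bh[i]),
      c(dets$bx[k], dets$by[k], dets$bw[k], dets$bh[k])), numeric(1))
    active[j[ious >= iou_threshold]] <- FALSE
  }
  dets[keep, , drop = FALSE]
}
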