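#' Binary cross-entropy
#'
#' `-(c*log(chat) + (1-c)*log(1-chat))`, with the prediction clamped to
#' `(eps, 1-eps)`. Accepts soft targets.
#'
#' @param c Target in `[0, 1]`.
#' @param chat Predicted probability.
#' @param eps Clamping constant.
#' @return Non-negative loss (vectorised).
#' @export
bce <- function(c, chat, eps = 1e-7) {
  chat <- pmin(pmax(chat, eps), 1 - eps)
  -(c * log(chat) + (1 - c) * log(1 - chat))
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Boxes as `c(bx, by, bw, bh)` (centre/size, any common unit).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iw <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
    max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  ih <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
    max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Loss weights
#'
#' Weights of the multi-task training loss: the total for a batch is
#' `n_b * (lambda_obj*l_obj + lambda_box*l_box + lambda_cls*l_cls +
#' lambda_cnst * (w_angular*l_ang + w_distance*l_dist))`, i.e. two
#' constraint families (angular, distance) each with its own weight.
#'
#' @param lambda_obj,lambda_box,lambda_cls,lambda_cnst Component weights.
#' @param w_angular,w_distance Constraint-family weights.
#' @param n_b Batch size scale.
#' @return List of class `"loss_weights"`.
#' @export
landet_loss_weights <- function(lambda_obj = 1, lambda_box = 0.2,
                                lambda_cls = 0.5, lambda_cnst = 0.1,
                                w_angular = 1, w_distance = 1, n_b = 1) {
  w <- list(lambda_obj = lambda_obj, lambda_box = lambda_box,
            lambda_cls = lambda_cls, lambda_cnst = lambda_cnst,
            w_angular = w_angular, w_distance = w_distance, n_b = n_b)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

# Decode the predicted box (pixels) at one assignment entry.
decode_at <- function(P, spec, level, ix, iy, anchor) {
  r <- anchor_rows(anchor, spec$n_out)
  col <- cell_col(ix, iy, spec$grid_h[level])
  decode_box(P[r[1], col], P[r[2], col], P[r[3], col], P[r[4], col],
             ix, iy, spec$strides[level], spec$anchors[[level]][anchor, ])
}

#' Objectness loss
#'
#' Per level, the mean over **all** cells and anchors of the binary
#' cross-entropy between the predicted objectness and its target, summed
#' over levels. At assigned entries the target is the IoU between the
#' currently decoded predicted box and the target box (treated as a
#' constant), encouraging anchor-channel specialisation; elsewhere it
#' is 0.
#'
#' @param G A [build_targets()] result.
#' @param Ghat List of three raw head matrices for the image.
#' @return Scalar loss.
#' @export
l_obj <- function(G, Ghat) {
  spec <- G$spec
  total <- 0
  for (l in 1:3) {
    P <- Ghat[[l]]
    obj_rows <- (seq_len(spec$n_anchor) - 1L) * spec$n_out + 5L
    tgt <- matrix(0, spec$n_anchor, ncol(P))
    A <- G$assignments[[l]]
    if (!is.null(A)) for (k in seq_len(nrow(A))) {
      pb <- decode_at(P, spec, l, A$ix[k], A$iy[k], A$anchor[k])
      tb <- c(A$bx_px[k], A$by_px[k], A$bw_px[k], A$bh_px[k])
      tgt[A$anchor[k], cell_col(A$ix[k], A$iy[k], spec$grid_h[l])] <-
        box_iou(pb, tb)
    }
    total <- total + mean(bce(tgt, sigmoid(P[obj_rows, , drop = FALSE])))
  }
  total
}

#' Box regression loss
#'
#' Per level, the mean over assigned entries of `1 - IoU(predicted,
#' target)`, summed over levels; 0 when nothing is assigned.
#'
#' @inheritParams l_obj
#' @return Scalar loss.
#' @export
l_box <- function(G, Ghat) {
  spec <- G$spec
  total <- 0
  for (l in 1:3) {
    A <- G$assignments[[l]]
    if (is.null(A)) next
    v <- vapply(seq_len(nrow(A)), function(k) {
      pb <- decode_at(Ghat[[l]], spec, l, A$ix[k], A$iy[k], A$anchor[k])
      1 - box_iou(pb, c(A$bx_px[k], A$by_px[k], A$bw_px[k], A$bh_px[k]))
    }, numeric(1))
    total <- total + mean(v)
  }
  total
}

#' Classification loss
#'
#' Per level, the mean over assigned entries of the per-entry mean
#' multi-label binary cross-entropy across the class channels (one-hot
#' targets), summed over levels.
#'
#' @inheritParams l_obj
#' @return Scalar loss.
#' @export
l_cls <- function(G, Ghat) {
  spec <- G$spec
  total <- 0
  for (l in 1:3) {
    A <- G$assignments[[l]]
    if (is.null(A)) next
    v <- vapply(seq_len(nrow(A)), function(k) {
      r <- anchor_rows(A$anchor[k], spec$n_out)
      col <- cell_col(A$ix[k], A$iy[k], spec$grid_h[l])
      chat <- sigmoid(Ghat[[l]][r[6:spec$n_out], col])
      tgt <- as.numeric(seq_len(spec$num_classes) - 1L == A$class_id[k])
      mean(bce(tgt, chat))
    }, numeric(1))
    total <- total + mean(v)
  }
  total
}

#' Pairwise geometric constraint targets
#'
#' For every unordered pair of landmark classes present, the displacement
#' vector and Euclidean distance between their centres in normalised
#' coordinates. These encode the rigid-body relations between landmarks
#' (e.g. the two sacral corners) that the constraint loss imposes.
#'
#' @param labels Label (or detection) data frame; the first row per class
#'   is used.
#' @return Data frame with `i`, `j` (class ids, `i < j`), `rx`, `ry`, `d`;
#'   zero rows when fewer than two classes are present.
#' @export
constraint_targets <- function(labels) {
  first <- labels[!duplicated(labels$class_id), , drop = FALSE]
  first <- first[order(first$class_id), , drop = FALSE]
  k <- nrow(first)
  if (k < 2)
    return(data.frame(i = integer(), j = integer(), rx = numeric(),
                      ry = numeric(), d = numeric()))
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  rx <- first$bx[pairs[, 2]] - first$bx[pairs[, 1]]
  ry <- first$by[pairs[, 2]] - first$by[pairs[, 1]]
  data.frame(i = first$class_id[pairs[, 1]], j = first$class_id[pairs[, 2]],
             rx = rx, ry = ry, d = sqrt(rx^2 + ry^2))
}

#' @rdname constraint_targets
#' @param dets Detection data frame; the highest-confidence detection per
#'   class is used.
#' @export
constraint_predictions <- function(dets) {
  if (is.null(dets$confidence)) dets$confidence <- 1
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  constraint_targets(dets)
}

# Best assigned entry per class (highest predicted objectness), with its
# decoded centre in normalised coordinates. Used by the constraint loss.
best_class_entries <- function(G, Ghat) {
  spec <- G$spec
  S <- max(spec$image_w, spec$image_h)
  best <- list()
  for (l in 1:3) {
    A <- G$assignments[[l]]
    if (is.null(A)) next
    P <- Ghat[[l]]
    for (k in seq_len(nrow(A))) {
      r <- anchor_rows(A$anchor[k], spec$n_out)
      col <- cell_col(A$ix[k], A$iy[k], spec$grid_h[l])
      po <- sigmoid(P[r[5], col])
      cid <- as.character(A$class_id[k])
      if (is.null(best[[cid]]) || po > best[[cid]]$po) {
        n <- spec$strides[l]
        cx <- (2 * sigmoid(P[r[1], col]) - 0.5 + A$ix[k]) * n / S
        cy <- (2 * sigmoid(P[r[2], col]) - 0.5 + A$iy[k]) * n / S
        best[[cid]] <- list(po = po, level = l, col = col, rows = r,
                            ix = A$ix[k], iy = A$iy[k], cx = cx, cy = cy)
      }
    }
  }
  best
}

#' Physics-informed constraint loss
#'
#' Compares the pairwise displacement structure of the predicted landmark
#' centres against the ground-truth structure: the angular family is the
#' mean over pairs of `1 - cosine_similarity(r_hat, r)` and the distance
#' family the mean over pairs of `| ||r_hat|| - ||r|| |`. Predicted
#' centres are the decoded box centres of each class's best assigned
#' prediction, so the constraint is differentiable through the box head
#' and adds no parameters. Pairs involving a class with no prediction are
#' skipped; zero-length predicted vectors are skipped with a warning.
#'
#' @inheritParams l_obj
#' @return Named numeric `c(angular =, distance =)`.
#' @export
l_cnst <- function(G, Ghat) {
  tg <- constraint_targets(G$labels)
  if (!nrow(tg)) return(c(angular = 0, distance = 0))
  best <- best_class_entries(G, Ghat)
  ang <- num <- dis <- 0
  for (k in seq_len(nrow(tg))) {
    bi <- best[[as.character(tg$i[k])]]
    bj <- best[[as.character(tg$j[k])]]
    if (is.null(bi) || is.null(bj)) next
    rh <- c(bj$cx - bi$cx, bj$cy - bi$cy)
    nh <- sqrt(sum(rh^2))
    if (nh == 0 || tg$d[k] == 0) {
      warning("zero-length constraint vector; pair skipped")
      next
    }
    ang <- ang + (1 - sum(rh * c(tg$rx[k], tg$ry[k])) / (nh * tg$d[k]))
    dis <- dis + abs(nh - tg$d[k])
    num <- num + 1
  }
  if (num == 0) return(c(angular = 0, distance = 0))
  c(angular = ang / num, distance = dis / num)
}

#' Total multi-task loss
#'
#' Weighted sum of the objectness, box, class and constraint components,
#' scaled by the batch size, with the per-component values returned for
#' logging.
#'
#' @inheritParams l_obj
#' @param weights A [landet_loss_weights()].
#' @return List with `total` and `components`.
#' @export
total_loss <- function(G, Ghat, weights = landet_loss_weights()) {
  co <- c(obj = l_obj(G, Ghat), box = l_box(G, Ghat), cls = l_cls(G, Ghat))
  cn <- l_cnst(G, Ghat)
  total <- weights$n_b * (weights$lambda_obj * co[["obj"]] +
    weights$lambda_box * co[["box"]] + weights$lambda_cls * co[["cls"]] +
    weights$lambda_cnst * (weights$w_angular * cn[["angular"]] +
                             weights$w_distance * cn[["distance"]]))
  list(total = total,
       components = c(co, cnst_angular = cn[["angular"]],
                      cnst_distance = cn[["distance"]]))
}

# --- analytic gradients for training ---------------------------------------

# dIoU/d(bx, by, bw, bh) of box a against fixed box b, matching box_iou.
iou_grad <- function(a, b) {
  aL <- a[1] - a[3] / 2; aR <- a[1] + a[3] / 2
  aT <- a[2] - a[4] / 2; aB <- a[2] + a[4] / 2
  bL <- b[1] - b[3] / 2; bR <- b[1] + b[3] / 2
  bT <- b[2] - b[4] / 2; bB <- b[2] + b[4] / 2
  iw <- min(aR, bR) - max(aL, bL)
  ih <- min(aB, bB) - max(aT, bT)
  if (iw <= 0 || ih <= 0) return(list(iou = 0, grad = numeric(4)))
  inter <- iw * ih
  U <- a[3] * a[4] + b[3] * b[4] - inter
  rmin <- as.numeric(aR < bR); lmax <- as.numeric(aL > bL)
  bmin <- as.numeric(aB < bB); tmax <- as.numeric(aT > bT)
  diw <- c(rmin - lmax, 0, 0.5 * (rmin + lmax), 0)
  dih <- c(0, bmin - tmax, 0, 0.5 * (bmin + tmax))
  dI <- ih * diw + iw * dih
  dA <- c(0, 0, a[4], a[3])
  dU <- dA - dI
  list(iou = inter / U, grad = (dI * U - inter * dU) / U^2)
}

# Vectorised IoU (and gradient w.r.t. the first box) for aligned vectors
# of centre/size boxes.
viou_grad <- function(px, py, pw, ph, qx, qy, qw, qh) {
  aL <- px - pw / 2; aR <- px + pw / 2; aT <- py - ph / 2; aB <- py + ph / 2
  bL <- qx - qw / 2; bR <- qx + qw / 2; bT <- qy - qh / 2; bB <- qy + qh / 2
  iw <- pmin(aR, bR) - pmax(aL, bL)
  ih <- pmin(aB, bB) - pmax(aT, bT)
  pos <- as.numeric(iw > 0 & ih > 0)
  iw2 <- pmax(iw, 0); ih2 <- pmax(ih, 0)
  inter <- iw2 * ih2
  U <- pw * ph + qw * qh - inter
  iou <- pos * inter / U
  rmin <- as.numeric(aR < bR); lmax <- as.numeric(aL > bL)
  bmin <- as.numeric(aB < bB); tmax <- as.numeric(aT > bT)
  diw_dx <- rmin - lmax; diw_dw <- 0.5 * (rmin + lmax)
  dih_dy <- bmin - tmax; dih_dh <- 0.5 * (bmin + tmax)
  gx <- ih2 * diw_dx; gy <- iw2 * dih_dy
  gw <- ih2 * diw_dw; gh <- iw2 * dih_dh
  scale <- pos / U
  list(iou = iou,
       gx = (gx - iou * (-gx)) * scale * pos,
       gy = (gy - iou * (-gy)) * scale * pos,
       gw = (gw - iou * (ph - gw)) * scale * pos,
       gh = (gh - iou * (pw - gh)) * scale * pos)
}

# Loss and gradients w.r.t. the raw head matrices for a batch of images.
# targets: list of build_targets() results; preds: list (per image) of
# 3-element head lists. Returns averaged components, the total, and grads
# with the same shape as preds. The IoU factor inside the objectness
# target is treated as a constant. Vectorised over assignments.
loss_and_grads <- function(targets, preds, weights = landet_loss_weights()) {
  B <- length(targets)
  spec <- targets[[1]]$spec
  no <- spec$n_out
  comp <- c(obj = 0, box = 0, cls = 0, cnst_angular = 0, cnst_distance = 0)
  grads <- vector("list", B)
  scale_img <- weights$n_b / B
  S <- max(spec$image_w, spec$image_h)
  ncls <- spec$num_classes
  obj_rows <- (seq_len(spec$n_anchor) - 1L) * no + 5L
  for (b in seq_len(B)) {
    G <- targets[[b]]; Ghat <- preds[[b]]
    gb <- vector("list", 3)
    # per-entry bookkeeping for the constraint term (plain vectors)
    e_lvl <- e_cls <- e_po <- e_ltx <- e_lty <- e_sx <- e_sy <-
      e_cx <- e_cy <- numeric(0)
    for (l in 1:3) {
      P <- Ghat[[l]]
      g <- matrix(0, nrow(P), ncol(P))
      tgt <- matrix(0, spec$n_anchor, ncol(P))
      Fq <- G$fast[[l]]
      if (!is.null(Fq)) {
        nA <- Fq$n
        n <- spec$strides[l]
        l1 <- Fq$lin0 + 1L; l2 <- Fq$lin0 + 2L
        l3 <- Fq$lin0 + 3L; l4 <- Fq$lin0 + 4L
        sx <- sigmoid(P[l1]); sy <- sigmoid(P[l2])
        sw <- sigmoid(P[l3]); sh <- sigmoid(P[l4])
        px <- (2 * sx - 0.5 + Fq$ix) * n; py <- (2 * sy - 0.5 + Fq$iy) * n
        pw <- (2 * sw)^2 * Fq$Aw; ph <- (2 * sh)^2 * Fq$Ah
        vg <- viou_grad(px, py, pw, ph, Fq$bx, Fq$by, Fq$bw, Fq$bh)
        tgt[cbind(Fq$anchor, Fq$cols)] <- vg$iou
        comp[["box"]] <- comp[["box"]] + sum(1 - vg$iou) / (nA * B)
        # chain dIoU/dbox through the decode transform
        cb <- weights$lambda_box / nA
        g[l1] <- -cb * vg$gx * 2 * sx * (1 - sx) * n
        g[l2] <- -cb * vg$gy * 2 * sy * (1 - sy) * n
        g[l3] <- -cb * vg$gw * 8 * sw^2 * (1 - sw) * Fq$Aw
        g[l4] <- -cb * vg$gh * 8 * sh^2 * (1 - sh) * Fq$Ah
        # class channels: ncls x nA slab
        sc <- matrix(sigmoid(P[Fq$clin]), ncls, nA)
        comp[["cls"]] <- comp[["cls"]] + mean(bce(Fq$tgtc, sc)) / B
        g[Fq$clin] <- weights$lambda_cls * (sc - Fq$tgtc) / (ncls * nA)
        e_lvl <- c(e_lvl, rep(l, nA)); e_cls <- c(e_cls, Fq$class_id)
        e_po <- c(e_po, sigmoid(P[Fq$lin0 + 5L]))
        e_ltx <- c(e_ltx, l1); e_lty <- c(e_lty, l2)
        e_sx <- c(e_sx, sx); e_sy <- c(e_sy, sy)
        e_cx <- c(e_cx, px / S); e_cy <- c(e_cy, py / S)
      }
      so <- sigmoid(P[obj_rows, , drop = FALSE])
      comp[["obj"]] <- comp[["obj"]] + mean(bce(tgt, so)) / B
      g[obj_rows, ] <- g[obj_rows, ] +
        weights$lambda_obj * (so - tgt) / length(tgt)
      gb[[l]] <- g
    }
    # constraint families (components always logged; lambda_cnst scales
    # the gradient, so 0 gives the unconstrained ablation)
    tg <- G$ct
    if (nrow(tg) && length(e_po)) {
      ord <- order(e_cls, -e_po)
      keep <- ord[!duplicated(e_cls[ord])]
      bi <- keep[match(tg$i, e_cls[keep])]
      bj <- keep[match(tg$j, e_cls[keep])]
      ok <- !is.na(bi) & !is.na(bj)
      rhx <- e_cx[bj] - e_cx[bi]; rhy <- e_cy[bj] - e_cy[bi]
      nh <- sqrt(rhx^2 + rhy^2)
      ok <- ok & !is.na(nh) & nh > 0 & tg$d > 0
      np <- sum(ok)
      if (np) {
        idx <- which(ok)
        cosv <- (rhx[idx] * tg$rx[idx] + rhy[idx] * tg$ry[idx]) /
          (nh[idx] * tg$d[idx])
        comp[["cnst_angular"]] <- comp[["cnst_angular"]] +
          sum(1 - cosv) / (np * B)
        comp[["cnst_distance"]] <- comp[["cnst_distance"]] +
          sum(abs(nh[idx] - tg$d[idx])) / (np * B)
        dangx <- -(tg$rx[idx] / (nh[idx] * tg$d[idx]) -
                     cosv * rhx[idx] / nh[idx]^2)
        dangy <- -(tg$ry[idx] / (nh[idx] * tg$d[idx]) -
                     cosv * rhy[idx] / nh[idx]^2)
        sgn <- sign(nh[idx] - tg$d[idx])
        drx <- (weights$lambda_cnst / np) *
          (weights$w_angular * dangx + weights$w_distance * sgn * rhx[idx] /
             nh[idx])
        dry <- (weights$lambda_cnst / np) *
          (weights$w_angular * dangy + weights$w_distance * sgn * rhy[idx] /
             nh[idx])
        for (q in seq_along(idx)) {
          for (side in list(list(e = bj[idx[q]], s = +1),
                            list(e = bi[idx[q]], s = -1))) {
            e <- side$e
            lv <- e_lvl[e]
            n <- spec$strides[lv]
            gb[[lv]][e_ltx[e]] <- gb[[lv]][e_ltx[e]] +
              side$s * drx[q] * 2 * e_sx[e] * (1 - e_sx[e]) * n / S
            gb[[lv]][e_lty[e]] <- gb[[lv]][e_lty[e]] +
              side$s * dry[q] * 2 * e_sy[e] * (1 - e_sy[e]) * n / S
          }
        }
      }
    }
    grads[[b]] <- lapply(gb, function(m) m * scale_img)
  }
  total <- weights$n_b * (weights$lambda_obj * comp[["obj"]] +
    weights$lambda_box * comp[["box"]] + weights$lambda_cls * comp[["cls"]] +
    weights$lambda_cnst * (weights$w_angular * comp[["cnst_angular"]] +
                             weights$w_distance * comp[["cnst_distance"]]))
  list(total = total, components = comp, grads = grads)
}
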