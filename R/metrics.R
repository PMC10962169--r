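#' Relative root mean square error (RRMSE)
#'
#' RMSE between prediction and ground truth divided by the ground-truth
#' standard deviation about its mean, both with the 1/N convention.
#' 0 is perfect; 1 is the threshold of uselessness (a constant predictor
#' at the ground-truth mean scores exactly 1).
#'
#' @param y Ground-truth values.
#' @param v Predicted values.
#' @return Non-negative scalar.
#' @export
rrmse <- function(y, v) {
  stopifnot(length(y) == length(v), length(y) >= 2)
  denom <- sqrt(mean((y - mean(y))^2))
  if (denom == 0) stop("rrmse: ground truth has zero variance")
  sqrt(mean((y - v)^2)) / denom
}

#' Prediction accuracy in percent
#'
#' `(1 - RRMSE) * 100`; may be negative when RRMSE exceeds 1 (reported
#' as-is).
#'
#' @inheritParams rrmse
#' @return Percentage.
#' @export
accuracy <- function(y, v) (1 - rrmse(y, v)) * 100

#' Mean absolute error and its spread
#'
#' @inheritParams rrmse
#' @param convention `"sample"` (1/(N-1), default) or `"n"` (1/N) for the
#'   SD of the absolute errors.
#' @return Named numeric `c(mae =, sd =)`.
#' @export
mae_sd <- function(y, v, convention = c("sample", "n")) {
  convention <- match.arg(convention)
  e <- abs(y - v)
  s <- if (convention == "sample") stats::sd(e)
    else sqrt(mean((e - mean(e))^2))
  c(mae = mean(e), sd = s)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value uses the exact t transform
#' `t = r * sqrt((N-2)/(1-r^2))` on `N - 2` degrees of freedom.
#'
#' @inheritParams rrmse
#' @return Named numeric `c(r =, p =)`.
#' @export
pearson_r <- function(y, v) {
  n <- length(y)
  stopifnot(n == length(v), n >= 3)
  yc <- y - mean(y); vc <- v - mean(v)
  sy <- sqrt(sum(yc^2)); sv <- sqrt(sum(vc^2))
  if (sy == 0 || sv == 0) stop("pearson_r: zero variance")
  r <- sum(yc * vc) / (sy * sv)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  c(r = r, p = p)
}

#' Intraclass correlation coefficient (single-rating consistency)
#'
#' One-way decomposition of an N-subject by m-rater table:
#' `ICC = (MSBS - MSWS) / (MSBS + (m - 1) * MSWS)` where MSBS and MSWS are
#' the between- and within-subject mean squares. Values near 1 indicate
#' that raters agree up to subject-level differences; the lower bound is
#' `-1/(m-1)`.
#'
#' @param rt Numeric N x m matrix (subjects x raters), no missing cells.
#' @return Scalar ICC.
#' @export
icc <- function(rt) {
  rt <- as.matrix(rt)
  N <- nrow(rt); m <- ncol(rt)
  stopifnot(N >= 2, m >= 2)
  if (anyNA(rt)) stop("icc: missing cells (apply listwise deletion first)")
  sm <- rowMeans(rt)
  msbs <- m * sum((sm - mean(rt))^2) / (N - 1)
  msws <- sum((rt - sm)^2) / (N * (m - 1))
  if (msbs == 0 && msws == 0) stop("icc: degenerate table (no variance)")
  (msbs - msws) / (msbs + (m - 1) * msws)
}

#' Mean average precision over IoU thresholds
#'
#' Per class: detections pooled over images and ranked by confidence are
#' greedily matched (each ground truth at most once, best IoU first) at
#' each threshold; average precision is the 101-point interpolated area
#' under the precision-recall curve; mAP averages over classes with
#' ground truth (and over thresholds).
#'
#' @param preds List (per image) of detection data frames.
#' @param gts List (per image) of ground-truth label data frames.
#' @param thresholds IoU threshold vector, e.g. `0.5` or
#'   `seq(0.5, 0.95, 0.05)`.
#' @return List with `map`, and `per_class` (class x threshold AP matrix).
#' @export
map_at_iou <- function(preds, gts, thresholds = 0.5) {
  stopifnot(length(preds) == length(gts))
  classes <- sort(unique(unlist(lapply(gts, function(g) g$class_id))))
  all_classes <- sort(unique(c(classes,
                               unlist(lapply(preds, function(p) p$class_id)))))
  if (length(setdiff(all_classes, classes)))
    warning("classes with predictions but no ground truth are skipped: ",
            paste(setdiff(all_classes, classes), collapse = ", "))
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(classes, thresholds))
  rec_grid <- seq(0, 1, 0.01)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    det <- do.call(rbind, lapply(seq_along(preds), function(i) {
      d <- preds[[i]][preds[[i]]$class_id == cl, , drop = FALSE]
      if (nrow(d)) cbind(d, img = i) else NULL
    }))
    ngt_img <- vapply(gts, function(g) sum(g$class_id == cl), integer(1))
    ngt <- sum(ngt_img)
    for (ti in seq_along(thresholds)) {
      thr <- thresholds[ti]
      if (is.null(det) || !nrow(det)) { ap[ci, ti] <- 0; next }
      det <- det[order(-det$confidence), , drop = FALSE]
      used <- lapply(ngt_img, function(k) logical(k))
      tp <- numeric(nrow(det))
      for (d in seq_len(nrow(det))) {
        g <- gts[[det$img[d]]]
        g <- g[g$class_id == cl, , drop = FALSE]
        if (!nrow(g)) next
        ious <- vapply(seq_len(nrow(g)), function(k) box_iou(
          c(det$bx[d], det$by[d], det$bw[d], det$bh[d]),
          c(g$bx[k], g$by[k], g$bw[k], g$bh[k])), numeric(1))
        best <- which.max(ious)
        if (ious[best] >= thr && !used[[det$img[d]]][best]) {
          tp[d] <- 1
          used[[det$img[d]]][best] <- TRUE
        }
      }
      cum_tp <- cumsum(tp); cum_fp <- cumsum(1 - tp)
      prec <- cum_tp / (cum_tp + cum_fp)
      rec <- cum_tp / ngt
      # 101-point interpolation with monotone precision envelope
      penv <- rev(cummax(rev(prec)))
      ap[ci, ti] <- mean(vapply(rec_grid, function(r) {
        ok <- which(rec >= r)
        if (!length(ok)) 0 else penv[ok[1]]
      }, numeric(1)))
    }
  }
  list(map = mean(ap), per_class = ap)
}

#' Landmark detection-success rate
#'
#' A landmark counts as successfully detected when the box of its
#' best-confidence detection overlaps the ground-truth box with IoU at or
#' above the success threshold (0.3 by default, the evaluation criterion
#' for landmark-as-object boxes). An image is complete when all ten
#' classes are detected.
#'
#' @param preds List (per image) of detection data frames (the best
#'   detection per class is used).
#' @param gts List (per image) of ground-truth label data frames.
#' @param iou_success Success IoU threshold.
#' @return List with `per_class` (data frame) and `image_complete` (the
#'   fraction of images with all present classes detected).
#' @export
detection_rate <- function(preds, gts, iou_success = 0.3) {
  stopifnot(length(preds) == length(gts))
  n_ok <- n_tot <- integer(10)
  complete <- logical(length(gts))
  for (i in seq_along(gts)) {
    g <- gts[[i]]
    p <- preds[[i]]
    if (is.null(p$confidence)) p$confidence <- 1
    all_ok <- TRUE
    for (cl in unique(g$class_id)) {
      n_tot[cl + 1L] <- n_tot[cl + 1L] + 1L
      gc <- g[g$class_id == cl, , drop = FALSE][1, ]
      pc <- p[p$class_id == cl, , drop = FALSE]
      ok <- FALSE
      if (nrow(pc)) {
        best <- pc[which.max(pc$confidence), ]
        ok <- box_iou(c(best$bx, best$by, best$bw, best$bh),
                      c(gc$bx, gc$by, gc$bw, gc$bh)) >= iou_success
      }
      if (ok) n_ok[cl + 1L] <- n_ok[cl + 1L] + 1L else all_ok <- FALSE
    }
    complete[i] <- all_ok
  }
  list(per_class = data.frame(class_id = 0:9, name = landet_classes(),
                              n = n_tot, detected = n_ok,
                              rate = ifelse(n_tot > 0, n_ok / n_tot, NA)),
       image_complete = mean(complete))
}

#' Agreement statistics for paired measure tables
#'
#' Computes, for each of the five spinopelvic measures, the MAE with SD,
#' Pearson correlation with p-value, RRMSE and accuracy between a
#' ground-truth table and a prediction table (rows paired by position).
#' Rows where either value is missing are dropped per measure.
#'
#' @param gt,pred Data frames with columns `ss_deg, pt_deg, pi_deg,
#'   ll_deg, sva`.
#' @return Data frame, one row per measure.
#' @export
evaluate_measures <- function(gt, pred) {
  stopifnot(nrow(gt) == nrow(pred))
  cols <- c(ss = "ss_deg", pt = "pt_deg", pi = "pi_deg", ll = "ll_deg",
            sva = "sva")
  rows <- lapply(names(cols), function(m) {
    y <- gt[[cols[[m]]]]; v <- pred[[cols[[m]]]]
    ok <- !is.na(y) & !is.na(v)
    y <- y[ok]; v <- v[ok]
    if (length(y) < 3)
      return(data.frame(measure = m, n = length(y), mae = NA, sd = NA,
                        r = NA, p = NA, rrmse = NA, accuracy = NA))
    ms <- mae_sd(y, v); pr <- pearson_r(y, v); rr <- rrmse(y, v)
    data.frame(measure = m, n = length(y), mae = ms[["mae"]],
               sd = ms[["sd"]], r = pr[["r"]], p = pr[["p"]], rrmse = rr,
               accuracy = (1 - rr) * 100)
  })
  do.call(rbind, rows)
}
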