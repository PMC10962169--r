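#' Fit the landmark detector
#'
#' Trains the dense anchor-based landmark detector on a set of labelled
#' images with the multi-task loss (objectness + box + class +
#' physics-informed pairwise constraints). Accepts either an in-memory
#' sample list (from [generate_samples()]) or a dataset directory written
#' by [generate_dataset()], in which case the `train` split is used.
#'
#' Optimisation is Adam with a linear warm-up followed by cosine decay.
#' With `flip_augment = TRUE` each image is presented mirrored with
#' probability 1/2 (labels mirrored exactly). Training is deterministic
#' under `seed`.
#'
#' @param data Sample list or dataset directory path.
#' @param preset Network preset, `"tiny"` or `"small"`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Images per gradient step.
#' @param lr Peak learning rate.
#' @param weights A [landet_loss_weights()]; `lambda_cnst = 0` gives the
#'   unconstrained ablation (the constraint components are still logged).
#' @param ratio_tolerance Anchor-match tolerance used for training-target
#'   assignment. The default (2.5) is tighter than the classical 4.0 so
#'   that the small spine boxes are only assigned to levels whose stride
#'   can resolve them; coarse-grid assignments of 6-7 px boxes produce
#'   confidently mislocalised duplicates that degrade the
#'   highest-confidence landmark selection.
#' @param flip_augment Random horizontal flips during training.
#' @param seed RNG seed for weight init, shuffling and flips.
#' @param net_widths Optional channel-width override, see [landet_net()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `"landet"` with elements `net`, `spec`,
#'   `weights`, `config`, `history` (per-epoch loss components).
#' @export
landet <- function(data, preset = "tiny", epochs = 60, batch_size = 8,
                   lr = 8e-3, weights = landet_loss_weights(),
                   ratio_tolerance = 2.5, flip_augment = TRUE, seed = 1,
                   net_widths = NULL, verbose = FALSE) {
  samples <- if (is.character(data)) load_dataset(data, split = "train")
    else data
  if (!length(samples)) stop("empty training set")
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  spec <- grid_spec(W, H, ratio_tolerance = ratio_tolerance)
  weights$n_b <- batch_size
  set.seed(seed)
  net <- landet_net(spec, preset, seed = seed, widths = net_widths)
  # precompute dense targets for both orientations once
  tg <- lapply(samples, function(s) build_targets(s$labels, spec))
  tg_flip <- NULL
  flipped <- NULL
  if (flip_augment) {
    flipped <- lapply(samples, function(s) {
      lab <- s$labels
      S <- max(W, H)
      lab$bx <- W / S - lab$bx
      # keep the smaller-x-first femoral-head convention after mirroring
      lab$class_id[lab$class_id == 0L] <- -1L
      lab$class_id[lab$class_id == 1L] <- 0L
      lab$class_id[lab$class_id == -1L] <- 1L
      lab <- lab[order(lab$class_id), , drop = FALSE]
      list(image = s$image[, W:1, drop = FALSE], labels = lab)
    })
    tg_flip <- lapply(flipped, function(s) build_targets(s$labels, spec))
  }
  n <- length(samples)
  steps <- max(1L, ceiling(n / batch_size))
  history <- NULL
  warmup <- min(3, max(1, epochs %/% 10))
  ema <- NULL
  ema_decay <- 0.99
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    lr_ep <- if (ep <= warmup) lr * ep / warmup else
      lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - warmup) /
                                           max(1, epochs - warmup))))
    ep_comp <- NULL; ep_total <- 0
    for (st in seq_len(steps)) {
      idx <- ord[((st - 1L) * batch_size + 1L):min(st * batch_size, n)]
      do_flip <- if (flip_augment) stats::runif(length(idx)) < 0.5
        else rep(FALSE, length(idx))
      imgs <- lapply(seq_along(idx), function(k)
        if (do_flip[k]) flipped[[idx[k]]]$image else samples[[idx[k]]]$image)
      tgts <- lapply(seq_along(idx), function(k)
        if (do_flip[k]) tg_flip[[idx[k]]] else tg[[idx[k]]])
      fwd <- net_forward_fast(net, imgs, train = TRUE)
      lg <- loss_and_grads(tgts, fwd$heads, weights)
      pgrads <- net_backward_fast(net, fwd, lg$grads)
      net <- adam_step(net, pgrads, lr_ep)
      net <- update_bn_stats_fast(net, fwd$stats)
      # exponential moving average of the weights, used at prediction time
      ema <- if (is.null(ema)) net$params else {
        d <- ema_decay * min(1, net$step / 100)
        mapply(function(e, p) {
          for (f in intersect(names(e), c("W", "b", "gamma", "beta")))
            e[[f]] <- d * e[[f]] + (1 - d) * p[[f]]
          e
        }, ema, net$params, SIMPLIFY = FALSE)
      }
      ep_total <- ep_total + lg$total / steps
      ep_comp <- if (is.null(ep_comp)) lg$components / steps
        else ep_comp + lg$components / steps
    }
    history <- rbind(history, data.frame(epoch = ep, lr = lr_ep,
                                         total = ep_total, t(ep_comp)))
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  total %.4f  obj %.4f box %.4f cls %.4f cnst %.4f/%.4f",
        ep, lr_ep, ep_total, ep_comp[["obj"]], ep_comp[["box"]],
        ep_comp[["cls"]], ep_comp[["cnst_angular"]],
        ep_comp[["cnst_distance"]]))
  }
  if (!is.null(ema)) {
    # EMA weights with the final running BN statistics
    for (nm in names(ema))
      for (f in c("rmean", "rvar"))
        if (!is.null(net$params[[nm]][[f]]))
          ema[[nm]][[f]] <- net$params[[nm]][[f]]
    net$raw_params <- net$params
    net$params <- ema
  }
  structure(list(net = net, spec = spec, weights = weights,
                 config = list(preset = preset, epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               flip_augment = flip_augment, seed = seed,
                               image_w = W, image_h = H),
                 history = history, call = match.call()),
            class = "landet")
}

#' Load a dataset directory into memory
#'
#' Reads images and labels referenced by `manifest.csv` under `dir`.
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param split `"train"`, `"val"`, `"test"` or `"all"`.
#' @return List of samples (`image`, `labels`, and `params` when
#'   `params.csv` is present).
#' @export
load_dataset <- function(dir, split = "all") {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  if (split != "all") man <- man[man$split == split, , drop = FALSE]
  params <- NULL
  pfile <- file.path(dir, "params.csv")
  if (file.exists(pfile)) {
    params <- utils::read.csv(pfile, stringsAsFactors = FALSE)
    rownames(params) <- params$id
  }
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(dir, man$image[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    id <- sub("\\.png$", "", basename(man$image[i]))
    list(image = img,
         labels = read_labels(file.path(dir, man$label[i])),
         params = if (!is.null(params)) params[id, ] else NULL,
         id = id, split = man$split[i])
  })
}

#' @export
print.landet <- function(x, ...) {
  cat("Landmark-as-object detector\n")
  cat(sprintf("  preset: %s, input %dx%d, %d epochs (batch %d, lr %.1e)\n",
              x$config$preset, x$config$image_w, x$config$image_h,
              x$config$epochs, x$config$batch_size, x$config$lr))
  cat(sprintf("  constraint weight lambda_cnst = %g\n",
              x$weights$lambda_cnst))
  lastrow <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss %.4f (obj %.4f, box %.4f, cls %.4f)\n",
              lastrow$total, lastrow$obj, lastrow$box, lastrow$cls))
  invisible(x)
}

#' @export
summary.landet <- function(object, ...) {
  print(object)
  cat("\nLoss history (first/last epochs):\n")
  h <- object$history
  print(utils::head(h, 2), row.names = FALSE, digits = 4)
  print(h[nrow(h), ], row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.landet <- function(object, ...) {
  unlist(lapply(object$net$params, function(p)
    unlist(p[names(p) %in% c("W", "b", "gamma", "beta")])))
}

#' @export
plot.landet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$obj, h$cls), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss",
                    main = "training loss", ...)
  graphics::legend("topright", c("total", "objectness", "class"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' @export
simulate.landet <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1
  generate_samples(nsim, seed = seed,
                   image_size = c(object$config$image_w,
                                  object$config$image_h), ...)
}

#' Predict landmarks and measures from images
#'
#' Runs the full prediction pipeline on new images: forward pass, grid
#' decoding, per-class non-maximum suppression, highest-confidence
#' landmark selection, and spinopelvic measure computation.
#'
#' @param object A fitted [landet()] model.
#' @param newdata A single image matrix, a list of image matrices, or a
#'   list of samples with an `image` element.
#' @param type `"measures"` (default; data frame, one row per image),
#'   `"landmarks"` (list of landmark sets + per-class reports), or
#'   `"detections"` (list of detection data frames after NMS).
#' @param conf_threshold Decoding confidence threshold. The prediction
#'   pipeline uses a permissive 0.1 (rather than the 0.25 decode default)
#'   so that every class keeps candidates for the highest-confidence
#'   selection step.
#' @param nms_iou NMS IoU threshold.
#' @param nms_per_class Suppress within classes only. The pipeline default
#'   is class-agnostic (`FALSE`): ground-truth landmark boxes of different
#'   classes never overlap at the NMS threshold by construction, so
#'   cross-class suppression removes only co-located duplicates carrying a
#'   confused class label — the dominant failure mode among adjacent
#'   endplate corners.
#' @param mm_per_pixel Optional calibration for SVA in mm.
#' @param batch Images per forward pass.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.landet <- function(object, newdata, type = c("measures", "landmarks",
                                                     "detections"),
                           conf_threshold = 0.1, nms_iou = 0.45,
                           nms_per_class = FALSE, mm_per_pixel = NULL,
                           batch = 16, ...) {
  type <- match.arg(type)
  imgs <- if (is.matrix(newdata)) list(newdata)
    else lapply(newdata, function(s) if (is.list(s)) s$image else s)
  dets <- vector("list", length(imgs))
  for (i0 in seq(1, length(imgs), by = batch)) {
    idx <- i0:min(i0 + batch - 1, length(imgs))
    fwd <- net_forward_fast(object$net, imgs[idx], train = FALSE)
    for (k in seq_along(idx))
      dets[[idx[k]]] <- nms(decode_predictions(fwd$heads[[k]], object$spec,
                                               conf_threshold), nms_iou,
                            per_class = nms_per_class)
  }
  if (type == "detections") return(dets)
  sel <- lapply(dets, select_landmarks, image_w = object$spec$image_w,
                image_h = object$spec$image_h)
  if (type == "landmarks") return(sel)
  out <- do.call(rbind, lapply(sel, function(s)
    as.data.frame(suppressWarnings(
      compute_measures(s$landmarks, mm_per_pixel)))))
  rownames(out) <- NULL
  out
}
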