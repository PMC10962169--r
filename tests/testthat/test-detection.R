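test_that("responsible cells use half-open boundaries", {
  expect_equal(responsible_cell(20, 12, 8, 16, 16), c(2, 1))
  expect_equal(responsible_cell(0, 0, 8, 16, 16), c(0, 0))
  expect_equal(responsible_cell(16, 16, 8, 16, 16), c(2, 2))
  expect_equal(responsible_cell(128, 128, 8, 16, 16), c(15, 15))
})

test_that("anchor matching is a strict worst-ratio test", {
  a <- cbind(w = c(26, 8, 5), h = c(26, 8, 5))
  m <- match_anchors(26, 26, a, ratio_tolerance = 4)
  expect_true(1 %in% m)
  expect_true(2 %in% m)   # 26/8 = 3.25 < 4
  expect_false(3 %in% m)  # 26/5 = 5.2 >= 4
  expect_length(match_anchors(26, 26, cbind(w = 6.5, h = 6.5), 4), 0)
})

test_that("targets assign the primary cell plus two side neighbours with a
          deterministic tie rule", {
  spec <- grid_spec(128, 128)
  lab <- data.frame(class_id = 3L, bx = 52.4 / 128, by = 67.7 / 128,
                    bw = 6.4 / 128, bh = 6.4 / 128)
  G <- build_targets(lab, spec)
  A <- G$assignments[[1]]
  prim <- A[A$primary, ]
  expect_equal(unique(prim$ix), 6)   # floor(52.4 / 8)
  expect_equal(unique(prim$iy), 8)
  cells <- unique(A[, c("ix", "iy")])
  expect_equal(nrow(cells), 3)
  # fx = 0.55 >= 0.5 -> right neighbour; fy = 0.4625 < 0.5 -> up neighbour
  expect_true(any(cells$ix == 7 & cells$iy == 8))
  expect_true(any(cells$ix == 6 & cells$iy == 7))
  # exact cell-centre tie: deterministic higher-index neighbours
  lab2 <- data.frame(class_id = 0L, bx = 56 / 128, by = 72 / 128,
                     bw = 14 / 128, bh = 14 / 128)
  A2 <- build_targets(lab2, spec)$assignments[[2]]
  cells2 <- unique(A2[, c("ix", "iy")])
  expect_equal(nrow(cells2), 3)
  # empty labels produce empty assignments
  G0 <- build_targets(empty_labels(), spec)
  expect_true(all(vapply(G0$assignments, is.null, logical(1))))
})

test_that("every matched label is recoverable from its encoded targets", {
  spec <- grid_spec(128, 128)
  set.seed(31)
  s <- generate_samples(5, seed = 31, image_size = c(128, 128))
  for (smp in s) {
    G <- build_targets(smp$labels, spec)
    for (l in 1:3) {
      A <- G$assignments[[l]]
      if (is.null(A)) next
      for (k in seq_len(nrow(A))) {
        dec <- landet:::decode_box(A$tx[k], A$ty[k], A$tw[k], A$th[k],
                                   A$ix[k], A$iy[k], spec$strides[l],
                                   spec$anchors[[l]][A$anchor[k], ])
        expect_equal(unname(dec["bx"]), A$bx_px[k], tolerance = 1e-6)
        expect_equal(unname(dec["by"]), A$by_px[k], tolerance = 1e-6)
        expect_equal(unname(dec["bw"]), A$bw_px[k], tolerance = 1e-6)
      }
    }
  }
})

test_that("decoding drops sub-threshold cells and keeps saturated ones", {
  spec <- grid_spec(128, 128)
  zero <- lapply(1:3, function(l)
    matrix(0, spec$n_anchor * spec$n_out, spec$grid_w[l] * spec$grid_h[l]))
  # all-zero logits: confidence = 0.5 * 0.5 = 0.25, not above 0.25
  expect_equal(nrow(decode_predictions(zero, spec)), 0)
  sat <- zero
  sat[[1]][5, 10] <- 50    # objectness of anchor 1
  sat[[1]][5 + 4, 10] <- 50  # class 3 (channel index 6 + 3)
  d <- decode_predictions(sat, spec)
  expect_equal(nrow(d), 1)
  expect_equal(d$class_id, 3)
  expect_gt(d$confidence, 0.99)
  bad <- zero; bad[[2]] <- bad[[2]][, 1:10]
  expect_error(decode_predictions(bad, spec), "shape mismatch")
})

test_that("NMS keeps the stronger of duplicates, keeps disjoint boxes, and
          resolves suppression chains greedily", {
  d <- data.frame(class_id = c(0, 0), bx = c(0.5, 0.5), by = c(0.5, 0.5),
                  bw = 0.1, bh = 0.1, confidence = c(0.9, 0.8))
  expect_equal(nms(d, 0.45)$confidence, 0.9)
  d2 <- data.frame(class_id = c(0, 0), bx = c(0.2, 0.8), by = 0.5,
                   bw = 0.1, bh = 0.1, confidence = c(0.9, 0.8))
  expect_equal(nrow(nms(d2, 0.45)), 2)
  # chain: A overlaps B, B overlaps C, A and C disjoint enough
  ch <- data.frame(class_id = 0, bx = c(0, 0.25, 0.5), by = 0,
                   bw = 1, bh = 1, confidence = c(0.9, 0.8, 0.7))
  out <- nms(ch, 0.5)
  expect_equal(out$confidence, c(0.9, 0.7))
})

test_that("NMS matches an independent greedy reference on random cases", {
  ref_nms <- function(d, thr) {
    keep <- integer()
    cand <- order(-d$confidence)
    while (length(cand)) {
      i <- cand[1]
      keep <- c(keep, i)
      cand <- cand[-1]
      if (!length(cand)) break
      drop <- vapply(cand, function(j) {
        d$class_id[j] == d$class_id[i] &&
          box_iou(as.numeric(d[i, c("bx", "by", "bw", "bh")]),
                  as.numeric(d[j, c("bx", "by", "bw", "bh")])) >= thr
      }, logical(1))
      cand <- cand[!drop]
    }
    sort(keep)
  }
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    d <- data.frame(class_id = sample(0:2, n, TRUE),
                    bx = runif(n), by = runif(n),
                    bw = runif(n, 0.05, 0.3), bh = runif(n, 0.05, 0.3),
                    confidence = runif(n))
    out <- nms(d, 0.4)
    expect_equal(sort(match(rownames(out), rownames(d))), ref_nms(d, 0.4))
  }
})

test_that("network output grids have the contractual shapes and the forward
          pass is deterministic and fast", {
  spec <- grid_spec(128, 128)
  net <- landet_net(spec, "tiny", seed = 3)
  img <- matrix(runif(128 * 128), 128, 128)
  f1 <- net_forward(net, list(img))
  expect_equal(vapply(f1$heads[[1]], ncol, numeric(1)),
               c(16 * 16, 8 * 8, 4 * 4))
  expect_equal(vapply(f1$heads[[1]], nrow, numeric(1)), rep(45, 3))
  f2 <- net_forward(net, list(img))
  expect_identical(f1$heads, f2$heads)
  spec2 <- grid_spec(160, 96)
  net2 <- landet_net(spec2, "tiny", seed = 3)
  img2 <- matrix(0.5, 96, 160)
  f3 <- net_forward(net2, list(img2))
  expect_equal(vapply(f3$heads[[1]], ncol, numeric(1)),
               c(20 * 12, 10 * 6, 5 * 3))
  expect_error(net_forward(net, list(matrix(0, 100, 100))), "grid spec")
  t0 <- Sys.time()
  invisible(net_forward(net, list(img)))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 0.25)
})

test_that("detection counts are invariant to constant intensity rescaling
          after input normalisation", {
  set.seed(12)
  s <- generate_samples(1, seed = 12)[[1]]
  spec <- grid_spec(128, 128)
  net <- landet_net(spec, "tiny", seed = 1)
  d1 <- decode_predictions(net_forward(net, list(s$image))$heads[[1]], spec,
                           conf_threshold = 0.1)
  d2 <- decode_predictions(net_forward(net, list(s$image * 0.6))$heads[[1]],
                           spec, conf_threshold = 0.1)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$class_id, d2$class_id)
})

test_that("the compiled single-precision path matches the reference
          implementation", {
  set.seed(13)
  s <- generate_samples(2, seed = 13)
  spec <- grid_spec(128, 128)
  net <- landet_net(spec, "tiny", seed = 2)
  imgs <- lapply(s, `[[`, "image")
  fR <- net_forward(net, imgs, train = TRUE)
  fF <- landet:::net_forward_fast(net, imgs, train = TRUE)
  for (b in 1:2) for (l in 1:3) {
    sc <- max(1, max(abs(fR$heads[[b]][[l]])))
    expect_lt(max(abs(fR$heads[[b]][[l]] - fF$heads[[b]][[l]])) / sc, 1e-4)
  }
  tg <- lapply(s, function(x) build_targets(x$labels, spec))
  lg <- landet:::loss_and_grads(tg, fF$heads, landet_loss_weights(n_b = 2))
  gR <- landet:::net_backward(net, fR, lg$grads)
  gF <- landet:::net_backward_fast(net, fF, lg$grads)
  for (nm in names(gF)) {
    for (f in intersect(names(gF[[nm]]), c("dW", "dgamma", "dbeta", "W",
                                           "b"))) {
      a <- as.numeric(gR[[nm]][[f]]); b2 <- as.numeric(gF[[nm]][[f]])
      expect_lt(max(abs(a - b2)) / max(1e-6, max(abs(a))), 5e-3)
    }
  }
})
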