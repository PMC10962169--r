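test_that("rrmse endpoints and hand oracle", {
  y <- c(0, 1, 2, 3)
  expect_equal(rrmse(y, y), 0)
  expect_equal(rrmse(y, rep(mean(y), 4)), 1)
  expect_equal(rrmse(y, c(0.5, 1.5, 1.5, 2.5)), 0.5 / sqrt(1.25),
               tolerance = 1e-12)
  expect_error(rrmse(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("accuracy is (1 - rrmse) * 100, identically", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(10); v <- y + rnorm(10, 0, runif(1, 0.1, 3))
    expect_equal(accuracy(y, v) + 100 * rrmse(y, v), 100, tolerance = 1e-10)
  }
  y <- c(0, 1, 2, 3)
  expect_equal(accuracy(y, y), 100)
  expect_lt(accuracy(y, -5 * y), 0)  # worse than useless, reported as-is
})

test_that("rrmse is invariant under simultaneous affine transforms", {
  set.seed(5)
  y <- rnorm(30, 40, 10); v <- y + rnorm(30, 0, 4)
  expect_equal(rrmse(2.5 * y + 7, 2.5 * v + 7), rrmse(y, v),
               tolerance = 1e-12)
})

test_that("MAE and its spread", {
  y <- c(5, 5); v <- c(6, 8)
  ms <- mae_sd(y, v)
  expect_equal(unname(ms), c(2, sqrt(2)))
  expect_equal(unname(mae_sd(y, v, convention = "n")), c(2, 1))
  expect_equal(mae_sd(y, 2 * y - v + 2 * (v - y)), mae_sd(y, v))
  expect_equal(unname(mae_sd(y, y)), c(0, 0))
})

test_that("pearson r matches cor.test on random data and hits the affine
          endpoints", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(unname(pearson_r(y, 2 * y + 3)[["r"]]), 1)
  expect_equal(unname(pearson_r(y, -y)[["r"]]), -1)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(15); b <- a * runif(1, -2, 2) + rnorm(15)
    ref <- stats::cor.test(a, b)
    pr <- pearson_r(a, b)
    expect_equal(pr[["r"]], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(pr[["p"]], ref$p.value, tolerance = 1e-9)
  }
  set.seed(12)
  r0 <- pearson_r(rnorm(10000), rnorm(10000))
  expect_lt(abs(r0[["r"]]), 0.05)
})

test_that("single-rating consistency ICC matches a brute-force
          sums-of-squares oracle", {
  icc_oracle <- function(rt) {
    N <- nrow(rt); m <- ncol(rt)
    grand <- mean(rt)
    ssb <- 0; ssw <- 0
    for (i in 1:N) {
      si <- mean(rt[i, ])
      ssb <- ssb + m * (si - grand)^2
      for (j in 1:m) ssw <- ssw + (rt[i, j] - si)^2
    }
    msbs <- ssb / (N - 1); msws <- ssw / (N * (m - 1))
    (msbs - msws) / (msbs + (m - 1) * msws)
  }
  # perfect agreement
  rt <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_equal(icc(rt), 1)
  # identical subjects, pure rater noise: at or below zero
  set.seed(21)
  rt2 <- matrix(rnorm(300), 100, 3)
  expect_lt(icc(rt2), 0.1)
  # constructed 4 x 3 table vs the oracle
  rt3 <- matrix(c(9, 10, 8, 6, 5, 7, 12, 11, 13, 2, 3, 1), 4, 3,
                byrow = TRUE)
  expect_equal(icc(rt3), icc_oracle(rt3), tolerance = 1e-10)
  # property: 100 random tables
  set.seed(22)
  for (i in 1:100) {
    N <- sample(3:12, 1); m <- sample(2:5, 1)
    subj <- rnorm(N, 0, runif(1, 0.1, 5))
    rt <- matrix(subj, N, m) + matrix(rnorm(N * m, 0, runif(1, 0.1, 2)),
                                      N, m)
    expect_equal(icc(rt), icc_oracle(rt), tolerance = 1e-10)
  }
  expect_error(icc(matrix(1, 3, 3)), "degenerate")
})

test_that("mAP endpoints, a hand-computed PR case, and threshold
          monotonicity", {
  fx <- fixture_anatomy()
  gt <- boxes_from_landmarks(fx$landmarks, 128, 128)
  perfect <- transform(gt, confidence = 1)
  expect_equal(map_at_iou(list(perfect), list(gt), 0.5)$map, 1)
  expect_equal(map_at_iou(list(empty_labels(TRUE)), list(gt), 0.5)$map, 0)
  # 1 GT, 2 predictions: TP (IoU 0.6, conf 0.9) outranks the FP -> AP 1
  g <- data.frame(class_id = 0L, bx = 0.5, by = 0.5, bw = 0.1, bh = 0.1)
  p <- data.frame(class_id = 0L,
                  bx = c(0.5 + 0.1 / 4, 0.9), by = c(0.5, 0.9),
                  bw = 0.1, bh = 0.1, confidence = c(0.9, 0.8))
  expect_gt(box_iou(c(p$bx[1], 0.5, 0.1, 0.1), c(0.5, 0.5, 0.1, 0.1)), 0.5)
  expect_equal(map_at_iou(list(p), list(g), 0.5)$map, 1)
  # reversing the ranks drops AP below 1
  p2 <- transform(p, confidence = c(0.8, 0.9))
  expect_lt(map_at_iou(list(p2), list(g), 0.5)$map, 1)
  # monotone non-increasing in the IoU threshold
  set.seed(31)
  s <- generate_samples(3, seed = 31)
  gts <- lapply(s, `[[`, "labels")
  preds <- lapply(gts, function(g) {
    d <- transform(g, bx = bx + runif(10, -0.01, 0.01),
                   by = by + runif(10, -0.01, 0.01),
                   confidence = runif(10, 0.5, 1))
    d
  })
  maps <- vapply(seq(0.5, 0.95, 0.05), function(t)
    map_at_iou(preds, gts, t)$map, numeric(1))
  expect_true(all(diff(maps) <= 1e-12))
  expect_equal(map_at_iou(preds, gts, seq(0.5, 0.95, 0.05))$map, mean(maps),
               tolerance = 1e-12)
})

test_that("detection success uses the 0.3 IoU criterion exactly", {
  fx <- fixture_anatomy()
  gt <- boxes_from_landmarks(fx$landmarks, 128, 128)
  perfect <- transform(gt, confidence = 1)
  dr <- detection_rate(list(perfect), list(gt))
  expect_true(all(dr$per_class$rate == 1))
  expect_equal(dr$image_complete, 1)
  # one class never predicted: that class 0, image-complete 0
  dr2 <- detection_rate(list(perfect[perfect$class_id != 4, ]), list(gt))
  expect_equal(dr2$per_class$rate[dr2$per_class$class_id == 4], 0)
  expect_equal(dr2$image_complete, 0)
  # boxes straddling the threshold: only IoU >= 0.3 counts
  # equal squares shifted by d have IoU (a-d)/(a+d) in 1D; in 2D with
  # dy = 0: iou = (a-d)*a / (2*a^2 - (a-d)*a)
  a <- 0.05
  iou_1d <- function(d) (a - d) * a / (2 * a^2 - (a - d) * a)
  d_lo <- uniroot(function(d) iou_1d(d) - 0.29, c(0, a))$root
  d_hi <- uniroot(function(d) iou_1d(d) - 0.31, c(0, a))$root
  g <- data.frame(class_id = 0L, bx = 0.5, by = 0.5, bw = a, bh = a)
  mk <- function(d) transform(g, bx = bx + d, confidence = 1)
  expect_equal(detection_rate(list(mk(d_lo)), list(g))$per_class$rate[1], 0)
  expect_equal(detection_rate(list(mk(d_hi)), list(g))$per_class$rate[1], 1)
})

test_that("evaluate_measures summarises paired tables per measure", {
  set.seed(41)
  gt <- data.frame(ss_deg = rnorm(12, 39, 10), pt_deg = rnorm(12, 19, 9),
                   pi_deg = NA, ll_deg = rnorm(12, 46, 16),
                   sva = abs(rnorm(12, 35, 3)))
  gt$pi_deg <- gt$ss_deg + gt$pt_deg
  pred <- gt + rnorm(12 * 5, 0, 1)
  names(pred) <- names(gt)
  em <- evaluate_measures(gt, pred)
  expect_equal(em$measure, c("ss", "pt", "pi", "ll", "sva"))
  expect_equal(em$accuracy + 100 * em$rrmse, rep(100, 5))
  expect_true(all(em$r > 0.9))
  em0 <- evaluate_measures(gt, gt)
  expect_true(all(em0$mae == 0))
  expect_true(all(em0$accuracy == 100))
})
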