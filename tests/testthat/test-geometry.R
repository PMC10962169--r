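test_that("circumcircle recovers centre and radius", {
  cc <- circumcircle(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(cc$center, c(0, 0), tolerance = 1e-12)
  expect_equal(cc$radius, 1, tolerance = 1e-12)

  cc <- circumcircle(c(0, 0), c(2, 0), c(1, 1))
  expect_equal(cc$center, c(1, 0), tolerance = 1e-12)
  expect_equal(cc$radius, 1, tolerance = 1e-12)

  # round-trip: three points sampled from a known circle
  set.seed(42)
  for (i in 1:20) {
    ctr <- c(37.2, 81.5); r <- 12.25
    th <- sort(runif(3, 0, 2 * pi))
    cc <- circumcircle(ctr + r * c(cos(th[1]), sin(th[1])),
                       ctr + r * c(cos(th[2]), sin(th[2])),
                       ctr + r * c(cos(th[3]), sin(th[3])))
    expect_equal(cc$center, ctr, tolerance = 1e-9)
    expect_equal(cc$radius, r, tolerance = 1e-9)
  }
  expect_error(circumcircle(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("hip axis is the femoral-head midpoint", {
  expect_equal(hip_axis(c(0, 0), c(10, 0)), c(5, 0))
  expect_equal(hip_axis(c(3, 4), c(3, 4)), c(3, 4))
  expect_equal(hip_axis(c(12.5, 80), c(17.5, 84)), c(15, 82))
})

test_that("signed inclination is positive when the endplate descends
          anteriorly and lies in (-90, 90]", {
  expect_equal(signed_inclination(c(0, 0), c(10, 0), 1), 0)
  # anterior point superior (smaller y) -> negative under this convention
  expect_equal(signed_inclination(c(0, 0), c(10, -10), 1), -45)
  expect_equal(signed_inclination(c(0, 0), c(10, 10), 1), 45)
  expect_equal(signed_inclination(c(100, 200), c(140, 170), 1),
               atan2(-30, 40) * 180 / pi)
  # facing correction: mirrored points give the identical angle
  expect_equal(signed_inclination(c(0, 0), c(-10, 10), -1), 45)
  expect_error(signed_inclination(c(1, 1), c(1, 1), 1), "coincident")
})

test_that("measures round-trip through the constructive anatomy", {
  fx <- fixture_anatomy(ss = 38.9, pt = 19.3, ll = 46.2, sva = 34.9)
  m <- compute_measures(fx$landmarks)
  expect_equal(m$ss_deg, 38.9, tolerance = 1e-9)
  expect_equal(m$pt_deg, 19.3, tolerance = 1e-9)
  expect_equal(m$pi_deg, 38.9 + 19.3, tolerance = 1e-9)
  expect_equal(m$ll_deg, 46.2, tolerance = 1e-9)
  expect_equal(m$sva_signed, 34.9, tolerance = 1e-9)
  expect_equal(m$sva, 34.9, tolerance = 1e-9)
})

test_that("pelvic tilt signs and degenerate cases", {
  fx0 <- fixture_anatomy(pt = 0)
  m <- compute_measures(fx0$landmarks)
  expect_equal(m$pt_deg, 0, tolerance = 1e-9)
  fx45 <- fixture_anatomy(ss = 30, pt = 45)
  expect_equal(pelvic_tilt(fx45$landmarks), 45, tolerance = 1e-9)
})

test_that("constructive PI oracle: ss 30 + pt 15 gives PI 45", {
  fx <- fixture_anatomy(ss = 30, pt = 15)
  expect_equal(pelvic_incidence(fx$landmarks), 45, tolerance = 1e-9)
})

test_that("lumbar lordosis is the absolute inclination difference", {
  fx <- fixture_anatomy(ll = 45)
  lm <- fx$landmarks
  i5 <- signed_inclination(lm$points["l5_post", ], lm$points["l5_ant", ],
                           lm$facing)
  i1 <- signed_inclination(lm$points["l1_post", ], lm$points["l1_ant", ],
                           lm$facing)
  expect_equal(abs(i1 - i5), 45, tolerance = 1e-9)
  expect_equal(lumbar_lordosis(lm), 45, tolerance = 1e-9)
})

test_that("SVA arithmetic and calibration", {
  pts <- list(fh1 = c(40, 100), fh2 = c(50, 102), s1_post = c(220, 60),
              s1_ant = c(236, 66), l5_post = c(218, 50), l5_ant = c(234, 52),
              l1_post = c(214, 20), l1_ant = c(230, 18),
              c7_post = c(255, 8), c7_ant = c(265, 9))
  lm <- make_lmset(pts)
  sv <- sagittal_vertical_axis(lm)
  expect_equal(sv$sva_signed, (255 + 265) / 2 - 220)
  expect_equal(sagittal_vertical_axis(lm, mm_per_pixel = 0.25)$sva_signed,
               ((255 + 265) / 2 - 220) * 0.25)
  # C7 midpoint directly above the S1 posterior corner
  pts$c7_post <- c(215, 8); pts$c7_ant <- c(225, 8)
  expect_equal(sagittal_vertical_axis(make_lmset(pts))$sva, 0)
})

test_that("PI = PT + SS holds to 1e-6 degrees on random anatomies", {
  set.seed(7)
  p <- sample_anatomy(50, "ds1")
  for (i in seq_len(nrow(p))) {
    m <- compute_measures(landmarks_from_params(p[i, ]))
    expect_lt(abs(m$pi_deg - (m$pt_deg + m$ss_deg)), 1e-6)
  }
})

test_that("measures are invariant to translation, scaling and mirroring;
          SVA scales linearly", {
  set.seed(8)
  p <- sample_anatomy(5, "ds1")
  for (i in seq_len(nrow(p))) {
    lm <- landmarks_from_params(p[i, ])
    m0 <- compute_measures(lm)
    tr <- landet:::transform_landmarks(lm, function(q) q + c(13.5, -7.25))
    m1 <- compute_measures(tr)
    for (f in c("ss_deg", "pt_deg", "pi_deg", "ll_deg", "sva"))
      expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9)
    sc <- landet:::transform_landmarks(lm, function(q) q * 2.5,
                                       radius_scale = 2.5)
    m2 <- compute_measures(sc)
    for (f in c("ss_deg", "pt_deg", "pi_deg", "ll_deg"))
      expect_equal(m2[[f]], m0[[f]], tolerance = 1e-9)
    expect_equal(m2$sva, 2.5 * m0$sva, tolerance = 1e-9)
    mi <- compute_measures(mirror_landmarks(lm, 128))
    for (f in c("ss_deg", "pt_deg", "pi_deg", "ll_deg", "sva"))
      expect_equal(mi[[f]], m0[[f]], tolerance = 1e-9)
  }
})

test_that("rigid rotation shifts SS and PT by the angle but leaves PI", {
  fx <- fixture_anatomy(ss = 35, pt = 18)
  lm <- fx$landmarks
  H <- hip_axis(lm$points["fh1", ], lm$points["fh2", ])
  th <- 5 * pi / 180
  rot <- landet:::transform_landmarks(lm, function(q) {
    d <- q - H
    H + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  })
  m0 <- compute_measures(lm)
  m1 <- suppressWarnings(compute_measures(rot))
  expect_equal(m1$pi_deg, m0$pi_deg, tolerance = 1e-6)
  expect_equal(abs(m1$ss_deg - m0$ss_deg), 5, tolerance = 1e-6)
  expect_equal(abs(m1$pt_deg - m0$pt_deg), 5, tolerance = 1e-6)
})

test_that("missing landmarks degrade per-measure, strict mode errors", {
  fx <- fixture_anatomy()
  pts <- fx$landmarks$points
  pts[c("fh1", "fh2"), ] <- NA_real_
  lm <- landmark_set(pts, c(NA, NA))
  m <- compute_measures(lm)
  expect_true(is.na(m$pt_deg) && is.na(m$pi_deg))
  expect_false(is.na(m$ss_deg) || is.na(m$ll_deg) || is.na(m$sva))
  expect_error(compute_measures(lm, strict = TRUE), "fh1")
})

test_that("landmark CSV round-trips", {
  fx <- fixture_anatomy()
  path <- tempfile(fileext = ".csv")
  write_landmarks(fx$landmarks, path)
  back <- read_landmarks(path)
  expect_equal(back$points, fx$landmarks$points)
  expect_equal(back$fh_radius, fx$landmarks$fh_radius)
  expect_equal(back$facing, fx$landmarks$facing)
})
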