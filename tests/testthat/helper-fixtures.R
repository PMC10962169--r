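# Shared fixtures: a hand-placed, internally consistent landmark set and a
# convenience constructor for landmark sets from a point list.

make_lmset <- function(pts, fh_radius = c(7, 7), facing = NULL) {
  m <- do.call(rbind, pts[landet_classes()])
  landmark_set(m, fh_radius, facing)
}

# anatomy constructed from known measures (uses the generator)
fixture_anatomy <- function(ss = 38.9, pt = 19.3, ll = 46.2, sva = 34.9,
                            size = c(128, 128)) {
  p <- sample_anatomy(1, population = list(
    mean = c(ss = ss, pt = pt, ll = ll, sva = sva),
    sd = c(ss = 0, pt = 0, ll = 0, sva = 0)), image_size = size, jitter = 0)
  list(params = p, landmarks = landmarks_from_params(p))
}

# Shared scaffolding: one synthetic image's targets plus prediction grids
# set to exactly reproduce them ("perfect" logits).
make_perfect <- function(seed = 20) {
  spec <- grid_spec(128, 128)
  s <- generate_samples(1, seed = seed)[[1]]
  G <- build_targets(s$labels, spec)
  zero <- lapply(1:3, function(l)
    matrix(0, spec$n_anchor * spec$n_out, spec$grid_w[l] * spec$grid_h[l]))
  perf <- lapply(zero, function(m) { m[] <- -50; m })
  for (l in 1:3) {
    A <- G$assignments[[l]]
    if (is.null(A)) next
    for (k in seq_len(nrow(A))) {
      r <- landet:::anchor_rows(A$anchor[k], spec$n_out)
      col <- landet:::cell_col(A$ix[k], A$iy[k], spec$grid_h[l])
      perf[[l]][r[1:4], col] <- c(A$tx[k], A$ty[k], A$tw[k], A$th[k])
      perf[[l]][r[5], col] <- 50
      perf[[l]][r[5 + 1 + A$class_id[k]], col] <- 50
    }
  }
  list(spec = spec, G = G, zero = zero, perfect = perf, sample = s)
}
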