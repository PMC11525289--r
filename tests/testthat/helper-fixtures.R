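# shared fixtures, built in code at test time

# binary disc mask of given pixel diameter, centred in a square canvas
disc_mask <- function(diameter_px, pad = 6L) {
  r <- diameter_px / 2
  n <- ceiling(diameter_px) + 2L * pad
  c0 <- (n + 1) / 2
  xy <- expand.grid(y = 1:n, x = 1:n)
  matrix((xy$x - c0)^2 + (xy$y - c0)^2 <= r^2, n, n)
}

# two discs of radius r with centres dist apart (fused when dist < 2r)
dumbbell_mask <- function(r = 20, dist = 30, pad = 10L) {
  W <- ceiling(dist + 2 * r) + 2L * pad
  H <- ceiling(2 * r) + 2L * pad
  cy <- (H + 1) / 2
  cx1 <- pad + r; cx2 <- cx1 + dist
  xy <- expand.grid(y = 1:H, x = 1:W)
  matrix((xy$x - cx1)^2 + (xy$y - cy)^2 <= r^2 |
           (xy$x - cx2)^2 + (xy$y - cy)^2 <= r^2, H, W)
}

# axis-aligned solid rectangle mask
rect_mask <- function(w, h, pad = 4L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# independent O(n^2) oracle: max pairwise distance over a point set
brute_force_max_dist <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# corner points of all TRUE pixels of a mask (same convention as the
# measurement path, but assembled independently)
mask_corner_points <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  x <- rc[, 2]; y <- rc[, 1]
  cbind(c(x - 0.5, x - 0.5, x + 0.5, x + 0.5),
        c(y - 0.5, y + 0.5, y - 0.5, y + 0.5))
}

# random rasterised blob mask (seeded by caller)
random_blob_mask <- function(size_px = 40, n = 64L) {
  th <- seq(0, 2 * pi, length.out = 200)
  r <- size_px / 2 * (1 + 0.2 * cos(2 * th + runif(1, 0, 2 * pi)) +
                        0.1 * cos(3 * th + runif(1, 0, 2 * pi)))
  c0 <- n / 2
  xy <- expand.grid(y = 1:n, x = 1:n)
  ang <- atan2(xy$y - c0, xy$x - c0)
  rad <- sqrt((xy$x - c0)^2 + (xy$y - c0)^2)
  rb <- approx(th, r, xout = ang %% (2 * pi), rule = 2)$y
  matrix(rad <= rb, n, n)
}

# flat image of one colour
flat_image <- function(rgb_col, H = 20L, W = 20L, px = 1.5) {
  arr <- array(rep(rgb_col, each = H * W), dim = c(H, W, 3))
  filter_image(arr, px)
}

# independent Dunn oracle: explicit scalar loops, no shared code with
# compare_groups()
dunn_oracle <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  rk <- rank(values)
  gs <- sort(unique(groups))
  tie_tab <- table(values)
  tie_sum <- sum(sapply(tie_tab, function(t) t^3 - t))
  s2 <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  out <- NULL
  for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
    ri <- mean(rk[groups == gs[i]]); rj <- mean(rk[groups == gs[j]])
    ni <- sum(groups == gs[i]); nj <- sum(groups == gs[j])
    z <- (ri - rj) / sqrt(s2 * (1 / ni + 1 / nj))
    out <- rbind(out, data.frame(group1 = gs[i], group2 = gs[j], z = z,
                                 p_unadj = 2 * (1 - pnorm(abs(z)))))
  }
  out$p_adj <- p.adjust(out$p_unadj, "holm")
  out
}

# small distractor-free calibration scene shared across tests
make_test_scene <- function(seed = 11, halo = 4, n_px = 420L,
                            density = 22,
                            sizes = c(12, min(120, n_px * 1.5 / 4))) {
  generate_scene(scene_spec(width_px = n_px, height_px = n_px,
                            halo_width_um = halo,
                            twp_density_per_mm2 = density,
                            twp_size_range_um = sizes,
                            rng_seed = seed))
}
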