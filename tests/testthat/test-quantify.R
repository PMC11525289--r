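test_that("LOD/LOQ follow the blank formula with the operational floor", {
  b0 <- blank_stats(c(0, 0, 0))
  expect_equal(b0$mean_blank, 0)
  expect_equal(b0$sd_blank, 0)
  expect_equal(b0$LOD, 1)              # floored at 1 particle per subsample
  expect_equal(b0$LOQ, 1)
  b2 <- blank_stats(c(2, 2, 2))
  expect_equal(b2$LOD, 2)              # zero variance: LOD = LOQ = mean
  expect_equal(b2$LOQ, 2)
  b <- blank_stats(c(1, 2, 3))
  expect_equal(b$mean_blank, 2)
  expect_equal(b$sd_blank, 1)
  expect_equal(b$LOD, 5)               # mean + 3 sd
  expect_equal(b$LOQ, 12)              # mean + 10 sd
  expect_lte(b$LOD, b$LOQ)
  expect_error(blank_stats(c(-1, 0)), "nonnegative")
  expect_error(blank_stats(numeric(0)), "at least one")
})

test_that("LOD never exceeds LOQ and both respect the floor across random blanks", {
  set.seed(201)
  for (i in 1:50) {
    b <- blank_stats(rpois(sample(1:6, 1), lambda = runif(1, 0, 3)))
    expect_lte(b$LOD, b$LOQ)
    expect_gte(b$LOD, b$operational_resolution)
  }
})

test_that("concentration extrapolation matches the per-kg scaling", {
  cc <- concentration(40.4, mass_g = 5)
  expect_equal(cc$concentration_per_kg, 8080)   # ~40 particles in 5 g
  expect_equal(concentration(c(0, 0, 0), 7)$concentration_per_kg, 0)
  a <- concentration(c(30, 40, 50), 5)
  b <- concentration(c(30, 40, 50), 10)
  expect_equal(a$concentration_per_kg, 2 * b$concentration_per_kg)
  expect_equal(a$se_per_kg, sd(c(30, 40, 50)) / sqrt(3) * 200)
  expect_error(concentration(10, 0), "mass_g")
})

test_that("cumulative distributions step correctly and respect their supports", {
  df <- data.frame(id = 1:1, pixel_count = 10, area_um2 = 22.5,
                   perimeter_um = 20, FD_um = 120, mFD_um = 100,
                   circularity = 0.8, centroid_x_um = 1, centroid_y_um = 1)
  tab <- twpscan:::.as_particle_table(df, 1.5)
  cd <- cumulative_distributions(tab)
  expect_equal(cd$FD$value, 120)
  expect_equal(cd$FD$cumfreq, 1)                 # single step 0 -> 1
  sc <- make_test_scene(seed = 41, n_px = 360L, density = 20)
  tab2 <- detect_particles(sc$image)
  cd2 <- cumulative_distributions(tab2)
  expect_true(all(diff(cd2$FD$cumfreq) >= 0))
  expect_equal(max(cd2$FD$cumfreq), 1)
  expect_true(all(cd2$circularity$value > 0 & cd2$circularity$value <= 1))
  empty <- twpscan:::.as_particle_table(df[0, ], 1.5)
  expect_warning(cd0 <- cumulative_distributions(empty), "empty")
  expect_equal(nrow(cd0$FD), 0)
})

test_that("uniform sizes give an empirical CDF within the Kolmogorov bound", {
  set.seed(42)
  n <- 400
  fd <- runif(n, 50, 150)
  df <- data.frame(id = seq_len(n), pixel_count = 10, area_um2 = 1,
                   perimeter_um = 1, FD_um = fd, mFD_um = fd * 0.8,
                   circularity = 0.9, centroid_x_um = 0, centroid_y_um = 0)
  cd <- cumulative_distributions(twpscan:::.as_particle_table(df, 1.5))
  theo <- (cd$FD$value - 50) / 100
  expect_lt(max(abs(cd$FD$cumfreq - theo)), 1.63 / sqrt(n))  # K-S 1% bound
})

test_that("Kruskal-Wallis H matches the hand-computed rank statistic", {
  gt <- compare_groups(c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(gt$H, 7.2)              # exact rank formula, no ties
  expect_equal(gt$df, 2)
  # identical groups: H ~ 0, adjusted p ~ 1
  same <- compare_groups(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$H, 1e-9)
  expect_true(all(same$pairwise$p_adj > 0.99))
  # permutation within groups leaves H unchanged
  g2 <- compare_groups(c(3, 2, 1, 12, 10, 11, 22, 21, 20),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(g2$H, gt$H)
  expect_error(compare_groups(1:5, c("a", "a", "b", "b", "c")), "c")
})

test_that("group tests agree with reference implementations including ties", {
  set.seed(301)
  for (i in 1:5) {
    vals <- c(rpois(6, 10), rpois(5, 12), rpois(7, 9))
    grp <- rep(c("g1", "g2", "g3"), c(6, 5, 7))
    gt <- compare_groups(vals, grp)
    kw <- kruskal.test(vals, factor(grp))
    expect_equal(gt$H, unname(kw$statistic), tolerance = 1e-12)
    expect_equal(gt$p_value, kw$p.value, tolerance = 1e-12)
    oracle <- dunn_oracle(vals, grp)
    expect_equal(gt$pairwise$z, oracle$z, tolerance = 1e-12)
    expect_equal(gt$pairwise$p_adj, oracle$p_adj, tolerance = 1e-12)
  }
})

test_that("the ellipsoid mass model reduces to the sphere and scales linearly", {
  df <- data.frame(id = 1, pixel_count = 1, area_um2 = 1, perimeter_um = 1,
                   FD_um = 100, mFD_um = 100, circularity = 1,
                   centroid_x_um = 0, centroid_y_um = 0)
  tab <- twpscan:::.as_particle_table(df, 1.5)
  m <- estimate_mass(tab, density_g_cm3 = 1.2, thickness_k = 1, mass_g = 5)
  sphere_mg <- (pi / 6) * 100^3 * 1e-12 * 1.2 * 1000
  expect_equal(m$total_mass_mg, sphere_mg)
  expect_equal(m$mass_mg_per_kg, sphere_mg * 200)
  expect_equal(m$model$name, "ellipsoid")
  m2 <- estimate_mass(tab, density_g_cm3 = 2.4, thickness_k = 1, mass_g = 5)
  expect_equal(m2$total_mass_mg, 2 * m$total_mass_mg)
  empty <- twpscan:::.as_particle_table(df[0, ], 1.5)
  expect_equal(estimate_mass(empty)$total_mass_mg, 0)
})
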