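test_that("matching is exact on identical tables and empty beyond the radius", {
  ref <- data.frame(centroid_x_um = c(10, 50, 90), centroid_y_um = c(10, 50, 90),
                    true_mFD_um = c(20, 30, 40))
  det <- data.frame(centroid_x_um = ref$centroid_x_um,
                    centroid_y_um = ref$centroid_y_um, mFD_um = ref$true_mFD_um)
  mm <- match_particles(ref, det)
  expect_equal(nrow(mm$matches), 3)
  expect_length(mm$misses, 0)
  expect_length(mm$false_positives, 0)
  far <- det; far$centroid_x_um <- far$centroid_x_um + 100
  mm2 <- match_particles(ref, far, max_dist_um = 20)
  expect_equal(nrow(mm2$matches), 0)
  expect_length(mm2$misses, 3)
})

test_that("greedy matching agrees with the exhaustive optimal assignment on small cases", {
  ref <- data.frame(centroid_x_um = c(0, 10, 30), centroid_y_um = c(0, 0, 0),
                    true_mFD_um = c(20, 20, 20))
  det <- data.frame(centroid_x_um = c(2, 11), centroid_y_um = c(0, 0),
                    mFD_um = c(20, 20))
  mm <- match_particles(ref, det, max_dist_um = 15)
  expect_equal(nrow(mm$matches), 2)
  expect_length(mm$misses, 1)
  # exhaustive oracle: all one-to-one assignments of 2 detections to 3 refs
  dmat <- outer(ref$centroid_x_um, det$centroid_x_um,
                function(a, b) abs(a - b))
  combos <- expand.grid(r1 = 1:3, r2 = 1:3)
  combos <- combos[combos$r1 != combos$r2, ]
  costs <- apply(combos, 1, function(cc) dmat[cc[1], 1] + dmat[cc[2], 2])
  best <- combos[which.min(costs), ]
  got <- mm$matches[order(mm$matches$det_idx), "ref_idx"]
  expect_equal(got, as.numeric(best))
})

test_that("accuracy of a particle measured against itself is exactly 100", {
  ref <- data.frame(centroid_x_um = 1:20 * 10, centroid_y_um = rep(5, 20),
                    true_mFD_um = seq(20, 210, 10))
  det <- data.frame(centroid_x_um = ref$centroid_x_um,
                    centroid_y_um = ref$centroid_y_um, mFD_um = ref$true_mFD_um)
  pairs <- accuracy_pairs(match_particles(ref, det), ref, det)
  expect_true(all(pairs$accuracy_pct == 100))
})

test_that("the LOESS curve is flat on constant accuracy and tracks a smooth trend", {
  pairs <- data.frame(reference_mFD_um = seq(10, 100, length.out = 40),
                      measured_mFD_um = NA, accuracy_pct = 100)
  cv <- accuracy_curve(pairs)
  expect_true(all(abs(cv$accuracy_pct - 100) < 1e-6))
  expect_error(accuracy_curve(pairs, span = 1.5), "span")
  expect_error(accuracy_curve(pairs[1:5, ]), "at least 10")
  # noiseless hinge: curve within ~1% away from the break
  x <- seq(5, 100, length.out = 120)
  y <- ifelse(x < 25, 90 - 4 * (25 - x), 90)
  p2 <- data.frame(reference_mFD_um = x, measured_mFD_um = NA, accuracy_pct = y)
  p2 <- rbind(p2, p2[60, ])                     # duplicate x must not error
  cv2 <- accuracy_curve(p2, span = 0.3)
  away <- cv2$mFD_um > 40
  expect_lt(max(abs(cv2$accuracy_pct[away] - 90)), 1)
})

test_that("the segmented fit recovers a known breakpoint", {
  set.seed(101)
  x <- runif(120, 5, 100)
  y <- ifelse(x < 25, 90 - 4 * (25 - x), 90) + rnorm(120, 0, 2)
  fit <- fit_breakpoint(data.frame(reference_mFD_um = x, measured_mFD_um = NA,
                                   accuracy_pct = y))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$breakpoint_um - 25), 3)
  expect_lt(abs(fit$plateau_pct - 90), 2)
  expect_gt(fit$slope_pre, 2)
})

test_that("degenerate accuracy data is flagged, not silently fitted", {
  set.seed(102)
  x <- runif(60, 5, 100)
  line <- data.frame(reference_mFD_um = x, measured_mFD_um = NA,
                     accuracy_pct = 50 + 0.5 * x + rnorm(60, 0, 0.5))
  expect_true(fit_breakpoint(line)$degenerate)
  plateau <- data.frame(reference_mFD_um = x, measured_mFD_um = NA,
                        accuracy_pct = 90 + rnorm(60, 0, 0.5))
  expect_true(fit_breakpoint(plateau)$degenerate)
})

test_that("recovery arithmetic, monotonicity and scale invariance hold", {
  truth <- data.frame(replicate = rep(1, 20), mFD_um = seq(10, 200, 10))
  # perfect detection
  perfect <- recovery_curve(truth, truth, thresholds = c(10, 35, 50))
  expect_true(all(perfect$mean_recovery_pct == 100))
  # 17 of 20 detected above 35 (drop three of the largest)
  det <- truth[truth$mFD_um >= 35, ][1:14, ]
  cv <- recovery_curve(truth, det, thresholds = 35)
  expect_equal(cv$mean_recovery_pct, 100 * 14 / sum(truth$mFD_um >= 35))
  # detection missing only particles < 35 um -> recovery nondecreasing in t
  det2 <- truth[truth$mFD_um >= 35, ]
  cv2 <- recovery_curve(truth, det2, thresholds = seq(10, 60, 5))
  expect_true(all(diff(cv2$mean_recovery_pct) >= -1e-9))
  # doubling both truth and detections leaves recovery unchanged
  t2 <- rbind(truth, truth); d2 <- rbind(det2, det2)
  cv3 <- recovery_curve(t2, d2, thresholds = seq(10, 60, 5))
  expect_equal(cv3$mean_recovery_pct, cv2$mean_recovery_pct)
  # threshold with no true particles above it is dropped with a warning
  expect_warning(recovery_curve(truth, det2, thresholds = c(35, 500)),
                 "dropped")
})

test_that("the recovery rule picks the first threshold at or above the floor", {
  curve <- structure(data.frame(threshold_um = c(25, 35, 45),
                                mean_recovery_pct = c(70, 85, 90),
                                sd_pct = 0, se_pct = 0, n_replicates = 3),
                     class = c("recovery_curve", "data.frame"))
  expect_equal(select_size_limit(curve, 80), 35)
  expect_equal(select_size_limit(curve, 60), 25)
  low <- curve; low$mean_recovery_pct <- c(50, 60, 70)
  expect_warning(lim <- select_size_limit(low, 80), "no threshold")
  expect_true(is.na(lim))
})

test_that("replicate recovery means and spread are computed across spikes", {
  truth <- data.frame(replicate = rep(1:3, each = 10),
                      mFD_um = rep(seq(20, 200, 20), 3))
  det <- truth[-c(1, 11, 12, 21), ]     # miss 1, 2 and 1 particles
  cv <- recovery_curve(truth, det, thresholds = 20)
  expect_equal(cv$mean_recovery_pct, mean(c(90, 80, 90)))
  expect_equal(cv$sd_pct, sd(c(90, 80, 90)))
  expect_equal(cv$n_replicates, 3)
})

test_that("calibration diagnostics export a plot file", {
  set.seed(103)
  x <- runif(40, 5, 100)
  pairs <- data.frame(reference_mFD_um = x, measured_mFD_um = NA,
                      accuracy_pct = ifelse(x < 25, 60, 90) + rnorm(40))
  curve <- structure(data.frame(threshold_um = c(25, 35), mean_recovery_pct = c(70, 85),
                                sd_pct = 1, se_pct = 0.5, n_replicates = 3),
                     class = c("recovery_curve", "data.frame"))
  td <- withr::local_tempdir()
  p <- plot_calibration(pairs, curve, fit_breakpoint(pairs),
                        path = file.path(td, "cal.png"))
  expect_true(file.exists(p))
})
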