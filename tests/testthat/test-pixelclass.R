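test_that("features on a constant image are constant with zero gradient", {
  img <- flat_image(c(120, 140, 160), H = 24, W = 24)
  f <- extract_features(img, scales = c(1, 2))
  inner <- function(name) {      # away from borders, where padding acts
    m <- matrix(f[, name], 24, 24)
    as.vector(m[8:16, 8:16])
  }
  expect_true(all(abs(inner("R_g1") - 120) < 1e-6))
  expect_true(all(abs(inner("B_g2") - 160) < 1e-6))
  expect_true(all(abs(inner("grad")) < 1e-6))
  expect_true(all(f[, "darkness"] == 120))
  expect_error(extract_features(img, scales = numeric(0)), "nonempty")
})

test_that("darkness feature is 0 for black and 255 for white pixels", {
  expect_true(all(extract_features(flat_image(c(0, 0, 0)), scales = 1)[, "darkness"] == 0))
  expect_true(all(extract_features(flat_image(c(255, 255, 255)), scales = 1)[, "darkness"] == 255))
})

test_that("Gaussian feature of an impulse matches the closed-form kernel", {
  H <- 31L
  arr <- array(0, dim = c(H, H, 3)); arr[16, 16, ] <- 255
  f <- extract_features(filter_image(arr, 1.5), scales = 2)
  g <- matrix(f[, "R_g2"], H, H)
  # discrete Gaussian oracle: separable normalised kernel, same support
  k <- dnorm(-15:15, sd = 2); k <- k / sum(k)
  oracle <- 255 * outer(k, k)
  expect_lt(max(abs(g - oracle)), 255 * 1e-4)
})

test_that("label sets are validated", {
  expect_error(label_set(1:3, 1:3, c("TWP", "TWP", "TWP")), "both classes")
  expect_error(label_set(c(1, 1), c(2, 2), c("TWP", "background")),
               "two different classes")
  expect_error(label_set(1, 99, c("TWP"), image_dim = c(10, 10)))
  ls <- label_set(c(1, 2), c(1, 2), c("TWP", "background"), c(10, 10))
  expect_s3_class(ls, "label_set")
})

test_that("a separable black-vs-blue problem is learned perfectly and reproducibly", {
  set.seed(21)
  H <- 60L
  arr <- array(0, dim = c(H, H, 3))
  for (ch in 1:3) arr[, , ch] <- c(190, 205, 225)[ch] + rnorm(H * H, 0, 4)
  arr[20:40, 20:40, ] <- runif(21 * 21 * 3, 5, 35)
  img <- filter_image(pmin(pmax(round(arr), 0), 255), 1.5)
  f <- extract_features(img, scales = 1)
  labs <- label_set(x = c(seq(21, 39, 2), seq(2, 18, 2), seq(44, 58, 2)),
                    y = c(seq(21, 39, 2), seq(2, 18, 2), seq(44, 58, 2)),
                    class = rep(c("TWP", "background"), c(10, 17)))
  m1 <- train_classifier(f, labs, seed = 5)
  expect_equal(m1$oob_accuracy, 1)
  c1 <- classify(img, m1)
  c2 <- classify(img, train_classifier(f, labs, seed = 5))
  expect_identical(c1$prob, c2$prob)       # same seed, same prediction
  expect_true(all(c1$class[25:35, 25:35])) # core is TWP
  expect_false(any(c1$class[1:15, 1:15]))  # background is background
  # a mislabelled pixel lowers accuracy without crashing
  labs_bad <- labs; labs_bad$class[11] <- "TWP"   # a blue pixel mislabelled
  m2 <- train_classifier(f, labs_bad, seed = 5)
  expect_lt(m2$oob_accuracy, 1)
  expect_error(train_classifier(f, labs, seed = 1, min_per_class = 20),
               "per class")
})

test_that("exclusion beats classification and white images are background", {
  img <- flat_image(c(255, 255, 255), H = 10, W = 10)
  cm <- classify(img, rule_classifier())
  expect_false(any(cm$class))
  dark <- flat_image(c(10, 10, 10), H = 10, W = 10)
  excl <- matrix(FALSE, 10, 10); excl[1:5, ] <- TRUE
  dark$exclusion_mask <- excl
  cm2 <- classify(dark, rule_classifier())
  expect_false(any(cm2$class[1:5, ]))
  expect_true(all(cm2$class[6:10, ]))
})

test_that("IsoData threshold sits between the modes of a bimodal histogram", {
  # oracle: direct fixed-point iteration on the histogram
  counts <- integer(256)
  counts[26] <- 500   # value 25  (prob 0.1 scaled)
  counts[231] <- 300  # value 230 (prob 0.9 scaled)
  t_or <- 127.5
  repeat {
    v <- 0:255
    lo <- v <= t_or
    m1 <- sum(v[lo] * counts[lo]) / max(1, sum(counts[lo]))
    m2 <- sum(v[!lo] * counts[!lo]) / max(1, sum(counts[!lo]))
    tn <- (m1 + m2) / 2
    if (abs(tn - t_or) < 1e-9) break
    t_or <- tn
  }
  t_pkg <- isodata_threshold(counts)
  expect_lt(abs(t_pkg - t_or), 1)
  expect_gt(t_pkg, 25); expect_lt(t_pkg, 230)
})

test_that("binarize maps {0,1} probabilities to the hard class map and warns on degenerate input", {
  prob <- matrix(c(0, 1, 1, 0, 1, 0), 2, 3)
  cm <- structure(list(prob = prob, class = prob >= 0.5, pixel_size_um = 1.5),
                  class = "class_map")
  expect_identical(binarize(cm), cm$class, ignore_attr = TRUE)
  flat <- structure(list(prob = matrix(0.4, 3, 3), class = matrix(FALSE, 3, 3),
                         pixel_size_um = 1.5), class = "class_map")
  expect_warning(mask <- binarize(flat), "degenerate")
  expect_false(any(mask))
})

test_that("core TWP pixels are recovered with >= 99% recall and precision on a clean scene", {
  sc <- make_test_scene(seed = 31, n_px = 360L, density = 18)
  set.seed(31)
  labs <- sample_labels(sc, 300)
  f <- extract_features(sc$image)
  clf <- train_classifier(f, labs, seed = 31)
  cm <- classify(sc$image, clf)
  chmax <- pmax(sc$image$rgb[, , 1],
                pmax(sc$image$rgb[, , 2], sc$image$rgb[, , 3]))
  core <- chmax <= 40            # rendered black cores
  expect_gte(sum(cm$class & core) / sum(core), 0.99)        # recall
  # the one-pixel band around the core (core/halo transition) is
  # undefined territory; precision is judged outside it
  band <- EBImage::dilate(core, EBImage::makeBrush(3, "box")) & !core
  confident <- cm$class & !band
  expect_gte(sum(confident & core) / max(1, sum(confident)), 0.99) # precision
})

test_that("coloured organic distractors yield no TWP pixels when labelled background", {
  sc <- generate_scene(scene_spec(width_px = 360L, height_px = 360L,
                                  twp_density_per_mm2 = 12,
                                  organic_density_per_mm2 = 12, rng_seed = 32))
  set.seed(32)
  labs <- sample_labels(sc, 300)
  clf <- train_classifier(extract_features(sc$image), labs, seed = 32)
  cm <- classify(sc$image, clf)
  org <- sc$truth[sc$truth$class == "organic", ]
  H <- dim(sc$image$rgb)[1]; W <- dim(sc$image$rgb)[2]
  xy <- expand.grid(y = 1:H, x = 1:W)
  hit <- 0; tot <- 0
  for (i in seq_len(nrow(org))) {
    r <- org$true_FD_um[i] / 2 / 1.5
    inside <- matrix((xy$x - org$centroid_x_px[i])^2 +
                       (xy$y - org$centroid_y_px[i])^2 <= r^2, H, W)
    hit <- hit + sum(cm$class & inside); tot <- tot + sum(inside)
  }
  expect_lt(hit / tot, 0.005)
})
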