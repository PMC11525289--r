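#' Sparse pixel labels for classifier training
#'
#' Validates a set of sparse pixel annotations marking black particles as
#' potential tire-wear particles and everything else (filter background,
#' coloured particles) as background.
#'
#' @param x,y 1-based pixel column/row coordinates.
#' @param class character vector, `"TWP"` or `"background"`.
#' @param image_dim `c(H, W)` of the source image, for bounds checking.
#' @return data frame of class `label_set`.
#' @export
label_set <- function(x, y, class, image_dim = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(class))
  class <- as.character(class)
  if (!all(class %in% c("TWP", "background")))
    stop("class must be 'TWP' or 'background'")
  if (!all(c("TWP", "background") %in% class))
    stop("both classes must be represented in the label set")
  if (!is.null(image_dim)) {
    if (any(x < 1 | x > image_dim[2] | y < 1 | y > image_dim[1]))
      stop("label coordinates outside the image")
  }
  key <- paste(x, y)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup) && length(unique(paste(key, class)[dup])) > length(unique(key[dup])))
    stop("a pixel is labelled with two different classes")
  structure(data.frame(x = as.integer(x), y = as.integer(y), class = class,
                       stringsAsFactors = FALSE),
            class = c("label_set", "data.frame"))
}

#' Per-pixel feature stack for trainable segmentation
#'
#' Computes the feature set used by the pixel classifier: the raw R, G, B
#' channels, per-channel Gaussian smoothings at each requested scale,
#' the gradient magnitude of the luminance, 3x3 local minimum and maximum
#' of the luminance (texture), and the per-pixel channel minimum (a
#' darkness feature: 0 for pure black, 255 for pure white).
#'
#' @param image a [filter_image].
#' @param scales numeric vector of Gaussian smoothing radii in pixels
#'   (nonempty).
#' @return numeric matrix, one row per pixel in column-major image order,
#'   with named feature columns; attribute `dim_hw` gives `c(H, W)` and
#'   attribute `scales` the smoothing radii.
#' @export
extract_features <- function(image, scales = c(1, 2, 4)) {
  stopifnot(inherits(image, "filter_image"))
  if (length(scales) == 0) stop("scales must be a nonempty list of smoothing radii")
  H <- dim(image$rgb)[1]; W <- dim(image$rgb)[2]
  ch <- list(R = image$rgb[, , 1], G = image$rgb[, , 2], B = image$rgb[, , 3])
  lum <- (ch$R + ch$G + ch$B) / 3
  feats <- list(R = ch$R, G = ch$G, B = ch$B)
  for (s in scales) for (nm in names(ch))
    feats[[sprintf("%s_g%g", nm, s)]] <- EBImage::gblur(ch[[nm]], sigma = s)
  gl <- EBImage::gblur(lum, sigma = min(scales))
  gx <- cbind(gl[, 2] - gl[, 1], (gl[, -(1:2), drop = FALSE] -
              gl[, seq_len(W - 2), drop = FALSE]) / 2, gl[, W] - gl[, W - 1])
  gy <- rbind(gl[2, ] - gl[1, ], (gl[-(1:2), , drop = FALSE] -
              gl[seq_len(H - 2), , drop = FALSE]) / 2, gl[H, ] - gl[H - 1, ])
  feats$grad <- sqrt(gx^2 + gy^2)
  br <- EBImage::makeBrush(3, "box")
  feats$local_min <- EBImage::erode(lum, br)
  feats$local_max <- EBImage::dilate(lum, br)
  feats$darkness <- pmin(ch$R, pmin(ch$G, ch$B))
  out <- vapply(feats, as.numeric, numeric(H * W))
  attr(out, "dim_hw") <- c(H, W)
  attr(out, "scales") <- scales
  out
}

#' Train the pixel classifier
#'
#' Fits a random forest (100 trees) on the labelled pixels only, the
#' programmatic counterpart of training a trainable-segmentation model
#' from sparse annotations. Training is reproducible under a fixed seed,
#' and the out-of-bag label accuracy is reported with the model.
#'
#' @param features feature stack from [extract_features()].
#' @param labels a [label_set()] (or data frame with `x`, `y`, `class`).
#' @param seed integer training seed.
#' @param num_trees number of trees (default 100).
#' @param min_per_class minimum labelled pixels required per class
#'   (default 10).
#' @return object of class `twp_classifier` carrying the forest, the
#'   feature configuration (enforced at prediction) and `oob_accuracy`.
#' @export
train_classifier <- function(features, labels, seed = 1L, num_trees = 100L,
                             min_per_class = 10L) {
  hw <- attr(features, "dim_hw")
  if (is.null(hw)) stop("features must come from extract_features()")
  cls <- factor(labels$class, levels = c("background", "TWP"))
  if (nlevels(droplevels(cls)) < 2L)
    stop("labels must contain both classes")
  if (any(table(cls) < min_per_class))
    stop("need at least ", min_per_class, " labelled pixels per class")
  idx <- (labels$x - 1L) * hw[1] + labels$y
  df <- as.data.frame(features[idx, , drop = FALSE])
  df$.class <- cls
  fit <- with_seed(seed,
    ranger::ranger(dependent.variable.name = ".class", data = df,
                   num.trees = num_trees, probability = TRUE,
                   seed = seed, num.threads = 1L))
  oob_hard <- colnames(fit$predictions)[max.col(fit$predictions)]
  structure(list(type = "forest", forest = fit,
                 feature_config = list(scales = attr(features, "scales"),
                                       features = colnames(features)),
                 classes = c("background", "TWP"), seed = seed,
                 oob_accuracy = mean(oob_hard == as.character(cls))),
            class = "twp_classifier")
}

#' Rule-based darkness classifier
#'
#' A transparent fallback for the trained forest: a pixel is a tire-wear
#' particle candidate iff all three channels lie at or below the darkness
#' cap (it is black). Useful for headless runs and as a deterministic
#' baseline; the trained forest is the default path.
#'
#' @param darkness_cap 8-bit threshold (default 40).
#' @return object of class `twp_classifier`.
#' @export
rule_classifier <- function(darkness_cap = 40) {
  structure(list(type = "rule", darkness_cap = darkness_cap,
                 feature_config = list(scales = numeric(0)),
                 classes = c("background", "TWP")),
            class = "twp_classifier")
}

#' @export
print.twp_classifier <- function(x, ...) {
  if (x$type == "forest")
    cat(sprintf("<twp_classifier> random forest, %d trees, OOB accuracy %.3f\n",
                x$forest$num.trees, x$oob_accuracy))
  else
    cat(sprintf("<twp_classifier> rule: all channels <= %g => TWP\n",
                x$darkness_cap))
  invisible(x)
}

#' Classify every pixel of a filter image
#'
#' Produces a per-pixel tire-wear-particle probability raster and a hard
#' class raster. Pixels under the image's exclusion mask are forced to
#' background regardless of the model output (exclusion beats
#' classification).
#'
#' @param image a [filter_image].
#' @param model a `twp_classifier` from [train_classifier()] or
#'   [rule_classifier()].
#' @return object of class `class_map`: list with `prob` (H x W matrix of
#'   TWP probability in 0..1), `class` (logical H x W, `TRUE` = TWP) and
#'   the pixel size.
#' @export
classify <- function(image, model) {
  stopifnot(inherits(image, "filter_image"), inherits(model, "twp_classifier"))
  H <- dim(image$rgb)[1]; W <- dim(image$rgb)[2]
  if (model$type == "rule") {
    chmax <- pmax(image$rgb[, , 1], pmax(image$rgb[, , 2], image$rgb[, , 3]))
    prob <- matrix(as.numeric(chmax <= model$darkness_cap), H, W)
  } else {
    feats <- extract_features(image, scales = model$feature_config$scales)
    if (!identical(colnames(feats), model$feature_config$features))
      stop("image features do not match the model's feature configuration")
    pred <- predict(model$forest, data = as.data.frame(feats),
                    num.threads = 1L, seed = model$seed)
    prob <- matrix(pred$predictions[, "TWP"], H, W)
  }
  if (!is.null(image$exclusion_mask)) prob[image$exclusion_mask] <- 0
  structure(list(prob = prob, class = prob >= 0.5,
                 pixel_size_um = image$pixel_size_um),
            class = "class_map")
}

#' IsoData automatic threshold of a class map
#'
#' Converts the probability raster to 8 bits and applies the IsoData
#' (ridler-calvard iterative intermeans) automatic threshold: starting
#' from the mid-grey, the threshold is repeatedly replaced by the mean of
#' the average foreground and average background intensities until it
#' stabilises. Polarity is fixed so that TWP pixels are the foreground.
#'
#' @param class_map result of [classify()].
#' @return logical matrix, `TRUE` = TWP foreground; attribute
#'   `threshold_8bit` records the threshold used. A degenerate
#'   single-valued probability raster yields an empty mask with a warning.
#' @export
binarize <- function(class_map) {
  stopifnot(inherits(class_map, "class_map"))
  p8 <- round(class_map$prob * 255)
  if (length(unique(as.vector(p8))) < 2L) {
    warning("degenerate probability raster (single value): empty mask")
    out <- matrix(FALSE, nrow(p8), ncol(p8))
    attr(out, "threshold_8bit") <- NA_real_
    return(out)
  }
  thr <- isodata_threshold(tabulate(as.vector(p8) + 1L, nbins = 256L))
  out <- p8 > thr
  if (!any(out)) warning("empty foreground after thresholding")
  attr(out, "threshold_8bit") <- thr
  out
}

#' IsoData threshold of a 256-bin histogram
#'
#' @param counts integer vector of length 256 (counts for values 0..255).
#' @return threshold `t`; foreground is `value > t`.
#' @export
isodata_threshold <- function(counts) {
  stopifnot(length(counts) == 256L)
  v <- 0:255
  t <- sum(v * counts) / sum(counts)   # start at global mean
  repeat {
    lo <- v <= t
    m1 <- if (any(counts[lo] > 0)) sum(v[lo] * counts[lo]) / sum(counts[lo]) else 0
    m2 <- if (any(counts[!lo] > 0)) sum(v[!lo] * counts[!lo]) / sum(counts[!lo]) else 255
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t) < 0.5) return(t_new)
    t <- t_new
  }
}

#' Sample training labels from a synthetic scene
#'
#' Emulates the sparse manual annotations used to train the pixel
#' classifier: black pixels inside rendered particles are labelled TWP,
#' and a mixture of background, halo and coloured-distractor pixels is
#' labelled background. Draws from R's current RNG stream.
#'
#' @param scene result of [generate_scene()].
#' @param n_per_class labels per class (default 400).
#' @param darkness_cap 8-bit cap defining "black" for the TWP labels.
#' @return a [label_set()].
#' @export
sample_labels <- function(scene, n_per_class = 400L, darkness_cap = 40) {
  rgb <- scene$image$rgb
  chmax <- pmax(rgb[, , 1], pmax(rgb[, , 2], rgb[, , 3]))
  dark <- which(chmax <= darkness_cap)
  light <- which(chmax > darkness_cap)
  if (length(dark) == 0) stop("scene contains no black pixels to label")
  H <- dim(rgb)[1]
  di <- sample(dark, min(n_per_class, length(dark)))
  li <- sample(light, min(n_per_class, length(light)))
  idx <- c(di, li)
  label_set(x = (idx - 1L) %/% H + 1L, y = (idx - 1L) %% H + 1L,
            class = rep(c("TWP", "background"), c(length(di), length(li))),
            image_dim = dim(rgb)[1:2])
}
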