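#' Synthetic filter-scene specification
#'
#' Describes a seeded synthetic filter image: a pale bluish filter
#' background with low-amplitude noise, opaque black tire-wear particles
#' whose outer rim is replaced by chromatic diffraction colours (the
#' blue/yellow/red halo that strips black pixels from small particles),
#' and optional distractors — coloured organic matter and black angular
#' charcoal. The generator emits exact ground truth for every rendered
#' particle, so every downstream stage can be validated against known
#' sizes and positions.
#'
#' Defaults mirror the reference acquisition: 1.5 um/pixel, a 4 um halo
#' (small particles lose most of their black core, large ones barely
#' notice), and tire-wear particle sizes drawn log-uniformly between 10
#' and 200 um minimum Feret diameter.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size, um per pixel.
#' @param background_rgb length-3 base colour of the filter (pale blue).
#' @param background_noise_sd per-pixel Gaussian noise SD (8-bit counts).
#' @param halo_width_um width of the chromatic diffraction rim eating into
#'   each black particle, in um; 0 disables the halo.
#' @param twp_density_per_mm2 number density of tire-wear particles.
#' @param twp_size_range_um range of true minimum Feret diameters (um),
#'   sampled log-uniformly.
#' @param organic_density_per_mm2,charcoal_density_per_mm2 distractor
#'   number densities (coloured organic blobs; black angular charcoal).
#' @param organic_size_range_um,charcoal_size_range_um distractor sizes.
#' @param darkness_cap 8-bit ceiling below which all three channels of a
#'   rendered "black" pixel stay (rendering convention).
#' @param allow_overlap if `FALSE` (default) particle interiors are kept
#'   pairwise disjoint by bounding-circle separation.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   image and ground truth.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 600L, height_px = 600L, pixel_size_um = 1.5,
                       background_rgb = c(190, 205, 225),
                       background_noise_sd = 4,
                       halo_width_um = 4,
                       twp_density_per_mm2 = 12,
                       twp_size_range_um = c(10, 200),
                       organic_density_per_mm2 = 0,
                       charcoal_density_per_mm2 = 0,
                       organic_size_range_um = c(30, 150),
                       charcoal_size_range_um = c(20, 120),
                       darkness_cap = 40,
                       allow_overlap = FALSE,
                       rng_seed = 1L) {
  stopifnot(width_px > 0, height_px > 0, pixel_size_um > 0,
            halo_width_um >= 0, length(background_rgb) == 3,
            background_noise_sd >= 0,
            twp_density_per_mm2 >= 0, organic_density_per_mm2 >= 0,
            charcoal_density_per_mm2 >= 0,
            length(twp_size_range_um) == 2, twp_size_range_um[1] > 0,
            diff(twp_size_range_um) >= 0, darkness_cap > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 background_rgb = background_rgb,
                 background_noise_sd = background_noise_sd,
                 halo_width_um = halo_width_um,
                 twp_density_per_mm2 = twp_density_per_mm2,
                 twp_size_range_um = twp_size_range_um,
                 organic_density_per_mm2 = organic_density_per_mm2,
                 charcoal_density_per_mm2 = charcoal_density_per_mm2,
                 organic_size_range_um = organic_size_range_um,
                 charcoal_size_range_um = charcoal_size_range_um,
                 darkness_cap = darkness_cap,
                 allow_overlap = isTRUE(allow_overlap),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# ---- analytic shapes -------------------------------------------------------
# All shapes are star-shaped polygons around their own origin, described by
# `n` boundary vertices; true Feret diameters are computed on the analytic
# polygon *before* rasterisation, so ground truth is exact.

.shape_polygon <- function(shape, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- switch(shape,
    ellipse = {
      b <- 1; a <- runif(1, 1, 2.2)
      a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    },
    superellipse = {
      b <- 1; a <- runif(1, 1, 1.8); p <- runif(1, 1.5, 4)
      (abs(cos(th) / a)^p + abs(sin(th) / b)^p)^(-1 / p)
    },
    blob = {
      k <- 2:5
      amp <- runif(4, 0, 0.15 / (k / 2))
      ph <- runif(4, 0, 2 * pi)
      1 + rowSums(vapply(1:4, function(i) amp[i] * cos(k[i] * th + ph[i]),
                         numeric(length(th))))
    },
    charcoal = {
      # angular fragment: few vertices with jittered radii, linear chords;
      # bounded angular jitter keeps every gap < pi, so the polygon stays
      # star-shaped around its origin and the radial form is valid
      nv <- sample(5:8, 1)
      va <- sort((2 * pi * (seq_len(nv) - 1 + runif(nv, -0.3, 0.3)) / nv) %% (2 * pi))
      vr <- runif(nv, 0.55, 1)
      .poly_radius(va, vr, th)
    },
    stop("unknown shape '", shape, "'"))
  cbind(x = r * cos(th), y = r * sin(th))
}

# radius of the chord polygon (vertex angles va, radii vr) along angles th
.poly_radius <- function(va, vr, th) {
  m <- length(va)
  va2 <- c(va, va[1] + 2 * pi); vr2 <- c(vr, vr[1])
  thm <- th %% (2 * pi)
  thm[thm < va[1]] <- thm[thm < va[1]] + 2 * pi
  i <- findInterval(thm, va2, rightmost.closed = TRUE)
  i[i < 1] <- 1; i[i > m] <- m
  t1 <- va2[i]; t2 <- va2[i + 1]; r1 <- vr2[i]; r2 <- vr2[i + 1]
  num <- r1 * r2 * sin(t2 - t1)
  den <- r1 * sin(thm - t1) + r2 * sin(t2 - thm)
  out <- num / den
  out[den <= .Machine$double.eps] <- r1[den <= .Machine$double.eps]
  out
}

.rotate <- function(poly, deg) {
  a <- deg * pi / 180
  cbind(x = poly[, 1] * cos(a) - poly[, 2] * sin(a),
        y = poly[, 1] * sin(a) + poly[, 2] * cos(a))
}

# ---- halo rendering --------------------------------------------------------

#' Render a black particle with a chromatic diffraction rim
#'
#' Takes a particle mask and paints the outer `halo_width_um` band with
#' saturated blue/yellow/red pixels while the remaining interior stays
#' strictly black (all channels below the darkness cap). This is the halo
#' model: the microscope's light diffraction replaces the rim of small
#' dark particles with chromatic pixels, so a colour-based classifier only
#' sees the shrunken black core — the mechanism behind the size-dependent
#' undersizing of small particles. A halo at least as wide as the particle
#' radius legally produces a particle with no black pixels at all (an
#' undetectable particle).
#'
#' Erosion depth is computed on the Euclidean distance transform, so
#' non-integer halo widths are honoured. Pixel values are drawn from R's
#' current RNG stream; seed the caller for reproducibility.
#'
#' @param mask logical matrix, `TRUE` inside the particle; must be
#'   nonempty.
#' @param halo_width_um halo width in um (`>= 0`).
#' @param pixel_size_um physical pixel size in um.
#' @param darkness_cap 8-bit ceiling for "black" pixel values.
#' @return `H x W x 3` array; `NA` outside the particle, chromatic values
#'   on the rim, black values on the core. Attribute `core` holds the
#'   logical core mask.
#' @export
render_halo <- function(mask, halo_width_um, pixel_size_um, darkness_cap = 40) {
  stopifnot(is.matrix(mask), halo_width_um >= 0, pixel_size_um > 0)
  mask <- mask & TRUE
  if (!any(mask)) stop("mask is empty")
  halo_px <- halo_width_um / pixel_size_um
  core <- if (halo_px == 0) mask else {
    dm <- EBImage::distmap(mask)
    mask & (dm > halo_px)
  }
  rim <- mask & !core
  patch <- array(NA_real_, dim = c(dim(mask), 3L))
  nc <- sum(core)
  if (nc > 0) {
    base <- runif(nc, 5, darkness_cap - 8)
    for (ch in 1:3) {
      pl <- patch[, , ch]
      pl[core] <- clamp(base + rnorm(nc, 0, 3), 0, darkness_cap)
      patch[, , ch] <- pl
    }
  }
  nr <- sum(rim)
  if (nr > 0) {
    palette <- rbind(c(40, 70, 220),   # blue
                     c(235, 205, 50),  # yellow
                     c(215, 45, 45))   # red
    pick <- sample.int(3L, nr, replace = TRUE)
    for (ch in 1:3) {
      pl <- patch[, , ch]
      pl[rim] <- clamp(palette[pick, ch] + rnorm(nr, 0, 10), 0, 255)
      patch[, , ch] <- pl
    }
  }
  attr(patch, "core") <- core
  patch
}

# ---- scene generation ------------------------------------------------------

#' Generate a synthetic filter image with exact ground truth
#'
#' Renders tire-wear particles (black core plus chromatic diffraction
#' halo), charcoal distractors (black, angular, internally grey-textured)
#' and organic distractors (coloured blobs) on a noisy pale-blue filter
#' background, and returns the image together with a ground-truth table
#' holding each particle's exact minimum/maximum Feret diameters (computed
#' from the analytic boundary before rasterisation), centroid, class and
#' orientation.
#'
#' @param spec a [scene_spec].
#' @param particles optional data frame overriding random particle
#'   sampling, with columns `mFD_um`, and optionally `class`
#'   (`"TWP"`/`"charcoal"`/`"organic"`, default TWP), `shape`,
#'   `orientation_deg`; placement is still random.
#' @return list with elements `image` (a [filter_image]) and `truth`
#'   (class `ground_truth_table`: one row per rendered particle with
#'   `id, class, shape, true_mFD_um, true_FD_um, orientation_deg,
#'   centroid_x_px, centroid_y_px, centroid_x_um, centroid_y_um`; the
#'   generating spec attached as attribute `scene_spec`).
#' @export
generate_scene <- function(spec, particles = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, .generate_scene_impl(spec, particles))
}

.generate_scene_impl <- function(spec, particles) {
  H <- spec$height_px; W <- spec$width_px; px <- spec$pixel_size_um
  area_mm2 <- H * W * px^2 / 1e6

  # background: pale blue + iid Gaussian noise
  rgb <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- clamp(spec$background_rgb[ch] +
                           rnorm(H * W, 0, spec$background_noise_sd), 0, 255)

  # particle roster
  if (is.null(particles)) {
    n_twp <- round(spec$twp_density_per_mm2 * area_mm2)
    n_org <- round(spec$organic_density_per_mm2 * area_mm2)
    n_cha <- round(spec$charcoal_density_per_mm2 * area_mm2)
    lu <- function(n, rg) exp(runif(n, log(rg[1]), log(rg[2])))
    particles <- data.frame(
      class = rep(c("TWP", "charcoal", "organic"), c(n_twp, n_cha, n_org)),
      mFD_um = c(lu(n_twp, spec$twp_size_range_um),
                 lu(n_cha, spec$charcoal_size_range_um),
                 lu(n_org, spec$organic_size_range_um)),
      stringsAsFactors = FALSE)
  } else {
    particles <- as.data.frame(particles)
    if (is.null(particles$class)) particles$class <- "TWP"
  }
  # place big particles first: greatly improves packing success without
  # changing the sampled size distribution
  particles <- particles[order(-particles$mFD_um), , drop = FALSE]
  n <- nrow(particles)
  truth <- data.frame(id = integer(0), class = character(0),
                      shape = character(0), true_mFD_um = numeric(0),
                      true_FD_um = numeric(0), orientation_deg = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  if (n > 0) {
    placed_x <- placed_y <- placed_r <- numeric(0)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- particles$class[i]
      shp <- if (!is.null(particles$shape) && !is.na(particles$shape[i]))
        particles$shape[i]
      else if (cls == "charcoal") "charcoal"
      else sample(c("ellipse", "superellipse", "blob"), 1)
      ori <- if (!is.null(particles$orientation_deg) &&
                 !is.na(particles$orientation_deg[i]))
        particles$orientation_deg[i] else runif(1, 0, 180)
      poly <- .rotate(.shape_polygon(shp), ori)
      fer <- feret_diameters(poly)
      scl_um <- particles$mFD_um[i] / fer$mFD      # um per unit
      true_mFD <- particles$mFD_um[i]
      true_FD <- fer$FD * scl_um
      r_px <- true_FD / 2 / px + 2                  # bounding radius, px
      if (2 * r_px >= min(H, W))
        stop("particle ", i, " (FD ", round(true_FD), " um) larger than image")
      ok <- FALSE
      for (try in 1:300) {
        cx <- runif(1, r_px + 1, W - r_px)
        cy <- runif(1, r_px + 1, H - r_px)
        if (spec$allow_overlap || !length(placed_x) ||
            all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >
                  placed_r + r_px + 2)) { ok <- TRUE; break }
      }
      if (!ok) stop("placement failure: could not place particle ", i,
                    " after 300 attempts (scene too crowded)")
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      placed_r <- c(placed_r, r_px)

      # rasterise: star-shaped inside test on the analytic radial function
      poly_px <- poly * (scl_um / px)
      x0 <- max(1L, floor(cx - r_px)); x1 <- min(W, ceiling(cx + r_px))
      y0 <- max(1L, floor(cy - r_px)); y1 <- min(H, ceiling(cy + r_px))
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      rr <- sqrt(dx^2 + dy^2)
      va <- atan2(poly_px[, 2], poly_px[, 1]) %% (2 * pi)
      o <- order(va)
      rb <- .poly_radius(va[o], sqrt(rowSums(poly_px^2))[o], atan2(dy, dx))
      inside <- rr <= rb
      if (any(inside)) {
        if (cls %in% c("TWP", "charcoal")) {
          patch <- render_halo(inside, spec$halo_width_um, px,
                               darkness_cap = spec$darkness_cap)
          if (cls == "charcoal") {
            # internal grey speckle: charcoal is distinguishable by texture
            core <- attr(patch, "core")
            ncore <- sum(core)
            if (ncore > 0) {
              spk <- runif(ncore) < 0.3
              gv <- runif(ncore, 70, 130)
              for (ch in 1:3) {
                pl <- patch[, , ch]
                v <- pl[core]; v[spk] <- clamp(gv[spk] + rnorm(sum(spk), 0, 8), 0, 255)
                pl[core] <- v; patch[, , ch] <- pl
              }
            }
          }
        } else {
          # organic matter: matte coloured fill, never black
          base <- rbind(c(125, 95, 55), c(90, 135, 65), c(170, 120, 60))
          colr <- base[sample.int(3L, 1L), ]
          patch <- array(NA_real_, dim = c(length(ys), length(xs), 3L))
          np <- sum(inside)
          for (ch in 1:3) {
            pl <- patch[, , ch]
            pl[inside] <- clamp(colr[ch] + rnorm(np, 0, 12), 60, 255)
            patch[, , ch] <- pl
          }
        }
        for (ch in 1:3) {
          tgt <- rgb[ys, xs, ch]
          src <- patch[, , ch]
          tgt[!is.na(src)] <- src[!is.na(src)]
          rgb[ys, xs, ch] <- tgt
        }
      }
      ctr <- polygon_area_centroid(poly_px)$centroid
      rows[[i]] <- data.frame(id = i, class = cls, shape = shp,
                              true_mFD_um = true_mFD, true_FD_um = true_FD,
                              orientation_deg = ori,
                              centroid_x_px = cx + ctr[1],
                              centroid_y_px = cy + ctr[2],
                              centroid_x_um = (cx + ctr[1]) * px,
                              centroid_y_um = (cy + ctr[2]) * px)
    }
    truth <- do.call(rbind, rows)
  }
  rgb <- round(rgb)
  class(truth) <- c("ground_truth_table", "data.frame")
  attr(truth, "scene_spec") <- spec
  list(image = filter_image(rgb, px), truth = truth)
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image (lossless TIFF or PNG), the ground truth as a
#' CSV (one row per particle) and the generating [scene_spec] as a JSON
#' sidecar.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if missing).
#' @param name basename for the three files.
#' @param format `"tiff"` (default) or `"png"`.
#' @return invisibly, the three paths written.
#' @export
write_scene <- function(scene, dir, name = "scene", format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, if (format == "tiff") ".tif" else ".png"))
  write_image(scene$image, img_path)
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(scene$truth, truth_path, row.names = FALSE)
  spec_path <- file.path(dir, paste0(name, "_spec.json"))
  jsonlite::write_json(unclass(attr(scene$truth, "scene_spec")), spec_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, truth = truth_path, spec = spec_path))
}
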