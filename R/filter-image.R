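#' Filter image container
#'
#' The unit every image stage consumes and produces: an 8-bit RGB raster of
#' a particle filter, the physical pixel size, and an optional exclusion
#' mask marking regions that must be ignored by all downstream detection
#' (the programmatic equivalent of covering debris in white by hand).
#'
#' @param rgb numeric array `H x W x 3`, values in 0..255.
#' @param pixel_size_um physical pixel size in micrometres per pixel
#'   (the reference acquisition scale is 1.5 um/pixel).
#' @param exclusion_mask optional logical `H x W` matrix; `TRUE` = ignore.
#' @return object of class `filter_image`.
#' @export
filter_image <- function(rgb, pixel_size_um, exclusion_mask = NULL) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an H x W x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("rgb values must lie in [0, 255] (8-bit)")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (!is.null(exclusion_mask)) {
    if (!is.matrix(exclusion_mask) ||
        !identical(dim(exclusion_mask), dim(rgb)[1:2]))
      stop("exclusion_mask must be a logical H x W matrix matching rgb")
    exclusion_mask <- exclusion_mask & TRUE
  }
  structure(list(rgb = rgb, pixel_size_um = pixel_size_um,
                 exclusion_mask = exclusion_mask),
            class = "filter_image")
}

#' @export
print.filter_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<filter_image> %d x %d px, %.3g um/px (%.2f x %.2f mm)%s\n",
              d[2], d[1], x$pixel_size_um,
              d[2] * x$pixel_size_um / 1000, d[1] * x$pixel_size_um / 1000,
              if (!is.null(x$exclusion_mask))
                sprintf(", %d px excluded", sum(x$exclusion_mask)) else ""))
  invisible(x)
}

#' @export
dim.filter_image <- function(x) dim(x$rgb)

#' Load a filter image from TIFF or PNG
#'
#' @param path path to an 8-bit RGB TIFF or PNG file.
#' @param pixel_size_um physical pixel size in um/pixel; required — the
#'   physical scale is never silently defaulted.
#' @return a [filter_image].
#' @export
load_image <- function(path, pixel_size_um) {
  if (missing(pixel_size_um))
    stop("pixel_size_um is required: a filter image without a physical scale is meaningless")
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)"))
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L)
    stop("input is not an RGB image (greyscale or malformed): ", path)
  rgb <- round(raw[, , 1:3] * 255)
  filter_image(rgb, pixel_size_um)
}

#' Write a filter image to TIFF or PNG
#'
#' @param image a [filter_image].
#' @param path output path; format chosen from the extension (.tif/.tiff
#'   lossless TIFF preferred, .png also lossless).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "filter_image"))
  arr <- image$rgb / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Assemble image tiles into one mosaic
#'
#' Recreates the whole-filter image from the per-quadrant acquisitions by
#' exact row-major abutment (tile geometry is known, so no registration or
#' blending is applied).
#'
#' @param tiles list of [filter_image] tiles, row-major order.
#' @param rows,cols grid dimensions; `rows * cols` must equal `length(tiles)`.
#' @return a single [filter_image].
#' @export
assemble_mosaic <- function(tiles, rows, cols) {
  stopifnot(length(tiles) == rows * cols, rows >= 1, cols >= 1)
  ps <- vapply(tiles, function(t) t$pixel_size_um, numeric(1))
  if (length(unique(ps)) != 1L) stop("tiles have mismatched pixel sizes")
  dims <- t(vapply(tiles, function(t) dim(t$rgb)[1:2], numeric(2)))
  # all tiles in one grid row must share height; in one column, width
  idx <- matrix(seq_along(tiles), nrow = rows, ncol = cols, byrow = TRUE)
  for (r in seq_len(rows))
    if (length(unique(dims[idx[r, ], 1])) != 1L) stop("tile heights differ within grid row ", r)
  for (cc in seq_len(cols))
    if (length(unique(dims[idx[, cc], 2])) != 1L) stop("tile widths differ within grid column ", cc)
  H <- sum(dims[idx[, 1], 1]); W <- sum(dims[idx[1, ], 2])
  out <- array(0, dim = c(H, W, 3))
  y0 <- 0L
  for (r in seq_len(rows)) {
    x0 <- 0L
    for (cc in seq_len(cols)) {
      tl <- tiles[[idx[r, cc]]]$rgb
      out[y0 + seq_len(dim(tl)[1]), x0 + seq_len(dim(tl)[2]), ] <- tl
      x0 <- x0 + dim(tl)[2]
    }
    y0 <- y0 + dim(tiles[[idx[r, 1]]]$rgb)[1]
  }
  filter_image(out, ps[1])
}

#' Exclude image regions from analysis
#'
#' Paints the given regions pure white and records them in the exclusion
#' mask, so that no particle can ever be detected there. This mirrors the
#' manual practice of covering insects, seeds, roots and leaf fragments in
#' white before segmentation, as a reproducible mask operation.
#'
#' @param image a [filter_image].
#' @param mask logical `H x W` matrix, `TRUE` = exclude.
#' @return a [filter_image] with white-painted pixels and updated mask.
#' @export
apply_exclusion <- function(image, mask) {
  stopifnot(inherits(image, "filter_image"))
  if (!identical(dim(mask), dim(image$rgb)[1:2]))
    stop("mask shape does not match image")
  mask <- mask & TRUE
  rgb <- image$rgb
  if (any(mask)) for (ch in 1:3) {
    m <- rgb[, , ch]; m[mask] <- 255; rgb[, , ch] <- m
  }
  prev <- image$exclusion_mask
  filter_image(rgb, image$pixel_size_um,
               exclusion_mask = if (is.null(prev)) mask else (prev | mask))
}

#' Contrast enhancement (exposure gain and black level)
#'
#' Per-channel linear stretch `v -> clip(gain * (v - black_level), 0, 255)`.
#' Raising the black level pushes dark (particle) pixels to 0 while the
#' gain drives the pale bluish filter background toward white, removing the
#' filter colour and maximising the contrast the pixel classifier sees.
#' The mapping is monotone in every channel.
#'
#' @param image a [filter_image].
#' @param exposure_gain multiplicative gain, `>= 1` (default 1.5).
#' @param black_level value subtracted before the gain, in 0..254
#'   (default 30).
#' @return enhanced [filter_image] (exclusion mask carried through).
#' @export
enhance <- function(image, exposure_gain = 1.5, black_level = 30) {
  stopifnot(inherits(image, "filter_image"))
  if (!is.numeric(exposure_gain) || exposure_gain < 1)
    stop("exposure_gain must be >= 1")
  if (!is.numeric(black_level) || black_level < 0 || black_level >= 255)
    stop("black_level must be in [0, 255)")
  rgb <- clamp(exposure_gain * (image$rgb - black_level), 0, 255)
  filter_image(rgb, image$pixel_size_um, exclusion_mask = image$exclusion_mask)
}
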