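#' Detect and measure particles in a filter image
#'
#' Convenience chain of the identification stages: contrast enhancement,
#' per-pixel classification, IsoData thresholding, tolerance watershed,
#' morphometry, and size-window filtering. Each stage is also available
#' individually.
#'
#' @param image a [filter_image].
#' @param classifier a `twp_classifier`; default is the rule-based
#'   darkness classifier.
#' @param enhance_gain,enhance_black_level contrast parameters passed to
#'   [enhance()]; set `enhance_gain = NA` to skip enhancement.
#' @param watershed_tolerance prominence tolerance for
#'   [adjustable_watershed()] (default 3).
#' @param min_mFD_um,max_mFD_um size window applied after measurement
#'   (defaults 0 and `Inf`, i.e. no filtering; the operational window of
#'   the method is 35–2000 um).
#' @param perimeter_method passed to [measure_particles()].
#' @return a `particle_table`; the unfiltered count is kept in the
#'   `n_before_filter` attribute.
#' @export
detect_particles <- function(image, classifier = rule_classifier(),
                             enhance_gain = 1.5, enhance_black_level = 30,
                             watershed_tolerance = 3,
                             min_mFD_um = 0, max_mFD_um = Inf,
                             perimeter_method = "chain") {
  stopifnot(inherits(image, "filter_image"))
  img <- if (is.na(enhance_gain)) image else
    enhance(image, enhance_gain, enhance_black_level)
  cm <- classify(img, classifier)
  mask <- suppressWarnings(binarize(cm))
  lab <- adjustable_watershed(mask, tolerance = watershed_tolerance)
  tab <- measure_particles(lab, image$pixel_size_um,
                           perimeter_method = perimeter_method)
  if (min_mFD_um > 0 || is.finite(max_mFD_um))
    tab <- filter_particles(tab, min_mFD_um, max_mFD_um)
  tab
}
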