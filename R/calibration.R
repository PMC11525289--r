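#' Match detected particles to reference particles
#'
#' One-to-one greedy nearest-centroid matching between a reference table
#' (ground truth or manual measurements) and a detected particle table,
#' both in the same physical coordinate frame. Pairs are assigned in
#' order of increasing centroid distance up to `max_dist_um`; unmatched
#' references are misses, unmatched detections are false positives.
#'
#' @param reference data frame with columns `centroid_x_um`,
#'   `centroid_y_um` and a size column (`true_mFD_um` for ground truth or
#'   `mFD_um`).
#' @param detected a `particle_table`.
#' @param max_dist_um maximum centroid distance for a match (default 20).
#' @return list with `matches` (data frame `ref_idx, det_idx, dist_um`),
#'   `misses` (reference row indices) and `false_positives` (detected row
#'   indices).
#' @export
match_particles <- function(reference, detected, max_dist_um = 20) {
  nr <- nrow(reference); nd <- nrow(detected)
  if (nr == 0 || nd == 0)
    return(list(matches = data.frame(ref_idx = integer(0), det_idx = integer(0),
                                     dist_um = numeric(0)),
                misses = seq_len(nr), false_positives = seq_len(nd)))
  dx <- outer(reference$centroid_x_um, detected$centroid_x_um, "-")
  dy <- outer(reference$centroid_y_um, detected$centroid_y_um, "-")
  dd <- sqrt(dx^2 + dy^2)
  cand <- which(dd <= max_dist_um, arr.ind = TRUE)
  m_ref <- integer(0); m_det <- integer(0); m_d <- numeric(0)
  if (nrow(cand)) {
    ord <- order(dd[cand])
    used_r <- logical(nr); used_d <- logical(nd)
    for (k in ord) {
      r <- cand[k, 1]; d <- cand[k, 2]
      if (!used_r[r] && !used_d[d]) {
        used_r[r] <- TRUE; used_d[d] <- TRUE
        m_ref <- c(m_ref, r); m_det <- c(m_det, d); m_d <- c(m_d, dd[r, d])
      }
    }
  }
  list(matches = data.frame(ref_idx = m_ref, det_idx = m_det, dist_um = m_d),
       misses = setdiff(seq_len(nr), m_ref),
       false_positives = setdiff(seq_len(nd), m_det))
}

#' Size-measurement accuracy pairs
#'
#' For every matched particle, the accuracy of the automated size
#' measurement is the pipeline's minimum Feret diameter divided by the
#' reference minimum Feret diameter, times 100.
#'
#' @param matches result of [match_particles()].
#' @param reference,detected the tables that were matched; the reference
#'   size column is `true_mFD_um` if present, else `mFD_um`.
#' @return data frame with `reference_mFD_um`, `measured_mFD_um`,
#'   `accuracy_pct`.
#' @export
accuracy_pairs <- function(matches, reference, detected) {
  refcol <- if ("true_mFD_um" %in% names(reference)) "true_mFD_um" else "mFD_um"
  ref <- reference[[refcol]][matches$matches$ref_idx]
  det <- detected$mFD_um[matches$matches$det_idx]
  stopifnot(all(ref > 0), all(det > 0))
  data.frame(reference_mFD_um = ref, measured_mFD_um = det,
             accuracy_pct = det / ref * 100)
}

#' LOESS accuracy curve
#'
#' Locally weighted smoothing of accuracy against reference size, used to
#' visualise how the measurement accuracy varies with particle size. The
#' smoother is descriptive only; the operational decision comes from the
#' segmented fit ([fit_breakpoint()]).
#'
#' @param pairs accuracy pairs from [accuracy_pairs()] (>= 10 rows).
#' @param span LOESS span in (0, 1], default 0.75.
#' @param n_grid evaluation grid size.
#' @return data frame `mFD_um`, `accuracy_pct` (fitted curve).
#' @export
accuracy_curve <- function(pairs, span = 0.75, n_grid = 100L) {
  if (nrow(pairs) < 10) stop("need at least 10 accuracy pairs")
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  fit <- stats::loess(accuracy_pct ~ reference_mFD_um, data = pairs,
                      span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(pairs$reference_mFD_um), max(pairs$reference_mFD_um),
              length.out = n_grid)
  data.frame(mFD_um = grid, accuracy_pct = stats::predict(fit, newdata =
               data.frame(reference_mFD_um = grid)))
}

#' Segmented (breakpoint) fit of accuracy vs particle size
#'
#' Fits a continuous two-segment linear model to the accuracy pairs to
#' identify the size from which the measurement accuracy stabilises: a
#' rising segment below the breakpoint and a plateau (or a second free
#' slope) above it. The model is fit by Levenberg-Marquardt nonlinear
#' least squares ([minpack.lm::nlsLM()]) with a multi-start grid of
#' candidate breakpoints across the observed size range to avoid local
#' minima.
#'
#' @param pairs accuracy pairs (>= 10 rows spanning both regimes).
#' @param constrain_plateau if `TRUE` (default) the post-break slope is
#'   fixed at 0 (pure plateau); if `FALSE` it is a free parameter.
#' @param n_starts breakpoint grid size (default 10).
#' @return object of class `breakpoint_fit`: list with `breakpoint_um`,
#'   `slope_pre` (% per um), `slope_post`, `plateau_pct` (fitted accuracy
#'   at the breakpoint), `rss`, `converged`, `degenerate` (breakpoint at
#'   the data boundary or indistinguishable slopes).
#' @export
fit_breakpoint <- function(pairs, constrain_plateau = TRUE, n_starts = 10L) {
  if (nrow(pairs) < 10) stop("need at least 10 accuracy pairs")
  x <- pairs$reference_mFD_um; y <- pairs$accuracy_pct
  rg <- range(x)
  starts <- seq(rg[1] + 0.05 * diff(rg), rg[2] - 0.05 * diff(rg),
                length.out = n_starts)
  best <- NULL
  for (bp0 in starts) {
    fit <- tryCatch({
      if (constrain_plateau) {
        minpack.lm::nlsLM(y ~ p + s1 * pmin(x - bp, 0),
                          start = list(p = stats::median(y[x >= bp0]),
                                       s1 = 2, bp = bp0),
                          lower = c(-Inf, -Inf, rg[1]),
                          upper = c(Inf, Inf, rg[2]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ p + s1 * pmin(x - bp, 0) + s2 * pmax(x - bp, 0),
                          start = list(p = stats::median(y[x >= bp0]),
                                       s1 = 2, s2 = 0, bp = bp0),
                          lower = c(-Inf, -Inf, -Inf, rg[1]),
                          upper = c(Inf, Inf, Inf, rg[2]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(breakpoint_um = NA_real_, slope_pre = NA_real_,
                          slope_post = NA_real_, plateau_pct = NA_real_,
                          rss = NA_real_, converged = FALSE, degenerate = TRUE),
                     class = "breakpoint_fit"))
  cf <- stats::coef(best$fit)
  bp <- unname(cf["bp"])
  margin <- 0.02 * diff(rg)
  s1 <- unname(cf["s1"])
  s2 <- if (constrain_plateau) 0 else unname(cf["s2"])
  # degenerate when the breakpoint hits the data boundary, or the hinge
  # does not improve on a plain straight line (F test on the extra
  # parameters): plateau-only or single-slope data has no breakpoint
  rss_line <- sum(stats::residuals(stats::lm(y ~ x))^2)
  dfree <- max(1, length(x) - length(cf))
  fstat <- ((rss_line - best$rss) / 2) / (best$rss / dfree)
  degenerate <- bp <= rg[1] + margin || bp >= rg[2] - margin ||
    fstat < stats::qf(0.95, 2, dfree)
  structure(list(breakpoint_um = bp,
                 slope_pre = unname(cf["s1"]),
                 slope_post = if (constrain_plateau) 0 else unname(cf["s2"]),
                 plateau_pct = unname(cf["p"]),
                 rss = best$rss, converged = TRUE, degenerate = degenerate),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(paste0("<breakpoint_fit> accuracy stabilises at mFD %.1f um ",
                     "(plateau %.1f%%, pre-break slope %.2f %%/um%s)\n"),
              x$breakpoint_um, x$plateau_pct, x$slope_pre,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Recovery rate by lower size threshold
#'
#' For each candidate lower size limit `t`, the per-replicate recovery is
#' `100 x (detected particles with mFD >= t) / (true particles with
#' mFD >= t)`; the curve reports mean, SD and SE across replicates.
#' Recovery can exceed 100% when false positives are present. A
#' threshold with zero true particles above it in some replicate has that
#' replicate dropped (undefined ratio); if no replicate remains the
#' threshold is dropped with a warning.
#'
#' @param spike_truth data frame with `replicate` and `mFD_um` (or
#'   `true_mFD_um`) of the spiked/true particles.
#' @param detected data frame with `replicate` and `mFD_um` of detections.
#' @param thresholds strictly increasing candidate lower size limits, um.
#' @return object of class `recovery_curve`: data frame
#'   `threshold_um, mean_recovery_pct, sd_pct, se_pct, n_replicates`.
#' @export
recovery_curve <- function(spike_truth, detected,
                           thresholds = seq(10, 60, by = 5)) {
  stopifnot(all(diff(thresholds) > 0))
  tcol <- if ("true_mFD_um" %in% names(spike_truth)) "true_mFD_um" else "mFD_um"
  reps <- sort(unique(spike_truth$replicate))
  rows <- lapply(thresholds, function(t) {
    rec <- vapply(reps, function(r) {
      n_true <- sum(spike_truth$replicate == r & spike_truth[[tcol]] >= t)
      if (n_true == 0) return(NA_real_)
      n_det <- sum(detected$replicate == r & detected$mFD_um >= t)
      100 * n_det / n_true
    }, numeric(1))
    rec <- rec[!is.na(rec)]
    if (length(rec) == 0) {
      warning("threshold ", t, " um dropped: no true particles above it")
      return(NULL)
    }
    data.frame(threshold_um = t, mean_recovery_pct = mean(rec),
               sd_pct = if (length(rec) > 1) stats::sd(rec) else 0,
               se_pct = if (length(rec) > 1) stats::sd(rec) / sqrt(length(rec)) else 0,
               n_replicates = length(rec))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("recovery_curve", "data.frame"))
}

#' Select the operational lower size limit from a recovery curve
#'
#' Returns the smallest candidate threshold whose mean recovery rate
#' reaches the acceptability floor (default 80%): excluding small,
#' poorly recovered particles raises the mean recovery, and the first
#' threshold reaching the floor becomes the particle lower size detection
#' limit. If no threshold reaches the floor, `NA` is returned with a
#' warning.
#'
#' @param curve a [recovery_curve()].
#' @param min_recovery_pct acceptability floor in % (default 80).
#' @return selected threshold in um, or `NA`.
#' @export
select_size_limit <- function(curve, min_recovery_pct = 80) {
  stopifnot(nrow(curve) > 0)
  ok <- which(curve$mean_recovery_pct >= min_recovery_pct)
  if (length(ok) == 0) {
    warning("no threshold reaches a mean recovery of ", min_recovery_pct, "%")
    return(NA_real_)
  }
  curve$threshold_um[min(ok)]
}

#' Diagnostic calibration plot
#'
#' Accuracy scatter with the LOESS curve and the segmented fit (left),
#' and the recovery-vs-threshold bars with the selection floor (right).
#'
#' @param pairs accuracy pairs; `curve` a [recovery_curve()]; `fit` a
#'   [fit_breakpoint()] result; `loess_curve` an [accuracy_curve()];
#'   `min_recovery_pct` the selection floor.
#' @param path output PNG path.
#' @export
plot_calibration <- function(pairs, curve, fit = NULL, loess_curve = NULL,
                             min_recovery_pct = 80, path = "calibration.png") {
  grDevices::png(path, width = 1200, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  plot(pairs$reference_mFD_um, pairs$accuracy_pct, pch = 16,
       col = grDevices::adjustcolor("grey30", 0.6),
       xlab = "reference mFD (um)", ylab = "measurement accuracy (%)",
       main = "size accuracy")
  if (!is.null(loess_curve))
    graphics::lines(loess_curve$mFD_um, loess_curve$accuracy_pct,
                    col = "blue", lwd = 2)
  if (!is.null(fit) && fit$converged) {
    xx <- seq(min(pairs$reference_mFD_um), max(pairs$reference_mFD_um),
              length.out = 200)
    yy <- fit$plateau_pct + fit$slope_pre * pmin(xx - fit$breakpoint_um, 0) +
      fit$slope_post * pmax(xx - fit$breakpoint_um, 0)
    graphics::lines(xx, yy, col = "red", lwd = 2)
    graphics::abline(v = fit$breakpoint_um, lty = 2)
  }
  graphics::barplot(curve$mean_recovery_pct, names.arg = curve$threshold_um,
                    xlab = "lower size limit, mFD (um)",
                    ylab = "mean recovery (%)", main = "recovery by size limit")
  graphics::abline(h = min_recovery_pct, lty = 2)
  invisible(path)
}
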