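#' Blank statistics and method limits of detection/quantification
#'
#' From the particle counts of procedural blanks (within the operational
#' size window), computes
#' `LOD = mean_blank + 3 * sd_blank` and `LOQ = mean_blank + 10 * sd_blank`
#' (sample SD, n-1 denominator). Both limits are floored at the
#' operational resolution of the method — the smallest reportable signal,
#' one particle per processed subsample — so blanks with no particles at
#' all give `LOD = LOQ = 1` and no blank correction is applied.
#'
#' @param blank_counts nonnegative particle counts, one per blank.
#' @param operational_resolution smallest reportable count (default 1).
#' @return object of class `blank_stats`: list with `counts`,
#'   `mean_blank`, `sd_blank`, `LOD_raw`, `LOQ_raw` (formula values),
#'   `LOD`, `LOQ` (floored) and `operational_resolution`.
#' @export
blank_stats <- function(blank_counts, operational_resolution = 1) {
  if (length(blank_counts) < 1) stop("need at least one blank count")
  if (any(blank_counts < 0)) stop("blank counts must be nonnegative")
  m <- mean(blank_counts)
  s <- if (length(blank_counts) > 1) stats::sd(blank_counts) else 0
  lod_raw <- m + 3 * s
  loq_raw <- m + 10 * s
  structure(list(counts = blank_counts, mean_blank = m, sd_blank = s,
                 LOD_raw = lod_raw, LOQ_raw = loq_raw,
                 LOD = max(lod_raw, operational_resolution),
                 LOQ = max(loq_raw, operational_resolution),
                 operational_resolution = operational_resolution),
            class = "blank_stats")
}

#' @export
print.blank_stats <- function(x, ...) {
  cat(sprintf(paste0("<blank_stats> %d blanks, mean %.3g, sd %.3g; ",
                     "LOD %.3g, LOQ %.3g (floored at %g particle/subsample)\n"),
              length(x$counts), x$mean_blank, x$sd_blank, x$LOD, x$LOQ,
              x$operational_resolution))
  invisible(x)
}

#' Concentration in particles per kg dry soil
#'
#' Extrapolates the mean particle count of the replicate subsamples to a
#' dry-soil concentration: `mean(counts) * 1000 / mass_g` particles per
#' kg, with standard error `sd(counts)/sqrt(n) * 1000 / mass_g`. With the
#' typical ~5 g subsample, about 40 particles correspond to ~8000
#' particles per kg.
#'
#' @param replicate_counts nonnegative particle counts, one per replicate
#'   subsample.
#' @param mass_g dry mass of one subsample in grams (> 0).
#' @return list with `mean_count`, `concentration_per_kg`, `se_per_kg`,
#'   `n_replicates`, `mass_g`.
#' @export
concentration <- function(replicate_counts, mass_g) {
  if (!is.numeric(mass_g) || mass_g <= 0) stop("mass_g must be > 0")
  if (any(replicate_counts < 0)) stop("counts must be nonnegative")
  n <- length(replicate_counts)
  scale <- 1000 / mass_g
  list(mean_count = mean(replicate_counts),
       concentration_per_kg = mean(replicate_counts) * scale,
       se_per_kg = if (n > 1) stats::sd(replicate_counts) / sqrt(n) * scale
                   else NA_real_,
       n_replicates = n, mass_g = mass_g)
}

#' Cumulative frequency distributions of size and shape
#'
#' Empirical cumulative distribution tables of the (maximum) Feret
#' diameter and the circularity, per replicate, for the distribution
#' plots. Ties are collapsed to one plateau step (each unique value
#' appears once at its cumulative frequency).
#'
#' @param table a `particle_table`, optionally with a `replicate` column
#'   (one replicate assumed otherwise).
#' @return list with data frames `FD` and `circularity`, each
#'   `replicate, value, cumfreq` with `cumfreq` nondecreasing and ending
#'   at 1 per replicate. Empty input yields empty tables with a warning.
#' @export
cumulative_distributions <- function(table) {
  if (nrow(table) == 0) {
    warning("empty particle table: empty distributions")
    e <- data.frame(replicate = character(0), value = numeric(0),
                    cumfreq = numeric(0))
    return(list(FD = e, circularity = e))
  }
  rep_col <- if ("replicate" %in% names(table)) table$replicate else
    rep("all", nrow(table))
  build <- function(column) {
    out <- lapply(split(table[[column]], rep_col), function(v) {
      v <- sort(v)
      u <- unique(v)
      data.frame(value = u, cumfreq = stats::ecdf(v)(u))
    })
    do.call(rbind, Map(function(r, d) cbind(replicate = r, d),
                       names(out), out))
  }
  list(FD = build("FD_um"), circularity = build("circularity"))
}

#' Kruskal-Wallis test with Dunn posthoc comparisons
#'
#' Nonparametric comparison of particle counts (or any measurements)
#' across groups: the Kruskal-Wallis rank-sum H statistic with tie
#' correction, followed by Dunn's pairwise z tests on mean ranks with
#' multiplicity adjustment (Holm by default).
#'
#' @param values numeric observations.
#' @param groups group labels, same length; >= 2 groups with >= 2
#'   observations each.
#' @param p_adjust_method method for [stats::p.adjust()] (default
#'   `"holm"`).
#' @return object of class `group_test_result`: list with `H`, `df`,
#'   `p_value`, and `pairwise` (data frame `group1, group2, z, p_unadj,
#'   p_adj` covering all pairs), plus the adjustment method name.
#' @export
compare_groups <- function(values, groups, p_adjust_method = "holm") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- as.numeric(tab[names(rbar)])
  H0 <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  C <- 1 - tie_sum / (N^3 - N)
  H <- if (C > 0) H0 / C else 0
  k <- length(rbar)
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  # Dunn z: difference of mean ranks over its null SE, with tie correction
  sigma2 <- (N * (N + 1) / 12) - tie_sum / (12 * (N - 1))
  gs <- names(rbar)
  prs <- utils::combn(gs, 2)
  z <- vapply(seq_len(ncol(prs)), function(j) {
    i1 <- which(gs == prs[1, j]); i2 <- which(gs == prs[2, j])
    (rbar[i1] - rbar[i2]) / sqrt(sigma2 * (1 / ni[i1] + 1 / ni[i2]))
  }, numeric(1))
  p_un <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(H = H, df = k - 1, p_value = p,
                 pairwise = data.frame(group1 = prs[1, ], group2 = prs[2, ],
                                       z = z, p_unadj = p_un,
                                       p_adj = stats::p.adjust(p_un, p_adjust_method)),
                 p_adjust_method = p_adjust_method),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  cat(sprintf("Dunn posthoc (adjustment: %s):\n", x$p_adjust_method))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Rough particle mass estimate (parameterised ellipsoid model)
#'
#' Estimates the total particle mass per kg dry soil from the measured
#' Feret diameters, treating each particle as an ellipsoid with axes
#' `FD x mFD x (k * mFD)` — the third (thickness) axis is not observable
#' in a 2-D image and is parameterised as a fixed fraction `k` of the
#' minimum Feret diameter. Volume is `(pi/6) * FD * mFD * (k * mFD)`.
#' This is explicitly a rough, model-tagged estimate: the result carries
#' the model name and parameters and must never be read as a measured
#' mass.
#'
#' @param table a `particle_table`.
#' @param density_g_cm3 assumed particle density (default 1.8 g/cm^3,
#'   typical of mineral-encrusted tire wear).
#' @param thickness_k thickness fraction `k` (default 0.4).
#' @param mass_g dry subsample mass in grams for the per-kg scaling.
#' @return list with `mass_mg_per_kg`, `total_mass_mg` (in the
#'   subsample), `n_particles`, `model` (name and parameters).
#' @export
estimate_mass <- function(table, density_g_cm3 = 1.8, thickness_k = 0.4,
                          mass_g = 5) {
  stopifnot(density_g_cm3 > 0, thickness_k > 0, mass_g > 0)
  vol_um3 <- if (nrow(table) == 0) numeric(0) else
    (pi / 6) * table$FD_um * table$mFD_um * (thickness_k * table$mFD_um)
  # 1 um^3 = 1e-12 cm^3; mass in mg = volume_cm3 * density_g_cm3 * 1000
  mass_mg <- sum(vol_um3) * 1e-12 * density_g_cm3 * 1000
  list(mass_mg_per_kg = mass_mg * 1000 / mass_g,
       total_mass_mg = mass_mg, n_particles = nrow(table),
       model = list(name = "ellipsoid", thickness_k = thickness_k,
                    density_g_cm3 = density_g_cm3))
}
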