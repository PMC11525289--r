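# twpscan

Tire wear particles (TWP) are one of the largest sources of microplastic
mass entering soils, yet they are awkward to count: they are small, black,
often mineral-encrusted, and sit on a filter among organic debris and
charcoal after extraction. `twpscan` implements an optical-microscopy
identification pipeline for exactly this situation — counting and sizing
black particles on pale filters from ordinary RGB microscope images — for
environmental scientists who need particle numbers, sizes and shapes per
kg of dry soil without access to spectroscopic imaging.

## What it computes

The pipeline runs from raw filter image to sample statistics:

1. **Preprocess** — mosaic assembly of image tiles, exclusion masking
   (debris regions painted white and barred from detection), and a linear
   exposure-gain / black-level contrast stretch that whitens the bluish
   filter and pushes dark particles to black.
2. **Pixel classification** — a trainable segmentation stage: a random
   forest over colour, multiscale Gaussian, gradient and local min/max
   texture features, trained from sparse pixel annotations
   (black particle vs background), producing a per-pixel TWP probability;
   binarised by the IsoData automatic threshold.
3. **Morphometry** — touching particles are separated by a
   distance-transform watershed whose merge *tolerance* (default 3)
   suppresses spurious maxima; each particle is measured: area, perimeter
   (Crofton line-intercept or chain-code), maximum Feret diameter FD
   (rotating calipers on the convex hull), minimum Feret diameter mFD
   (exact minimal caliper), and circularity 4πA/P².
4. **Calibration** — detections are matched to reference sizes;
   accuracy = 100 · mFD_measured / mFD_reference is smoothed by LOESS and
   fit with a continuous two-segment (breakpoint) model via
   Levenberg–Marquardt to find where accuracy stabilises; recovery rates
   by candidate lower size limit select the operational threshold
   (smallest limit with mean recovery ≥ 80%).
5. **Quantification** — blank-based limits,
   LOD = mean_blank + 3·SD_blank and LOQ = mean_blank + 10·SD_blank,
   both floored at the operational resolution of 1 particle per
   subsample; concentrations as mean count × 1000 / subsample mass (g) in
   particles kg⁻¹ dry soil; cumulative FD and circularity distributions;
   Kruskal–Wallis with Dunn–Holm posthoc group comparison; and a rough
   ellipsoid mass estimate (thickness = k · mFD).

Because real filters come with no ground truth, the package ships a
seeded synthetic scene generator (`generate_scene()`) that renders black
particles with the optical artefact that limits this method in practice:
a chromatic (blue/yellow/red) diffraction rim that replaces the particle
edge, so small particles lose their black core and are under-sized or
missed entirely. Charcoal (black, angular, grey-textured) and coloured
organic distractors are available to probe interference. Every rendered
particle carries exact analytic mFD/FD ground truth.

## Worked example

```r
library(twpscan)

sc  <- generate_scene(scene_spec(width_px = 600, height_px = 600, rng_seed = 42))
tab <- detect_particles(sc$image)          # classify -> threshold -> watershed -> measure
head(as.data.frame(tab)[, c("id", "area_um2", "FD_um", "mFD_um", "circularity")], 4)
#>   id area_um2  FD_um mFD_um circularity
#> 1  1     9169 120.54  92.28      0.8912
#> 2  2    14128 203.35  90.56      0.7136
#> 3  3     3424  95.40  47.91      0.7764
#> 4  4     2372  82.38  39.11      0.7587

mm <- match_particles(sc$truth, tab)
ap <- accuracy_pairs(mm, sc$truth, tab)
mean(ap$accuracy_pct[ap$reference_mFD_um >= 25])
#> [1] 91.0        # sizes are ~91% accurate above 25 um ...
mean(ap$accuracy_pct)
#> [1] 81.0        # ... but the halo drags small particles down

blank_stats(c(0, 0, 0))
#> <blank_stats> 3 blanks, mean 0, sd 0; LOD 1, LOQ 1 (floored at 1 particle/subsample)

win <- filter_particles(tab, 35, 2000)     # operational size window, um
concentration(rep(nrow(win), 3), mass_g = 5)$concentration_per_kg
#> [1] 1000       # 5 particles in a 5 g subsample -> 1000 particles/kg
```

All 10 rendered particles are recovered; the mean size accuracy above
25 µm mFD sits on the ~90% plateau, while the average over all sizes is
pulled down by the diffraction halo on the small particles — the
mechanism that motivates the 35 µm operational lower size limit.

A command-line interface with subcommands
`simulate | segment | measure | calibrate | quantify | demo` is installed
at `inst/cli/twpscan`; try
`Rscript inst/cli/twpscan demo --seed 1 --out demo_out`.

## Further reading

The methods vignette (`vignettes/twpscan-methods.Rmd`) documents the
halo model, the watershed tolerance semantics, the Feret and perimeter
estimators, the segmented-regression parameterisation, every default
with its rationale, and the known limitations (charcoal interference,
untextured discrimination, the idealised synthetic scenes).
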