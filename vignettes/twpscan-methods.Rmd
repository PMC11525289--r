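---
title: "Methods: colour-based tire wear particle detection and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-based tire wear particle detection and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twpscan)
```

# The measurement problem

Tire wear particles (TWP) extracted from soil end up on a filter as
small black grains among whatever survived the clean-up: bleached
organic fragments and, critically, charcoal. Optical microscopy can see
them; the question is whether a colour-based identification — "black on
a pale filter" — can count and size them reliably, and down to what
size. `twpscan` implements that identification chain and, because real
filters come without ground truth, a synthetic scene generator that
makes every stage testable against exact references.

Two physical facts shape the whole design:

* **Diffraction halo.** Under the ring illuminator, the rim of a dark
  particle diffracts light into blue, yellow and red pixels. A classifier
  keyed to black pixels therefore sees a *shrunken core*: a particle of
  true minimum Feret diameter (mFD) $d$ with a halo of width $h$
  presents a black core of roughly $d - 2h$. For large particles this is
  a few percent; below ~20 µm it destroys the size estimate, and a
  particle whose radius is smaller than $h$ has no black pixels at all
  and is invisible.
* **Charcoal.** Charcoal is also black. A colour-only classifier cannot
  reject it; it differs only in texture (internal grey speckle, angular
  outline). This is a documented interference, not something the
  pipeline pretends to solve.

# Synthetic scenes and the halo model

`scene_spec()` / `generate_scene()` render a pale-blue filter background
(default RGB (190, 205, 225), Gaussian noise SD 4 counts) at
1.5 µm/pixel — the acquisition scale of the reference setup — and place
non-overlapping particles with exact analytic ground truth. Shapes are
star-shaped polygons (ellipses with aspect 1–2.2, superellipses, and
Fourier-perturbed blobs; charcoal uses angular 5–8-vertex chord
polygons), scaled so that the polygon's *exact* minimal caliper equals
the requested mFD. True mFD and FD are computed from the analytic
polygon before rasterisation, so ground truth carries no discretisation
error.

The halo is modelled as **annular replacement**: the outer
`halo_width_um` band of the particle (measured on the Euclidean distance
transform, so non-integer widths work) is painted with saturated
blue/yellow/red pixels; the remaining core gets near-black values with
all channels at or below a darkness cap of 40/255. No attempt is made to
model the diffraction optics — the replacement width is a scene
parameter — because what matters downstream is only the *geometry* of
the black-pixel deficit, which this reproduces: core mFD ≈ true mFD −
2 × halo, undetectability when the halo covers the centre, and monotone
degradation with halo width (all property-tested).

Generator defaults are the study conditions of the validation suite:
halo 4 µm (the observed rims motivate a 3–5 µm band, and the acceptance
runs cycle through 3, 4 and 5), TWP sizes log-uniform on 10–200 µm
(small particles dominate environmental size spectra; the upper end
keeps scenes well below the 2000 µm operational ceiling), and a number
density of 12 particles/mm². The density was chosen once so that
bounding-circle disjoint placement succeeds across frame sizes while
keeping loadings realistic for a well-distributed filter; it is not a
tuning knob. The darkness cap of 40 is a rendering convention — the
reference workflow never states the darkness range its model used — and
the rule-based classifier uses the same cap so the two conventions stay
aligned.

What the generator deliberately does **not** emulate: defocus blur,
mosaic seams, illumination gradients, camera noise models, or particles
touching by deposition (scenes are disjoint unless `allow_overlap`).
Passing tests on synthetic scenes therefore demonstrate the *algorithmic*
chain under the stated optics model, not robustness to every acquisition
artefact of a physical microscope.

# Identification chain

**Contrast enhancement** is the linear map
$v \mapsto \mathrm{clip}(g\,(v - b),\,0,\,255)$ per channel. The
reference workflow states the goal (suppress the bluish filter colour,
stretch particle/background contrast) but not its numbers; the defaults
$g = 1.5$, $b = 30$ whiten the synthetic background while keeping black
cores inside the classifier's darkness range. The map is monotone, so it
never reorders intensities. Exclusion masking paints regions pure white
*and* records them, and `classify()` forces excluded pixels to
background — exclusion always beats classification.

**Pixel classification** uses a 100-tree random forest (`ranger`, fixed
seed, single-threaded for reproducibility) over 16 features per pixel:
raw R, G, B; per-channel Gaussian smoothings at radii 1, 2, 4 px;
gradient magnitude; 3×3 local minimum and maximum; and the channel
minimum as an explicit darkness feature. The exact feature set of the
interactive tool this replaces is not documented anywhere; this set is
the standard colour + multiscale smoothing + edge + texture complement,
and the configuration is stored inside the trained model and enforced at
prediction. A transparent rule-based classifier (all channels ≤ darkness
cap ⇒ TWP) is provided for headless runs and as a deterministic
baseline; the forest is the default path.

**Binarisation** converts the TWP-probability raster to 8 bits and
applies the IsoData iterative-intermeans threshold — pinned to one named
algorithm because "automatic threshold" is not reproducible otherwise —
with polarity fixed so TWP is foreground. A degenerate single-valued
raster yields an empty mask with a warning rather than an arbitrary cut.

**Watershed.** Touching particles are split on the Euclidean distance
transform with a *merge tolerance*: candidate maxima whose basin depth
above the saddle is below the tolerance (in distance units, i.e. pixels)
are merged into their neighbour. The default tolerance 3 is the
operational setting of the chain. The implementation delegates the
tolerance watershed to `EBImage::watershed(distmap(mask), tolerance)`,
which implements exactly these semantics, and then carves a one-pixel
background line between adjacent labels so split particles are spatially
disjoint; foreground is never added, and the removed line is bounded by
the contact length (both property-tested on fused-disc dumbbells with
known basin depth ≈ 6.8 px: split at tolerance 3, merged at 8).

**Morphometry.** Feret diameters are computed on the corner points of
the boundary pixels — so a $w \times h$ pixel rectangle measures exactly
$\min(w,h)$ / $\sqrt{w^2+h^2}$ — with FD from rotating calipers over
antipodal convex-hull pairs and mFD as the exact minimal caliper (the
minimum width of a convex polygon is attained flush with a hull edge; no
orientation sampling). The caliper FD is verified against a brute-force
$O(n^2)$ pairwise maximum on every test shape. Circularity is
$4\pi A / P^2$, clipped to 1. Two perimeter estimators are available:

* `crofton` (default): 4-direction line-intercept estimate,
  $P = \tfrac{\pi}{8}\,(t_h + t_v + (t_{d1}+t_{d2})/\sqrt2)$,
  asymptotically unbiased on smooth outlines (a rasterised disc of
  diameter 100 px measures circularity ≈ 1.00);
* `chain`: weighted boundary steps (straight 1, diagonal $\sqrt2$),
  closest to classic chain-code measures but biased a few percent high
  on smooth outlines, which depresses circularity (~0.92 for the same
  disc).

The choice is a config flag because the platform this reconstructs does
not document which convention its shape descriptors used; circularity is
the only quantity affected. Single-pixel particles take FD = mFD = one
pixel by convention. Components are 8-connected throughout; coordinates
are pixel-centre, origin top-left, x right, y down, and every CSV header
names the units and convention.

The size-window filter retains $\text{mFD} \in [\min, \max)$ — inclusive
at the lower bound, so a particle at exactly 35 µm survives the
operational window [35, 2000) µm. Identification itself always runs
unfiltered (0 to infinity); the window is applied afterwards and the
pre-filter count is preserved in the table metadata.

# Calibration

Detections are matched to references by greedy nearest-centroid
one-to-one assignment within 20 µm (any radius below the inter-particle
spacing of the scenes works; the reference workflow matched by hand).
Accuracy per pair is $100 \cdot \text{mFD}_{meas}/\text{mFD}_{ref}$.

The accuracy–size relation is summarised two ways, mirroring the
descriptive/decision split: a LOESS smoother (span 0.75, visualisation
only) and a **continuous two-segment linear model**
$y = p + s_1 \min(x - c, 0)\;[+\;s_2 \max(x - c, 0)]$ fit by
Levenberg–Marquardt (`minpack.lm::nlsLM`) with a 10-point multi-start
grid on the breakpoint $c$ to avoid local minima. The post-break slope
is constrained to 0 by default (the plateau reading of the stabilisation
point); the unconstrained variant sits behind a flag since the original
parameterisation is not documented. A fit is flagged *degenerate* when
the breakpoint lands on the data boundary or when an F-test shows the
hinge does not improve on a plain line (plateau-only or single-slope
data has no meaningful breakpoint); degenerate and non-converged fits
are never reported silently. Under the validation conditions (plateau
90%, break at 25 µm, noise SD 2, 120 points), the median absolute
breakpoint error over 100 seeded runs is below 3 µm.

Recovery is count-based: for each candidate lower limit $t$,
$100 \times \#\{\text{detected mFD} \ge t\} / \#\{\text{true mFD} \ge t\}$
per replicate, averaged with SD/SE across replicates. Recovery may
exceed 100% when false positives are present, which is why it is
reported rather than clipped. `select_size_limit()` applies the decision
rule: the smallest threshold whose mean recovery reaches the floor
(default 80%). On curves crossing 80% between 25 and 35 µm this selects
35 µm — deliberately more conservative than the ~25 µm at which size
*accuracy* stabilises, because recovery (detecting the particle at all)
degrades more slowly than sizing but is the quantity that bounds
concentration error.

# Quantification

Limits follow the blank-based convention
$\text{LOD} = \bar{x}_B + 3 s_B$, $\text{LOQ} = \bar{x}_B + 10 s_B$
(sample SD, $n-1$), floored at the **operational resolution** of 1
particle per subsample — the smallest signal the method can report.
Blanks with zero counts therefore give LOD = LOQ = 1 and no blank
correction is applied.

Concentration is $\bar{n} \times 1000 / m$ particles kg⁻¹ dry soil for
subsample mass $m$ in grams, with SE $= s_n/\sqrt{k} \times 1000/m$.
(A literal reading of "multiplying by the subsample weight" cannot
produce per-kg units; the implemented scaling is the one that reproduces
the reported magnitudes, ~40 particles in 5 g → ~8000 kg⁻¹, and is
stated here prominently for that reason.)

Group comparison is a Kruskal–Wallis rank test with tie correction
followed by Dunn's pairwise z statistics (the same tie-corrected rank
variance) with Holm adjustment by default. These are implemented
directly in the package — the posthoc helper package the field commonly
uses is not a dependency here — and are cross-checked in the test suite
against `stats::kruskal.test` and an independent loop-written oracle to
10⁻⁸.

The mass estimate treats each particle as an ellipsoid
$V = \tfrac{\pi}{6}\,\text{FD}\cdot\text{mFD}\cdot(k\,\text{mFD})$ with
thickness fraction $k = 0.4$ and density 1.8 g cm⁻³ (mineral-encrusted
rubber) by default. The third axis is unobservable in a 2-D image, so
this is a parameterised model, not a measurement; results always carry
the model name and parameters, and should be read as order-of-magnitude.

# Numerical and interface choices

* Determinism: every stochastic stage (scene generation, label sampling,
  forest training and prediction) takes an explicit seed; scenes are
  bit-identical under identical spec + seed, and RNG state is restored
  after seeded calls so library use never disturbs a caller's stream.
* Degenerate inputs: empty masks, single-valued probability rasters,
  empty tables, thresholds with no true particles, and single-blank SDs
  all have defined behaviour (empty result + warning, or an explicit
  convention) rather than errors or silent guesses.
* Mosaics are assembled by exact abutment — tile geometry is known here,
  so no registration, overlap blending or seam correction is attempted.
* Config: one YAML file mirroring `default_run_config()`; unknown keys
  error. CLI artifacts ship with a manifest (config, seed, input
  checksums, version) and are never silently overwritten.
* Problem sizes in the shipped validation: training scenes 420² px,
  evaluation scenes 560–600² px at 12 particles/mm², ≥ 100 particles for
  the accuracy study, 100 replicates for breakpoint recovery, 20 random
  fixtures for the statistics cross-check — sizes at which every
  reported behaviour is stable under reseeding.

# Known limitations

* Colour-only identification cannot separate charcoal from TWP; the
  synthetic charcoal distractors make the resulting false positives
  visible and testable, but the pipeline does not attempt texture-based
  discrimination.
* The halo model is geometric, not optical: halo width is a parameter,
  not a prediction from particle size, refractive index or illumination.
* The accuracy plateau and recovery behaviour demonstrated on synthetic
  scenes validate the algorithmic chain under the stated optics model;
  physical recovery (extraction losses, particle adhesion) is outside
  what any desk-scale simulation can establish.
* The ellipsoid mass model inherits all the uncertainty of an assumed
  thickness and density; treat mass outputs as rough estimates.
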