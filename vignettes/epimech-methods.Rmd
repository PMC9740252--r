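---
title: "Methods: models, parameters and validation in epimech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation in epimech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

epimech quantifies tight-junction (TJ) assembly and epithelial cell
mechanics from fluorescence, bright-field and electron-microscopy-derived
inputs. This vignette is the package's account of the underlying models,
the tunable parameters that matter, what the synthetic-data generators do
and do not emulate, and the numerical choices made where the procedures are
genuinely open. Nothing stated here goes beyond what the test suite and the
acceptance script themselves compute.

## Coordinates, units, containers

All images use one frame: origin at the centre of the top-left pixel, x
rightward, y downward, 0-based; calibration is carried as µm/px on every
`intensity_image`. Vector fields (displacement, traction) live on regular
square lattices of spacing `h` µm; freeze-fracture strand annotations are
polylines in nm. Tabular results are tibbles so analyses compose with dplyr
pipelines; result objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Junctional intensity ratiometrics

The junctional formation index (JFI) is the mean intensity along a stroked
junctional line divided by the average of two parallel cytosolic lines.
Stroke membership is geometric — a pixel belongs to the stroke when its
centre lies within `width_px / 2` of the polyline — so measurements are
deterministic and resolution-independent. Conventional widths are 15 px for
occludin-type and 20 px for p120-catenin-type channels
(`default_stroke_width()`). A `mediatrix_line()` helper builds the
perpendicular bisector between two nucleus centres for cell pairs without a
visible junction; when to invoke it is the analyst's call, as it is a
judgement made while tracing.

Integrated densities (tricellular accumulation, junctional segment values)
subtract a background estimated as the histogram mode over the lowest 90%
of intensities — a deterministic, robust rule chosen because "measured
background" admits many conventions. Background-subtracted means are
clipped at zero: densities are physical quantities.

## Sensitized-emission FRET

For a three-filter acquisition (DD, DA, AA) with donor bleed-through
$\beta$ and acceptor cross-excitation $\gamma$ calibrated from
single-fluorophore references (least-squares slopes through the origin over
above-background pixels), the corrected transfer signal is
$F_c = DA - \beta\,DD - \gamma\,AA$ (clipped at 0) and the apparent
efficiency is $E_{app} = F_c / (F_c + DD)$ where $F_c + DD > 0$. Pixels
without signal are `NA`, never 0, so "no signal" is distinct from "no
FRET". The monotone alternative $F_c / DD$ is available via
`method = "ratio_to_donor"`. No G-factor correction is applied: the
E-cadherin tension sensor is intramolecular with 1:1 stoichiometry, so the
map is an efficiency index comparable within an instrument, not an absolute
efficiency. Lower junctional efficiency reads as higher tension on the
sensor; this is a sign convention, not a force calibration.

The `ratio_of_total` form is the default because it exactly inverts the
generative model of `make_fret_triplet()` (DD = donor·(1−E), DA =
donor·E + β·DD + γ·AA): the round trip is exact noise-free and recovers a
uniform E = 0.25 to better than 0.01 at a signal-to-noise ratio of 20.

## Cell, nucleus and focal-adhesion morphometry

`segment_cells()` thresholds the smoothed junction channel (Otsu), clears
small cytosolic specks, closes 1-px gaps, takes connected components of the
complement as cell interiors, and grows the interior labels across the
junction band with a geodesic Voronoi completion (`EBImage::propagate`).
The completion step matters: without it, per-cell areas are eroded by half
the junction band width; with it, shared junction pixels split at the
midline and areas match the generating mosaic to within a few percent.
Border-touching cells are censored (flagged, excluded from `glance()` area
statistics) since their true extent is unknown — standard morphometry
practice.

`count_nuclei()` is classical blob segmentation (Gaussian smooth, Otsu,
hole filling, distance-transform watershed, size floor). A pretrained
deep-learning segmenter would be the contemporary choice on real data;
classical segmentation is used here deliberately — it is dependency-free,
deterministic, and sufficient for blob-like nuclei, which is what the
density classification consumes. Density calls use the published count
thresholds for a 1.6×10⁴ µm² field (glass: 10–25 sparse, >40 dense;
40 kPa: 15–30 sparse, >50 dense; 1 kPa fields are never classified). The
thresholds are defined for that reference field; other field sizes are
scaled to it before thresholding, and the scaling is flagged in the output
— whether raw or normalised counts are intended for unusual fields is
genuinely open, and area-scaling is the declared choice here.

Focal adhesions: morphological (rolling-ball-style) background subtraction
via a disc opening (radius 15 px default), locally adaptive threshold
(window 51 px; offset 0.01 on the normalised scale, just above numerical
round-off so an empty background stays empty), distance-transform
watershed to split fused objects, then per-object area and maximum Feret
diameter. The Feret diameter is computed exactly as the maximum pairwise
distance between convex-hull vertices of the object's pixel centres, which
equals the maximum projected extent over all orientations; the test suite
verifies this against a 0.5°-step angle sweep on every fixture object.
Pixel-centre coordinates slightly undersample the half-pixel rim, keeping
measurements within one pixel of the analytic value for the ellipse
fixtures.

## 2D morphogenesis

Bright-field islands are textured against a smooth background, so island
outlines come from a Sobel gradient magnitude thresholded by Otsu, followed
by 3×3 median despeckle, one 3×3 dilation, hole filling and a disc opening
(radius 5 px). Components above `min_island_area` (default 200 µm², about
one cell — the cleaning steps imply a debris floor but none is published,
so it is a declared, configurable default) are islands; border-touching
islands count. Coverage is the percentage of the field covered; the
morphogenesis index is coverage divided by island count, so fragmentation
lowers it — merging two islands at fixed coverage roughly doubles it,
which the tests assert with a bridge fixture. The index is undefined (NA)
for empty fields rather than zero.

## Traction force microscopy

The substrate is an elastic half-space (Young's modulus `E`, Poisson ratio
`nu`). In Fourier space, surface displacement and traction are related per
wavevector $k$ by the Boussinesq Green tensor

$$G(k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}(1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y\\
-\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2\end{pmatrix},$$

with $\hat u = G \hat T$ forward and $\hat T = G^{-1}\hat u$ inverse
(unconstrained FTTC: no regularisation). The zero mode is set to zero (no
rigid translation / no net-force information at k = 0). Defaults: `nu =
0.5` (incompressible polyacrylamide), `E = 16400` Pa (the mean stiffness of
the TFM gels), output grid `h = 2.6` µm.

Numerical conventions, and why:

* The forward generator zero-pads the traction by a factor 2 before the
  FFT. Padding is exact for compactly supported tractions and suppresses
  periodic wrap-around of the slowly decaying (1/r) displacement field.
* The inversion applies no window and no padding by default, so that
  `fttc()` is the exact inverse of `tfm_forward()` on a shared grid — the
  central oracle identity, which holds to FFT round-off (~1e-13 relative)
  and anchors the whole pipeline. A Hann window and padding are available
  as flags for noisy experimental fields and are recorded choices, not
  silent defaults.
* Displacement estimation: coarse PIV (32 px windows, 50% overlap,
  parabolic subpixel peaks) seeds nearest-neighbour bead tracking; the
  scattered bead displacements go onto the 2.6 µm grid by Gaussian-weighted
  local plane fits (kernel sd `fit_sigma = 0.75 h`, radius `2 h`). The
  kernel width is a genuine bias–variance trade-off: wider kernels flatten
  displacement curvature at traction peaks and bias the recovered strain
  energy low by ~8–10%, while narrower kernels (or locally quadratic fits)
  pass per-bead localisation error into the unconstrained inversion, which
  amplifies high-frequency content and biases the energy high by tens of
  percent, because $U = \tfrac12\sum \hat u^* G^{-1}\hat u$ grows with the
  noise power times $k$. At 0.75 h the full pipeline recovers the
  generator's strain-energy density to within a few percent on average.
* Drift registration uses normalised cross-correlation with parabolic
  subpixel refinement, and resamples by an exact Fourier phase shift
  (bead spots are smooth, so spectral interpolation is essentially exact);
  a correlation floor of 0.2 raises a registration error on uncorrelated
  pairs.

Strain energy is $U = \tfrac12\sum_{\text{island}} (T\cdot u)\,h^2$
(Pa µm³ = 1e-18 J; reported in J and fJ), the density is U over the island
area (the polygon area when the island is a polygon, so truth and recovery
share the denominator), and the equilibrium ratio is $|\sum T| / \sum|T|$.
Islands with ratio above 0.10 are discarded; the area bounds of the final
island filter are required arguments because no defensible default exists.
Per-gel condition means are expressed as folds of the paired control.

## Freeze-fracture strand morphometry

Input is vectorised annotation (polylines in nm with per-strand appearance
labels and an apical strand id), not raw micrographs: the measurement
geometry is implemented exactly and tracing is left to the annotator or the
generator. Grid lines are placed every 200 nm of arc length along the
apical strand, each perpendicular to the local tangent averaged over a
400 nm window (a global orientation mode exists; local is the default
because replicas curve). Per grid line, the number of *distinct* strands
intersected is counted — a strand crossed twice by one line (a U-turn)
counts once. Intersections are with the infinite grid line, and tangent
touches at strand tips count as crossings; grid positions start at half an
interval so lines avoid the strand endpoints. Meshwork depth is the mean,
over grid lines crossing at least two strands, of the extent between the
extreme crossings measured along the line; a single-strand network has
depth 0 by definition (one strand has no meshwork extension). Breaks are
polyline interruptions whose end-to-end gap strictly exceeds 20 nm — a gap
of exactly 20 nm is not a break. Because the grid derives from the apical
strand, every output is invariant under rigid motions of the network,
which the tests assert.

## Barrier metrics and small statistics

TER per unit area is `(r_sample - r_blank) * filter_area` (Ω·cm²; default
area 0.33 cm², the 24-well Transwell growth area); negative blank-corrected
values are flagged, never silently dropped. The apparent permeability
converts receiver fluorescence to concentration by interpolation on a
strictly monotone standard curve, takes the least-squares slope of amount
versus time (R² reported), and divides by filter area times donor
concentration; no sink-condition correction is applied because receiver
accumulation stays far below the donor concentration in these assays. The
pooled two-proportion Z-test and the Bonferroni–Holm step-down adjustment
(delegated to `stats::p.adjust` after validation) are provided for strand
appearance proportions and the ultrastructure comparisons;
Kruskal–Wallis/Wilcoxon comparisons are ordinary base-R calls
(`kruskal.test`, `wilcox.test`) and are intentionally not wrapped.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of (parameters, seed) and always emits
ground truth alongside the images.

* `make_monolayer()`: a jittered-grid Voronoi mosaic with a bright
  junction band (half-width 8 px, so the paper-style 15 px measurement
  stroke fits inside it), cytosol and nuclei channels, additive Gaussian
  noise. Default contrast J = 200, C = 100, B = 0. The companion
  `monolayer_junction_rois()` places the junction line on each shared edge
  (trimmed away from tricellular corners) and the cytosolic lines at a
  normal offset that clears the band — with a 15 px stroke, a small fixed
  offset would overlap the band, so the default is band half-width +
  stroke/2 + 3 px, validated per-ROI against the truth distance map.
* `make_tfm_pair()`: Gaussian traction spots through the forward model;
  beads rendered as Gaussian PSF spots of sd 1 px (0.20 µm beads are below
  the diffraction limit, so the PSF sets the spot size), uniform random
  placement at 1 bead/µm² by default, optional Gaussian localisation
  noise on the stressed positions.
* `make_fret_triplet()`, `make_strand_network()`, `make_adhesion_image()`,
  `make_nuclei_image()`, `make_island_field()`: as described above, each
  with closed-form or read-back truth.

Not emulated: optical aberrations, shot (Poisson) noise by default,
photobleaching, uneven illumination, out-of-focus haze, real junction
tortuosity, strand branching at tricellular contacts, or 3D cyst imagery.
Passing the recovery tests therefore shows the *computations* are correct
and well-conditioned at realistic noise levels — it does not certify
segmentation performance on arbitrary real micrographs, where parameter
defaults (thresholds, size floors, watershed tolerances) may need
adjustment; all are exposed as arguments and echoed in outputs.

## Validation scale and limitations

The test-suite problem sizes are chosen for thorough coverage at desk
scale: 512–600 px monolayers with 16–25 cells, 80 µm TFM fields (400² px,
~6400 beads, 31² analysis nodes) over 10 seeds, 128²-node inversion grids,
1000² px island fields, and 4-strand meshworks. Known limitations: the
unconstrained inversion is noise-amplifying by construction, so strain
energies from low-bead-density or high-noise data will be biased high
unless the optional window is enabled; the TER/flux records assume the
standard two-compartment Transwell geometry; TIFF export is unsigned
integer (8/16/32-bit), so continuous-valued maps are quantised on export
while the tabular outputs remain exact; and the classical nuclei counter
will undercount heavily overlapping nuclei that a learned segmenter would
separate.
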