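---
title: "3D X-ray histology: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D X-ray histology: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrh)
```

## The imaging model

An unstained FFPE block imaged by laboratory μCT produces a 3D map of X-ray
attenuation with three gray-value populations, ordered air < paraffin wax <
dehydrated tissue. Everything in this package rests on that ordering: it is
what makes a wax block self-calibrating (air and wax are always present and
chemically stable), what makes absolute-threshold segmentation meaningful,
and what the synthetic phantoms emulate.

Volumes are scalar 3D grids with an isotropic voxel size in micrometres
(8.48 μm is the default, the value of the scanning protocol the toolkit was
designed around). Arrays are indexed `[z][y][x]`; the XY plane (fixed z) is,
by convention, parallel to the histology cassette, so stepping through z is
virtual serial sectioning. Continuous coordinates are zero-based with voxel
centres at integers; the physical position of voxel `(z, y, x)` is
`(x, y, z) * voxel_size_um`.

## Preprocessing chain

Reconstructed 32-bit volumes pass through a fixed chain before calibration:

1. **3D median filter**, neighbourhood half-width `radius` (default 1, a
   3×3×3 window). A radius-parameterized median is the only reading under
   which a "unit kernel" denoises at all — a literal single-voxel window is
   the identity — so the default is the smallest genuine window, and the
   radius is exposed.
2. **2D unsharp mask per slice**:
   `out = (I − w·G_σ(I)) / (1 − w)` with Gaussian σ = 2 px. The mask weight
   is not a protocol constant anywhere we could anchor it; the default
   `w = 0.6` is the customary default of interactive unsharp tools, and the
   normalization by `(1 − w)` keeps flat regions at their original level
   (constants and linear ramps pass through unchanged away from borders).
3. **Linear windowing to 16-bit**: the window (−50, 100) brackets air, wax
   and soft tissue in the reconstructed float data; values map linearly onto
   `[0, 65535]` with round-half-up and clamping. Round-half-up (rather than
   banker's rounding) makes quantization bit-exact and platform-independent.

Both filters replicate edges. Replication introduces no out-of-range values
at the block borders, which matters because the histogram analysis
downstream keys on population extremes.

## Gray-value calibration

For one scan containing air and wax with mean gray values $I_{air}$,
$I_{wax}$, the **contrast factor**

$$Cf = \frac{I_{wax} - I_{air}}{I_{wax}}$$

is the normalized air/wax contrast. A wax phantom scanned under identical
settings anchors a batch: the **calibration factor** $f = Cf_{phantom} /
Cf_{sample}$ multiplies the sample, and the result is offset linearly so the
mean air gray is 0 (offset $= f \cdot I_{air,sample}$), then negatives are
clamped to 0. Choosing wax (not water) as reference and air = 0 keeps every
calibrated gray positive, the dehydrated-specimen analogue of offset
Hounsfield units.

Two observations shaped the implementation:

- $Cf$ is invariant under pure rescaling of the grays, so once air sits at
  0 the contrast factor of *any* calibrated volume is identically 1. The
  "contrast transfer" guarantee is therefore stated between calibrated
  volumes: after calibration, sample and phantom have equal contrast
  factors (both 1 within one gray level of the wax reading). Scaling a
  sample's raw grays by $c$ scales its calibrated output by exactly $c$ —
  the tests assert this algebra rather than a folklore invariance.
- Clamping negatives biases the mean of a *noisy* air region upward by about
  $\sigma/\sqrt{2\pi}$. The air-assigned-0-within-±0.5 contract is exact in
  the regime it was stated for — populations whose spread is small against
  one gray step, where rounding is the only error source — and the
  acceptance fixtures use exact populations with seeded means accordingly.

**Level estimation** defaults to histogram analysis of the central z-slice
(air = lowest mode, wax = next above), with an ROI-mask override giving
exact means over known regions (the stand-in for manually placed ROIs).
The histogram uses 256 bins, an 11-bin running-mean smoother, local maxima
with a height floor of 10% of the tallest peak, and a merge rule that fuses
peaks not separated by a genuine dip (valley below 60% of the smaller
peak). The floor and the dip rule exist because the unsharp mask rings at
material borders: the rings form low-mass satellite modes well below any
bulk population. Each mode's mean is taken over the samples inside the
peak's half-height span — a symmetric truncation, unbiased for symmetric
populations and insensitive to border tails. A constant slice, or any slice
with fewer than two such modes, is an error, not a guess.

**Stability reporting** summarizes calibrated scans per material as the
grand mean over specimen means, SEM = sd/√n over those means (not over
voxels), and the maximum percent fluctuation relative to the grand mean —
the form in which multi-month protocol stability (wax within 1%, tissue
within 2%) is quoted.

## Morphometry

Segmentation is absolute thresholding inside a volume of interest.
The threshold is deliberately a *required* argument everywhere, including
the CLI: cross-specimen comparability comes from applying one identical
absolute threshold per study, and its value depends on the study's
calibrated scale — a silent default would be a scientific bug.

**Local thickness** follows the maximal-inscribed-sphere definition: at
point $p$, the diameter of the largest sphere containing $p$ that fits in
the structure. The implementation is exact Euclidean distance transform
(Felzenszwalb–Huttenlocher, integer-squared distances), a redundant-sphere
reduction, and sphere painting. Discretization conventions, fixed once:

- the volume border counts as background;
- a sphere seated at voxel $q$ with EDT value $e$ has radius $r = e - 0.5$
  and covers voxels with centre distance $< r + 0.5$, i.e. integer
  $d^2 < e^2$ — all comparisons are exact integer arithmetic;
- thickness $= 2e - 1$ voxels, so an isolated voxel has thickness one voxel
  and a full-width slab of $t$ voxels has thickness exactly $t$;
- the reduction drops a sphere only when a 26-neighbour's sphere provably
  contains it ($r_p \ge r_q + |p-q|$, with a conservative margin); keeping a
  redundant sphere cannot change the painted maximum, so the result equals
  the exhaustive computation voxel for voxel — the test suite checks this
  against an independent brute-force oracle on dozens of random fixtures.

Digital geometry caveat: a digital ball of diameter $d$ (voxel centres
strictly inside radius $d/2$) measures slightly under $d$ (e.g. 14.1 for
$d = 15$), because its nearest outside voxel sits only marginally beyond
the continuous radius in diagonal directions. This is a property of the
discretization, not an implementation error; the shape recovery guarantee
is stated as within one voxel at ≥95% of foreground voxels.

Mean thickness is the plain mean over foreground voxels (each voxel carries
equal volume, so this is the volume-weighted arithmetic mean); the
histogram uses a fixed bin width defaulting to one voxel (8.48 μm), the
resolution at which per-voxel thickness distributions are reported. Volume
fraction is the exact count ratio foreground/VOI.

## Rendering

Axis-aligned MIPs are exact per-column maxima. Oblique MIPs resample the
volume on a rotated grid with *trilinear* interpolation and then take
column maxima; bicubic is reserved for 2D reslicing, where it is the
protocol's stated interpolator. Rotating MIP sequences use bases that
rotate continuously with the angle and coincide with the single-direction
MIP frame at angle 0, so frame 0 is bit-identical to the direct call.
Out-of-volume samples pad with 0 — the calibrated value of air. Orthogonal
views are exact array extractions (no interpolation). The bicubic kernel is
Keys cubic convolution (a = −0.5): exact at lattice points (lattice-aligned
oblique slices are bit-identical to stored slices) and linear-reproducing;
support taps beyond the border are clamped, which preserves lattice
exactness at the edge.

## Coregistration

Histology sections are cut from the scanned block, so each slide has a
geometric counterpart inside the volume. Three or more landmark pairs
(2D slide pixels ↔ 3D voxel coordinates, as a plain CSV with header
`x2d,y2d,x3d,y3d,z3d`) define a total-least-squares plane (centroid +
smallest principal direction as normal; principal axis signs are
canonicalized so the basis is reproducible). The matching virtual slice is
resampled with bicubic interpolation, together with a ladder of candidate
slices at offsets along the normal: slice choice is assisted — optionally
ranked by normalized cross-correlation against a reference — but never
silently automatic, mirroring the visual-identification step of the manual
protocol.

The elastic step is a landmark-interpolating thin-plate spline
(`U(r) = r² log r`, affine part plus radial coefficients, regularization
weight λ with λ = 0 interpolating). This stands in deliberately for the
external vector-spline plugin of the original workflow: the contract is
identical — landmarks in, smooth landmark-exact warp out — and
intensity-driven refinement is out of scope. The spline reproduces affine
maps with vanishing radial coefficients and maps each source landmark
exactly onto its target; images are resampled through the backward fit with
bicubic interpolation; collinear landmarks degrade to an affine-only fit
with a warning. The registration report gives per-landmark residuals and
the displacement-magnitude field |fwd(x) − x| — a map of how far the
section had to be unwarped.

## What the phantoms emulate — and what they do not

The generators produce: a wax cylinder in air (calibration standard);
geometric primitives (balls, slabs, rods) whose true thickness is the
defining diameter; foam-like parenchyma as a thresholded Gaussian random
field, thresholded at the exact order statistic so the achieved volume
fraction is known *by construction*, never measured by the code under test;
a complete FFPE block (air surround, wax block, foam tissue in a VOI); and
histology/CT pairs `H(x) = S(x + u(x))` with a known smooth displacement
field, a stain-like palette, and landmark pairs `(x, x + u(x))` placed
stratified over the section the way an operator spreads them. The
deformation field is long-wavelength (periods of the order of the section
extent, amplitude a few pixels) — the stretch/shear/bend regime of
mechanical sectioning that a sparse landmark set can capture; recovery is
scored against the forward field, avoiding numerical inversion.

Defaults sit on the calibrated 16-bit scale of the reference protocol: air
0, wax 30419, tissue 40289, voxel 8.48 μm, so synthetic histograms resemble
real calibrated stability data. Raw-scale means are free parameters for
preprocessing/calibration fixtures.

Not modelled: CT noise texture (streaks, rings, beam hardening), partial
volume at interfaces beyond what Gaussian blur induces, stain variability,
tears or folds in sections (the deformation is smooth and invertible), and
anisotropic voxels. Passing tests therefore demonstrate correctness of the
algorithms under the stated gray-level model, not robustness to scanner
artefacts.

## Problem sizes and determinism

All generators are bit-reproducible under `(seed, parameters)` and restore
the caller's RNG state. The test suite runs on volumes between 6³ and
roughly 40×96×96 voxels: brute-force oracle comparisons use ≤16³ fixtures
(where exhaustive sphere fitting is exact and fast), foam morphometry uses
48³, and the end-to-end pipeline 40×96×96 — sizes at which every check is
exact or statistically sharp while the whole suite runs in seconds. The
acceptance script processes a 32×80×80 block and phantom pair per seed.

## Known limitations

- Histogram-based level estimation assumes bulk air and wax populations
  (each ≥10% of the tallest mode on the analysed slice); heavily cropped
  scans should use ROI masks instead.
- Even-diameter geometric balls centred on voxels are asymmetric by one
  voxel; use odd diameters (or half-integer centres) for benchmark shapes.
- The TIFF writer stores 16-bit unsigned only; float volumes go to
  raw + sidecar (lossy implicit conversion is refused by design).
- `rotating_mip` frames are sized by the volume diagonal and padded with 0;
  they are not cropped to content.
- Thin-plate-spline recovery degrades for deformation wavelengths shorter
  than the landmark spacing — as it must; the reported displacement map and
  landmark residuals are the practical diagnostics.
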