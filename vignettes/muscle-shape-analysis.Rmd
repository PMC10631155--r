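---
title: "Quantifying muscle cross-section shape with covariance ellipses and the J index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle cross-section shape with covariance ellipses and the J index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jshape)
```

## The problem

Supine MRI deforms bulky musculature: the posterior thigh rests on the
table, and the amount of knee elevation changes how soft tissue is
distributed relative to the imaging plane. A muscle's segmented anatomical
cross-sectional area (CSA) therefore carries a positioning-dependent shape
component. `jshape` quantifies that component per slice with a single
scalar — how elliptical the cross-section is — and tracks how it shifts
between positioning conditions.

## The model

### Covariance ellipse fit

A segmented slice is a binary mask on an anisotropic pixel grid. Every
foreground pixel contributes one point at its physical center
(`(index + 0.5) × spacing`, 0-based indices), giving a filled point cloud —
the covariance of a filled lamina, not of its boundary, is what the
analytic identities below assume. With population covariance `Σ`
(divide-by-`N`; the lamina identities are exact for this normalization and
the `N`/`N−1` difference is negligible at realistic pixel counts, but it
must be pinned for exact oracle tests), the eigen-decomposition
`Σ = V diag(λ₁, λ₂) Vᵀ`, `λ₁ ≥ λ₂`, yields:

* center — the centroid;
* orientation — the angle of the `λ₁` eigenvector, normalized to [0°, 180°);
* aspect ratio — `√(λ₁/λ₂)`;
* semi-axes — `a = 2√λ₁`, `b = 2√λ₂` by default.

The `2√λ` scaling is exact for a uniformly filled elliptical lamina (its
covariance eigenvalues are `a²/4`, `b²/4`): a disc of radius `r` has
`λ = r²/4`, a `w × h` rectangle has `λ₁ = w²/12` so the fitted
`a = w/√3`. These closed forms are the package's test oracles. Because only
the ratio and orientation are canonical consequences of the
eigen-decomposition while the absolute scaling is a modelling choice, an
alternative area-matching scaling (`πab` equals the mask area; aspect ratio
and orientation unchanged) is available via
`study_config(ellipse_scaling = "area")` and `fit_ellipse(scaling =
"area")`. The default is `2√λ` because it is parameter-free and makes the J
index of a true ellipse maximal (degenerate, see below).

Numerical edge cases are pinned deterministically: eigenvalues equal within
a relative `1e-9` (a circle has no principal axis) force orientation 0°;
`λ₂/λ₁ < 1e-6` (a near-collinear cloud) raises a degenerate-geometry error
rather than returning a meaningless ellipse; fewer than 3 points is an
error.

### The J index

The fitted ellipse is rasterized back onto the mask's grid by pixel-center
containment — a closed region: boundary centers count as inside — and

\[ J = \frac{|A \cap E|}{|A \,\Delta\, E|} \]

with `A` the mask and `E` the rasterized ellipse. The denominator is the
symmetric difference (area in *exactly one* region), not the union: this is
**not** the Jaccard index, though `J = \mathrm{Jaccard}/(1 -
\mathrm{Jaccard})` monotonically. Working on the rasterized grid rather
than with continuous geometry matches how the segmentation itself is
defined and makes the pixel-counting identity
`|A| + |E| = 2|A∩E| + |AΔE|` hold exactly, which the tests exploit.

If the mask equals the rasterized ellipse exactly the denominator is zero.
The continuous-limit value is infinite, so such slices are flagged
`degenerate`, excluded from means, and written to the output tables with
the sentinel `degenerate` — capping them at some large value would silently
bias per-muscle means.

### Aggregation and comparison

Per muscle and position, the mean and sample (`n−1`) SD of J are taken over
included slices (sample SD being the standard convention for reported
mean ± SD; a single slice reports SD 0). Slices with fewer than
`min_pixels` foreground pixels (default 10) are excluded: covariance fits
on a handful of muscle-end pixels are meaningless, and no principled
inclusion rule exists for end slices, so the threshold is explicit and
configurable.

Conditions are compared by percentage change of mean J against a reference
position, `|J̄_b − J̄_ref| / J̄_ref × 100`. The no-elevation condition is the
natural baseline ("changing elevation *from* 8° *to* 15°") and shape
deviation can move in either direction across conditions, so the magnitude
is reported with the signed change retained alongside.

With several subjects, per-subject summaries are emitted together with two
aggregation readings, because either may be wanted when comparing against
externally reported values: `ALL` (unweighted mean of subject means, SD
across subjects) and `POOLED` (all subjects' slices pooled). For one
subject only its own rows appear.

### Knee-elevation angle

The goniometer module measures `arccos(|û · n̂|)` between the femoral axis
(two user-supplied landmarks in physical coordinates — the package does not
detect the femur) and the imaging-plane normal, which defaults to the
slice-stacking direction `(0, 0, 1)` since the acquisitions are transverse.
Folding by the absolute value makes the result independent of landmark
order and confined to [0°, 90°].

## The synthetic phantom

`default_phantom_spec()` encodes a three-condition study of seven thigh
muscles — hamstrings (biceps femoris, semitendinosus, semimembranosus)
posterior, quadriceps (rectus femoris, three vasti) anterior — on a
256 × 288 grid at 0.65 × 0.65 mm in-plane spacing with 40 slices of 3 mm,
matching a typical thigh MRI acquisition. Base semi-axes (10–26 mm) are in
the range of adult mid-thigh cross-sections; both axes taper along the
normalized muscle length `s` as `(4s(1−s))^{0.25}` and centers drift
linearly a few millimetres to mimic oblique muscle paths.

Surface-contact deformation is modelled as **chordal truncation**: all
pixels below `y_min + f (y_max − y_min)` are removed, cutting a D-shape
into the posterior side. This is the simplest one-parameter family with
analytically checkable geometry whose J index provably degrades as `f`
grows; it is a truncation, not a volume-preserving squash — volume
preservation is irrelevant to a per-slice shape index. `f` is capped at
0.45 at spec level so every slice stays non-empty. The default schedule
flattens the hamstrings increasingly across conditions (none 0.05, modest
0.15, high 0.30) with quadriceps fixed at 0.02, so the hamstrings' shape
change dominates — the qualitative signature the study design probes. The
nominal condition angles are high = 15°, modest = 12°, none = 8°.

Segmentation jitter is emulated by flipping pixels within one pixel of the
region boundary (4-neighborhood) with probability
`min(0.5, σ / (2 · mean(spacing)))`, default σ = 0.3 mm — roughly
quarter-pixel-scale raggedness that cannot disconnect the region interior.
One seeded generator drives all randomness and the seed is recorded in the
manifest, so identical specs reproduce byte-identical volumes.

What the phantom does **not** emulate: real muscles are not ellipses even
unloaded, neighbouring muscles share deformed boundaries, intensity-based
segmentation errors are spatially correlated, and real deformation
redistributes rather than removes tissue. Passing tests therefore
demonstrate that the *pipeline* measures what it claims on controlled
geometry — not that real thigh shape change follows the truncation model.

## Numerical choices and test design

* Rasterization and overlap are pixel-center decisions, so all overlap
  tests can demand *exact* pixel-count equality against independent
  double-loop oracles, and the covariance path is checked bitwise against a
  brute-force enumeration of pixel centers on masks up to 64 × 64.
* Discretization consistency: halving the pixel spacing of a fixed
  continuous shape changes J by < 5% once the shape is resolved at
  sub-millimetre spacing (tests refine 0.5 mm → 0.25 mm on 18–30 mm
  shapes); at coarse 1 mm grids small shapes can still move J by ~10%,
  which is why the phantom uses MRI-scale 0.65 mm pixels.
* Fit-parameter recovery (axes within 2%, orientation within 2°) is
  asserted for generated ellipses with both semi-axes ≥ 15 px, where
  discretization bias is below the tolerance.
* Test problem sizes: unit and property tests use 64–90 px grids and a
  reduced phantom (10 slices, 128 × 144 px at 1.3 mm); the end-to-end
  ordering check and the acceptance script use the full default phantom
  (3 × 40 slices at 256 × 288 px), which runs in well under a minute each.

## Limitations

* The analysis is strictly per-slice; no 3-D surface or volume shape index
  is computed, and muscle volume or line-of-action changes are out of scope.
* The covariance fit is the specified method; boundary-based algebraic
  conic fits are deliberately not provided.
* Reading DICOM and performing segmentation are out of scope: the package
  consumes already-segmented NIfTI label volumes or per-slice PNG/CSV
  masks.
* Statistical hypothesis testing across subjects is not performed; the
  pipeline reports descriptive summaries and percentage changes only.
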