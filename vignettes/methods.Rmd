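---
title: "Quantifying 3D plaque morphology in phase-contrast tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D plaque morphology in phase-contrast tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cereplaq)
```

## The measurement problem

X-ray phase-contrast tomography (XPCT) of cerebellar cortex resolves
beta-amyloid plaques as hyper-intense clusters — a dense core inside a
fainter corona — embedded in the molecular layer, together with
near-spherical Purkinje somata lined along the granular–molecular
interface, and blood vessels. From a reconstructed isotropic gray-level
volume (1.625 µm voxels by default), `cereplaq` computes per-plaque
volume, surface area, sphericity and principal-axis orientation, and
population statistics: the plaque volume distribution and its log-normality,
sphericity summaries and a plaque-vs-Purkinje group comparison, and
undirected axial orientation statistics resolved by anatomical region.

A fixed anatomical frame underlies all angle arithmetic: grid axis 1 is
dorso-ventral, axis 2 medio-lateral, axis 3 anterior-posterior, so axis-3
slices are coronal planes. An axis `(v_DV, v_ML, v_AP)` is reported as
azimuth `atan2(v_ML, v_DV)` and elevation `asin(v_AP)` in degrees; a vector
normal to the transverse plane has azimuth 0 (or ±180) and elevation 0, and
a vector normal to the sagittal plane has azimuth ±90. Elevation is
restricted to [−90°, 90°]: plaque axes are sign-ambiguous, and any wider
elevation range for such axes is a plotting convention, not a distinct
orientation, so the package does not reproduce one.

## Segmentation model

Plaque segmentation is semi-automatic, mirroring how an annotator works on
maximum intensity projections: each candidate plaque gets a circular
in-plane seed with a coronal slice range, which the package extrudes into a
cylindrical volume of interest (VOI). Gray values of **all** VOI voxels are
pooled into one 256-bin histogram; after a 5-bin moving-average smoothing,
peaks are detected by prominence (≥ 1% of the maximum smoothed count). With
two or more surviving peaks, the two most prominent are taken as tissue
background and plaque, and the threshold is placed at the count minimum
between them — the midpoint of the minimal plateau on ties. The histogram
valley is a deliberate choice: the peak pair fixes only the interval, and
the valley is the gray value that misclassifies fewest voxels under any
two-component mixture with well-separated modes. When fewer than two peaks
survive, Otsu's threshold is used instead and the result is flagged, never
silent. Foreground is strictly `gray > threshold`; components are
26-connected by default (6 available); and components with physical volume
at most 150 µm³ are discarded — both inequalities strict so that counts are
reproducible. Bright vessels inside a VOI stay out of the plaque mask
because the valley threshold sits far below their gray level; an optional
maximum-gray cap exists but is off by default.

Purkinje somata are segmented by shape, not by seeds. At each scale *s* of
a multi-scale bank (defaults 6, 8, 10, 12 µm, the soma radius range) the
volume is Gaussian-smoothed, the per-voxel Hessian is formed with
scale-normalized (s²-multiplied) second derivatives, and eigenvalues are
sorted by magnitude |λ1| ≤ |λ2| ≤ |λ3|. Bright blobs curve downwards in
all directions, so blobness is zero unless all eigenvalues are negative,
and otherwise

B = (|λ1|/|λ3|) · (1 − exp(−(λ1² + λ2² + λ3²)/(2c²))),

with c half the maximum Hessian Frobenius norm at that scale. The first
factor vanishes on tubes (λ1 ≈ 0 along the axis) and plates; the second
suppresses low-contrast responses. The per-voxel maximum over scales gives
the blobness map. Detection is two-stage: blobness above a cutoff (default
0.5) proposes candidate components, and each candidate's full soma extent
is recovered by a local gray refinement — a threshold halfway between the
gray at the blobness peak and the median of a local crop. A plain local
Otsu fails here because the background itself is bimodal (the granular
layer is brighter than the molecular layer), which is also why the
refinement uses the peak gray as the bright anchor. Refined regions are
kept when their equivalent-sphere diameter lies in 12–30 µm. The
blobness functional is isolated in one function so the "modification" can
be swapped; tie-breaking in the |λ| sort uses the signed value.

## Morphometry

Volume is voxel count times voxel volume; the centroid is the mean of
voxel centers; physical coordinates are voxel-center based. Sphericity is

S = π^(1/3) (6V)^(2/3) / A,

the surface area of the equal-volume sphere over the measured surface area:
1 for a sphere, below 1 for elongated objects, deliberately not clamped —
values above 1 flag surface underestimation on coarsely digitized regions.

The surface estimator is the single most consequential numerical choice.
Counting exposed voxel faces overestimates the area of smooth bodies by up
to ~50%, and even a 0.5-level triangulation of the raw binary lattice
overestimates by 8–10% (the piecewise surface follows lattice planes), which
would bias every sphericity well below its true value. `cereplaq` therefore
triangulates the 0.5 level set (marching tetrahedra on the zero-padded
mask) after a light Gaussian pre-smoothing. Smoothing removes the lattice
bias but shrinks the surface by a curvature term of order σ²/r, so the
smoothing scale adapts to object size: σ = clamp(r_eq/8, 0.5, 1.2) voxels,
with r_eq the equivalent-sphere radius. At these settings a digitized
sphere measures S = 1.018, 1.001, 0.997 at radii 10, 20, 40 voxels, and a
digitized 2:1 prolate spheroid measures 0.932 against the closed-form
0.929. Objects too small to retain a 0.5 crossing after smoothing fall
back to the raw-mask triangulation and are flagged; such objects sit below
the 150 µm³ filter in practice.

Orientation is the eigenvector of the largest eigenvalue of the second
central moment matrix of voxel centers (unweighted; a gray-weighted variant
is a config option). The sign is canonicalized (largest-magnitude component
positive) for reporting only — all statistics treat axes as undirected.
When the top two eigenvalues agree to a relative gap below 1e-6 the object
is effectively isotropic and the axis is flagged undefined; a perfectly
symmetric digitized ball triggers this exactly. Moment eigenvectors are the
standard reading of an "enclosing ellipsoid" axis; a minimal bounding
ellipsoid would weight extreme voxels more and is not used.

## Population statistics

`summarize_values` reports mean, sample SD, adjusted Fisher–Pearson
skewness and type-7 quantiles. For orientation analysis only objects with
S strictly below (mean + SD) of the sphericity distribution enter, because
near-spherical objects carry no reliable axis; under a Normal sphericity
model the retained fraction is Φ(1) ≈ 0.84. Log-normality of volumes is
assessed exactly as the visual overlay it supports: the log-volume
histogram against the Gaussian with the *same* mean and SD (moment-matched,
not MLE-fitted), plus the Kolmogorov–Smirnov statistic of that comparison.
The group comparison is a two-sided Mann–Whitney U — sphericity is bounded
and skewed, so a rank test is preferred over a t-test; which test produced
the original P < 0.05 is not recorded in the source material, and the
choice is noted in the report metadata. For both group sizes ≤ 8 the
p-value is computed by exact enumeration (tie-aware), making small-sample
tests deterministic.

The mean of undirected axes is the principal eigenvector of the orientation
tensor T = (1/n) Σ aᵢaᵢᵀ. Per-axis deviations arccos|aᵢ·mean| summarize
into 50th/90th-percentile "cone semi-angles", overall and after projecting
the axes into two named coordinate planes (default transverse and coronal),
which resolves anisotropic cones like the vermis pattern. The 2D
azimuth–elevation histogram (10° bins) counts each axis at both antipodal
representations, reproducing the paired clusters that sign-ambiguous axes
produce in such plots. Cone semi-angles are operationalized as the
90th-percentile deviation; published envelope figures of this kind (~30°
hemisphere, 60°/30° vermis) are approximate visual reads, so the package's
accuracy claims rest on recovery of known phantom parameters, not on
matching real-data envelopes.

## The synthetic phantom

No tomographic volumes are publicly deposited for this tissue, so the
package ships a ground-truthed generator emulating the features the
analysis relies on: three gray-ordered layers (white 85, granular 120,
molecular 100 — granular brighter than molecular) with interfaces warped by
a single sinusoid (amplitude 20 µm, period 300 µm) to create a spatially
varying layer normal; prolate plaques confined to the molecular layer with
log-normal true volumes (median 1000 µm³, sdlog 1.25 — chosen so that half
the volumes fall below 10³ µm³ and ninety percent below 5·10³ µm³, the
quantile ratio implying sdlog = ln 5 / 1.28), uniform aspect ratio 1.5–3.5,
corona +60 and core +100 gray offsets at a 0.15 core volume fraction;
Purkinje-like spheres (15–25 µm diameter, +70) centered on the
granular–molecular interface; straight vessels (+60) in the coronal plane;
and additive Gaussian noise (σ = 5). The offsets are set once so that the
VOI histogram valley (~130) clears the granular gray: brighter neighboring
structures then stay out of plaque masks for the same reason they do in
real data. The default 256³ grid splits into a "hemisphere" half (preferred
plaque axis dorso-ventral, isotropic 30° spread) and a "vermis" half
(preferred axis medio-lateral, anisotropic spread: 60° towards
anterior-posterior within the transverse plane, 30° towards dorso-ventral).
Isotropic cones sample uniformly over the spherical cap; anisotropic cones
sample uniformly over an elliptical disk in deviation-angle space.

Objects are placed by rejection sampling with 200 retries and then an error
naming the object class — silent overlap would corrupt the ground truth.
Each object keeps a 1.5-voxel clearance from other objects and layer
boundaries, so segmented components never merge. Aspect ratios are a free
choice (no published values exist); 1.5–3.5 makes the measured sphericity
distribution straddle 0.82. The generator is deterministic given its seed
and restores the caller's RNG state.

What the phantom does *not* emulate: phase-contrast fringes and ring
artifacts (handled upstream of this package in practice), folium topology
beyond a single sinusoid, vessel branching, and partial-volume gray
gradients at object boundaries (objects are rendered with hard gray
offsets). Tests passing on the phantom therefore demonstrate correct
geometry, thresholding and statistics under the stated contrast model — not
robustness to reconstruction artifacts or to plaques whose gray overlaps
the granular layer, which the original semi-automatic procedure also could
not separate.

## Numerical and interface choices

* Volumes: HDF5 (`/volume` dataset with a `voxel_size_um` attribute;
  bit-exact float64 round-trip) or multi-page TIFF, one page per coronal
  slice. TIFF samples are stored min–max normalized as 32-bit values with a
  JSON sidecar carrying the voxel size and gray scaling, because baseline
  TIFF tags writable from R do not cover them; a stack without metadata is
  readable only with an explicit voxel-size override, otherwise reading
  fails naming the missing piece.
* Maximum intensity projections cover floor(thickness/voxel) slices,
  minimum 1 — 25 µm at 1.625 µm voxels projects 15 slices.
* The pipeline's global seed fans out to per-stage seeds by a fixed hash of
  the stage name; identical configuration and seed give byte-identical CSV
  and JSON outputs, and the run manifest lists every output with an MD5
  checksum.
* Default problem sizes used by the test-suite phantoms (160–256 voxels per
  axis, 20–120 plaques, 8–60 somata) were chosen as the smallest grids that
  hold the full layer geometry and the study's object counts without
  placement jamming.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 20)            # 256^3 study conditions
cfg <- pipeline_config(phantom = spec, out_dir = "run", seed = 20)
res <- run_pipeline(cfg)

rec <- subset(res$records, class == "plaque")
summ <- summarize_values(rec$sphericity)
el <- select_elongated(rec, summ)
orientation_summary(el)
```

## Known limitations

* Sphericity of objects below ~10 voxels is dominated by digitization and
  is only comparable within a fixed estimator; cross-study comparisons
  should match surface estimators first.
* The blobness cutoff is contrast-normalized per scale via the maximum
  Frobenius norm, so extremely bright non-blob structures in the same
  volume lower the effective sensitivity; the cutoff is a config parameter.
* Region assignment for file-based inputs inherits the nearest seed's
  region tag; for atlases with interdigitated regions supply explicit tags
  per seed.
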