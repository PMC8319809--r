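---
title: "Quantifying bacteria-nanotopography interactions from slice-and-view stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacteria-nanotopography interactions from slice-and-view stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocontact)
```

## The measurement problem

Nanostructured surfaces (nanopillar fields on titanium or silicon) can kill
bacteria by mechanically interacting with the cell envelope. Classifying
those interactions - no effect, deformation, penetration, rupture,
impedance - and quantifying them (depths, contact areas, cell volume loss)
requires the full three-dimensional adhesion interface. FIB-SEM
slice-and-view imaging supplies it: an ion beam mills consecutive
cross sections (20-30 nm steps) that an electron beam images at a stage
tilt, and the resulting anisotropic image stack is aligned, corrected for
tilt foreshortening, segmented into substrate / pillar / envelope / cytosol
classes, and reconstructed into triangle meshes on which morphometry is
performed.

`nanocontact` implements that pipeline end to end, together with a
ground-truthed phantom generator. Raw FIB-SEM stacks for this kind of study
are rarely deposited, so the phantom is a first-class component: it builds
scenes with *known* interactions and simulates their acquisition, making
every downstream stage testable against exact truth.

## The phantom

**Pillar fields.** A surface type is described by an areal density (per
um^2), truncated-normal height and tip-diameter distributions, an
orientation mode and a hard-core minimum spacing. Four presets mirror the
characterized surfaces this pipeline targets: `ah-ns-medium` (444 +/- 85 nm,
43 +/- 9 nm tips, 36 per um^2, random orientation), `to-ns-short` (350 +/-
52, 27 +/- 4, 58), `to-ns-long` (1700 +/- 347, 114 +/- 26, 8) and
`pe-ns-short` (181 +/- 26, 50 +/- 6, 137, vertically aligned). Pillar
counts are Poisson draws with expectation density x area; placement is
seeded uniform rejection sampling honoring the minimum spacing, failing
loudly after a 100x attempt budget. Minimum spacings are not reported for
the real surfaces; the presets carry conventions scaled to the mean pitch
(40-200 nm), exposed as configuration.

**Pillar shape.** A truncated cone (base diameter defaulting to twice the
tip diameter) capped by a hemispherical tip - enough degrees of freedom to
match tapered pillar profiles without over-parameterization.

**Cells.** A coccus is a sphere (S. aureus, 1 um default diameter,
sectioned at 20 nm); a rod is a spherocylinder (E. coli, 500 x 2000 nm,
sectioned at 30 nm). Analytic surface area and volume travel with each cell
for oracle use. The envelope is rendered as a 40 nm shell - a rendering
construct chosen to exceed one voxel, not a biological claim; real
wall/membrane stacks differ between the organisms.

**Imposed interactions.** `compose_scene()` adjusts each referenced pillar
so the intended relationship holds exactly on the analytic geometry before
voxelization: a *none* apex touches the envelope; a *penetration* apex ends
`depth_nm` inside the cell (the pillar locally overrides the envelope - the
opening); a *deformation* apex rests on the floor of a smooth cosine dimple
(default 60 nm deep, 200 nm radius) that the envelope shell follows at
constant thickness; *impedance* shifts the pillar base until its flank is
tangent to the cell flank at zero indentation; *rupture* first shrinks the
cell isotropically to `1 - volume_deficit_fraction` of its reference volume
(turgor loss), then penetrates. Tips narrower than a voxel are voxelized
with an explicit apex voxel chain so the apex always exists on the grid.
Ground truth records the *realized* values measured on the pristine grid -
depths from the interior distance field, contact areas from the pristine
meshes - because voxelization itself quantizes the intended values by up to
one voxel.

**Acquisition.** Labels map to 8-bit gray levels (background 20, cytosol
60, substrate 90, envelope 160, pillar 200 - separable by thresholding yet
close enough to stress segmentation under noise). The in-image vertical
axis is compressed by `sin(tilt)` (52 degrees by convention), slices drift
by an integer random walk (the canvas grows so drifting content stays in
view, as an operator framing the region would), and images carry Gaussian
noise, optional curtaining stripes, and a smooth volumetric *texture*
locked to the scene content. The texture models the material graininess of
real milled faces; it is what makes translation registration well posed on
cross sections whose classes are otherwise locally uniform.

## Stack processing

Alignment estimates one integer-pixel translation per slice pair by
FFT cross-correlation of mean-subtracted images, accumulated from the
first slice; ties break toward the smallest displacement, then
lexicographically. Sub-pixel registration is deliberately out of scope:
slice thickness (20-30 nm) dominates the error budget, and integer shifts
make the noise-free recovery property exactly testable. All-constant slices
get zero offset with zero confidence rather than an error.

Foreshortening correction rescales the in-image vertical axis by
`1/sin(tilt)` with linear interpolation, guarded by a state flag. The
compression axis convention is fixed jointly in the simulator and the
corrector, so round-trip tests are convention-independent.

Segmentation maps intensity bands to labels with fixed cuts (midpoints of
the default gray levels) or multi-level Otsu thresholding (a dynamic
programme over the 256-bin histogram; 5 classes by default). Two artifacts
of the imaging model get dedicated treatment:

* *Interpolation blend.* The foreshortening round trip blends intensities
  along the vertical axis, and a blend of two non-adjacent classes (e.g.
  envelope over background) transits through unrelated intermediate bands,
  biasing the recovered surface outward by a fraction of a voxel (about +5%
  on envelope surface area before the fix). Voxels in a steep vertical
  gradient are therefore re-assigned to whichever flanking class (sampled
  two rows away, outside the blend) has the nearer mean intensity, which
  puts the boundary at the 50% blend point - unbiased.
* *Thin-structure erosion.* The 3x3x3 median filter that suppresses noise
  speckle also erodes structures thinner than its window - precisely the
  nanopillar tips. Raw-threshold pillar evidence is restored after the
  median: everywhere outside the envelope, above an intensity margin inside
  it (so the envelope/pillar boundary shell is not inflated), and by
  adjacency-constrained growth along voxel-thin tip chains. The
  component-size cleanup then drops the speckles this re-admits.

Cleanup removes per-label connected components below a voxel-count floor
(orphans re-assigned to the local 6-neighborhood majority) and fills
enclosed background holes per label.

## Reconstruction

Isosurfaces are extracted at level 0.5 from one-voxel zero-padded binary
masks by marching tetrahedra over the Kuhn 6-tetrahedron decomposition.
The decomposition triangulates space consistently across cell boundaries
and has no ambiguous configurations, so every extracted mesh is watertight
and consistently outward-oriented *by construction* - the property the
divergence-theorem volume integral requires - and the tests assert it
structurally (every edge on exactly two faces) rather than assuming it.

Marching a raw binary mask places vertices at edge midpoints and
overestimates curved surface areas substantially (about +27% for a digital
sphere at 10 nm voxels with this tetrahedral decomposition). Two
anti-aliasing steps bring the closed-form errors down: a compact
edge-preserving prefilter on the indicator field (a sharpened binomial
kernel, (-2, 5, 10, 5, -2)/16 separably per axis) and ten Taubin smoothing
passes (lambda = 0.5, mu = -0.56; the slightly expansive mu compensates the
residual systematic shrink). With both, a 300 nm digital sphere at 10 nm
voxels reads +1.8% in area and -0.4% in volume, a 300 nm cube -2.9% / -0.7%,
and a 500 x 2000 nm spherocylinder +2.1% / +0.5% - all inside the 3% / 2%
oracle tolerances, with errors decreasing at finer resolution. The raw mesh
remains available (`antialias = FALSE`, `smooth_iterations = 0`), and is
what pillar meshes use: the prefilter suppresses voxel-thin structures
entirely (an isolated one-voxel column falls below the 0.5 level), which
would delete exactly the tip geometry the contact measurements need.

## Morphometry

* **Surface area** is the triangle-area sum; **volume** the signed
  tetrahedron sum, sign-normalized with an orientation warning, refused on
  non-watertight input with the open-edge count.
* **Interior depth field**: anisotropic Euclidean distance transform
  (Felzenszwalb's separable lower-envelope algorithm with physical
  spacings) of the cell interior after a morphological closing (60 nm ball,
  implemented with two distance transforms). The closing seals the narrow
  channel a penetrating pillar leaves through the envelope, so pillar
  voxels past the surface lie inside the field's support; 60 nm exceeds
  every preset's tip radius while staying far below cell radii, and
  deformation dimples (radius 200 nm at 60 nm depth, curvature radius
  about 135 nm) survive it.
* **Penetration depth** is the maximum interior depth over a pillar's
  voxels - the apex depth, matching arrow-to-tip measurements on cross
  sections - measured on the voxel grid rather than the mesh for
  robustness. Whether a pillar *has* penetrated is decided topologically:
  its voxels sit directly against cytosol (26-adjacency), i.e. it has
  pierced through the envelope shell. A tangent or deforming tip stays
  separated from the cytosol by the shell, so sub-voxel carving artifacts
  cannot masquerade as penetration.
* **Tip contact area** sums envelope faces whose centroid lies within
  `epsilon` of the pillar mesh (nearest-point distance, with bounding-box
  culling). `epsilon` defaults to 2.5x the largest voxel spacing: each of
  the two meshed surfaces is quantized by up to half a voxel and the
  corrupted reconstruction displaces surfaces by a further fraction of a
  voxel, and the patch must stay wide relative to that displacement for
  areas to be stable. Contact areas are measured on the *closed* interior
  surface: the apex-scale contact patch, not the walls of a penetration
  channel, which is also how the per-contact areas in the target tables are
  scaled. The contact zone is `tip` when the area-majority of nearest
  pillar points lies in the apex cap (top 10% of the pillar height along
  its principal axis), else `sidewall`; the patch centroid's height
  fraction on the cell (0 = bottom) supports the impedance rule.
* **Deformation depth** is the inward deviation of the actual envelope
  from a reference surface within a 120 nm patch around the contact
  centroid, evaluated at the 95th percentile of inward deviations rather
  than the strict maximum: a genuine dimple moves most of the patch,
  whereas voxel-scale carving at a touching tip moves a few vertices only.
  On phantoms the reference is the voxelized ideal cell; on real data a
  heavily Laplacian-smoothed envelope copy stands in (an approximation that
  flattens dimples but slightly shrinks everything - documented,
  overridable).
* **Field characterization** recovers density (count/area), heights
  (extent along each component's principal axis above the substrate plane)
  and tip diameters (equivalent-circle diameter of the cross section at
  95% height) from either spec tables or label volumes.

## Classification

The decision ladder is explicit, first match wins: (1) penetrated and the
cell's volume deficit at/above `tau_rupture` (default 0.20) - *rupture*;
(2) penetrated - *penetration*; (3) deformation depth at/above `tau_deform`
- *deformation*; (4) positive contact area on the sidewall at/above a
height fraction of 0.25 with sub-threshold deformation - *impedance*; (5)
positive contact area - *none*; no contact, no record. Rupture is a
per-cell condition attached to its penetrating contacts: turgor loss
belongs to the cell, not to one pillar, so a scene cannot mix intended
`penetration` and `rupture` on the same cell - all its penetrating contacts
are rupture.

The source definitions of these classes are qualitative; the thresholds
here are declared conventions, exposed in configuration. `tau_deform`
defaults to one slice thickness (at least 15 nm): below measurement
resolution, nothing is called deformation. The reference volume for the
deficit is the phantom's known reference on synthetic data and a configured
expected volume per cell kind otherwise (defaults 0.35 um^3 coccus, 0.75
um^3 rod - approximations, flagged as such).

## Reports

`build_cell_report()` aggregates one cell's contact records into the
standard row: envelope surface area, cell volume, counts and percentages of
penetrating / deforming / impeding structures, class-wise mean depths,
total contacts, total tip contact area, and the contact percentage of the
envelope area. Machine fields are raw floats; the formatted view truncates
percentages and depth means to two decimals and marks depth means averaged
over several contacts with `*`, while prose-style integer percentages
round - published tables mix both conventions, so both are covered by
tests. The invariants (counts conserve, each percentage is exactly
100 x count / total, contact percentage is exactly 100 x area / SA) are
property-tested on randomized inputs.

## Study conditions, problem sizes, and what passing tests show

Phantom scenes use 15 nm in-plane sampling (12 nm for the finest-tipped
preset, whose 13.5 nm tip radius must span a voxel), the organism-specific
slice thicknesses, and the corruption level the round-trip suite targets
(stage tilt 52 degrees, drift steps of 2 px, noise sd 10, texture sd 5).
The truth-recovery suite runs twenty seeded scenes spanning all four
presets and all five interaction classes; depths must recover the realized
ground truth within max(voxel, slice thickness), per-cell total tip contact
areas within 15%, the intended-vs-assigned confusion matrix must be the
identity, and contact counts exact. Individual per-contact areas are
noisier than the per-cell totals (a tangent contact patch spans few mesh
faces, so a half-voxel surface displacement moves its area by tens of
percent); the total - the quantity the per-cell report tabulates - is the
stable and asserted one.

The phantom emulates geometry, acquisition distortion and intensity
statistics. It does not emulate charging, curtaining-correlated shading,
platinum caps, membrane wrinkling or partial-volume chemistry of stained
specimens; passing the suite therefore demonstrates the pipeline's
geometric and statistical correctness under the modeled physics, not
segmentation robustness on arbitrary real material.

## Numerical choices and degenerate inputs

Registration confidence is the normalized correlation peak; all-constant
slices short-circuit to zero offset. Multi-Otsu on an image with fewer
distinct levels than classes is a thresholding-failure error. Empty label
selections are errors for meshing (`empty object`) but an empty pillar map
or an empty report is a valid result. Double foreshortening correction is a
state error. The voxel budget guard (25M voxels) aborts scene composition
before memory does. All randomness is seeded and every (params, seed) pair
reproduces scenes, stacks and reports bit for bit.

## Known limitations

Integer-pixel alignment leaves up to half a pixel of jitter that smoothing
must absorb; tips much finer than a voxel remain at the mercy of the grid
even with apex-chain voxelization; impedance tangency is inherently
marginal at voxel resolution, so impeding contact areas are order-of-
magnitude quantities; and the smoothed-envelope deformation reference on
non-phantom data underestimates broad shallow dimples. The cleanup's
hole-filling assumes enclosed cavities belong to the enclosing label, which
is correct for cells but would fill a genuinely hollow object.
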