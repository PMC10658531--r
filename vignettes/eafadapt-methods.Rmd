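---
title: "Methods: personalized fistula-adapter design and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized fistula-adapter design and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eafadapt)
```

# The clinical problem

An enteroatmospheric fistula (EAF) opens the intestinal tract directly onto
the granulating surface of an open abdomen. Negative pressure wound therapy
(NPWT) cannot be maintained while effluent leaks into the sponge, so the
fistula must be isolated above the wound surface — a "floating stoma". A
personalized ring adapter achieves this: its inner hole reproduces the
fistula outline, its lower face rests on the wound bed around the orifice,
and its flanged upper brim carries the sealing film.

This vignette documents the geometric model, the parameter conventions, the
synthetic validation phantom and the statistical conventions implemented by
`eafadapt`, and the reasoning behind each numerical choice.

# Scan ingestion and quality control

Structured-light scanners deliver pre-registered point clouds in millimetres
(XYZ text or PLY; meshes may be supplied directly as STL). The workflow
applies a hard quality gate before any modelling: a cloud with fewer than
**400,000 points** triggers a re-scan request; a second scan is concatenated
(registration is the scanner software's responsibility) and the merged cloud
is re-gated. The threshold reflects the capture density needed for
sub-millimetre wound morphometry at typical abdominal patch sizes
(~160 × 120 mm: 400,000 points ≈ 21 points/mm²).

# 2.5-D surface reconstruction

The wound patch is a height field over its best-fit plane to good
approximation, so reconstruction is deliberately 2.5-D:

1. PCA/SVD best-fit plane; normal oriented by an `up` hint (default `+z`,
   the outward direction of a supine scan).
2. Regular grid binning at `grid_pitch` (default 1 mm): one vertex per
   occupied cell at the cell centre, height = mean height of the cell's
   points. Averaging ~20 points per cell attenuates sensor noise by ~4.5×.
3. Interior dropout holes are filled by iterative 4-neighbour averaging,
   restricted to cells that have occupied cells in all four axis directions;
   this fills specular dropouts without growing the patch past its footprint.
4. Two triangles per fully occupied 2 × 2 block, oriented along the normal.

If fewer than 50 % of the bounding-rectangle cells are occupied the cloud is
declared too sparse for the pitch and the user is told to increase it —
silently interpolating a mostly-empty grid would fabricate anatomy.

# Morphometry

The clinician supplies a closed **wound-rim lasso** and one **fistula lasso**
per orifice (ordered 3-D polylines). Measurements are frame-based and hence
invariant under rigid motion of the scan:

- **Length/width**: extents of the rim loop along its two principal axes
  (length ≥ width; `swap_axes` available because the principal frame cannot
  know the anatomical longitudinal direction).
- **Depth**: distance from the rim plane down to the robust wound-bed level,
  the 5th percentile of in-rim vertex heights — robust to isolated noise
  spikes while tracking the deepest granulating region.
- **Orifice height** per fistula: the stoma plateau level (95th percentile
  of the selected region's vertex heights) minus the bed level.

Region selection keeps the faces whose centroids project inside the lasso on
its best-fit plane; if the selection splits, the largest edge-connected
component is kept with a warning, and its boundary loop is traced from the
directed edges whose reverse is absent.

# Parametric adapter design

The design frame sits on the fistula region's boundary plane (origin at the
boundary centroid, z outward). The fistula contour is the region boundary
projected into that plane, lightly smoothed (5-point circular moving
average) to soften grid staircase artefacts, and resampled to uniform arc
length (256 vertices).

Three sketches define the device (all offsets are round-join Minkowski
offsets computed with `polyclip`):

| sketch | height | radial offset | default | rationale |
|--------|--------|---------------|---------|-----------|
| bottom | 0      | `bottom_offset` | 5 mm  | small footprint: the NPWT sponge should contact as much wound bed as possible |
| middle | `f·h`  | `middle_offset` | = bottom | narrow body flaring to the brim (conical seal morphology) |
| top    | `h`    | `top_offset` (+ eccentricity) | 15 mm, ≤ 20 mm | the brim carries the sealing film; eccentricity steers it away from the adipose wall |

Device height `h` is clinically 10–20 mm (a warning is issued outside).
The middle-sketch fraction `f` follows a height rule: `f = 0.25` at
`h = 10 mm` falling linearly to `f = 0.15` at `h = 20 mm` (clamped) — lower
devices need their waist proportionally higher to keep the flare printable.
With `height = "auto"` the workflow uses 10 × wound depth (cm), clamped to
10–20 mm; with `top_offset = "auto"` it uses the lateral clearance between
fistula contour and wound rim minus a 5 mm margin (capped at 20 mm). These
auto rules are this package's proposal for sensible defaults, not a clinical
prescription.

## Hole subtraction as analytic ring assembly

The through-hole is the straight extrusion of the fistula contour (offset by
an optional 0–1 mm clearance). Because every sketch must *strictly contain*
the hole contour (checked, with the violating margin reported as a
`design_infeasible` error), the Boolean subtraction has a closed-form mesh:
outer loft wall + flipped inner prism wall + two annular cap bands. This
avoids general mesh Booleans entirely and guarantees, by construction:

- watertightness and Euler characteristic `V − E + F = 0` (a torus-like ring);
- the exact identity `volume(adapter) = volume(loft) − area(hole) × h`,
  which the test suite verifies to machine precision across randomized
  specifications and cross-checks against an independent 0.25 mm
  ray-casting voxelization oracle.

Ring correspondence between sketches uses uniform arc length plus the
twist-minimising cyclic shift, so the loft never self-intersects for the
star-shaped contours that fistula orifices present.

## Fit check

The adapter is posed with its hole axis along the frame z-axis. The bottom
annulus is sampled at three radial stations and compared against the local
wound surface height (hash-grid neighbourhood mean): the report gives the
maximum penetration (0 in the workflow's resting pose, which lifts the
device onto its highest contact point), whether the fistula contour passes
through the hole (with 0.05 mm boundary slack against resampling round-off),
and the minimum brim-to-rim clearance.

# The synthetic phantom

No patient scans can be distributed, so validation uses an analytic phantom:
a flat skin plane, an elliptical crater with a flat floor (55 % of the
elliptical radius) and a cosine taper to the rim, and plateau-topped stoma
bumps that must sit on the flat floor so their truth height is unambiguous.
Sampling emulates a structured-light scan: uniform xy sampling, Gaussian
displacement **along the local surface normal** (σ default 0.2 mm, the
middle of the 0.1–0.3 mm white-light scanner range), optional dropout, and
a Poisson-distributed realised count. Everything is deterministic given the
seed, and the generator never touches the caller's RNG stream.

The phantom emulates capture geometry and sensor noise. It does **not**
emulate tissue deformation between scans, specular dropout patterns,
registration error between merged scans, or effluent on the wound surface.

Recovery performance under the default study conditions (120,000-point
clouds, 1 mm grid): median absolute errors at σ = 0.2 mm are ~0.08 mm
(depth) and ~0.12 mm (orifice height), zero for rim-defined length/width,
with total error monotone in σ over {0, 0.1, 0.2, 0.3} mm.

# Outcome statistics conventions

The packaged case-series tables (16 devices, 8 patients, MD5-checksummed)
reproduce every published aggregate only under the conventions of mainstream
clinical statistics software, which therefore are the package defaults:

- **Quantiles**: the weighted-average estimator at position `(n+1)p`
  (`quantile type 6`); verified as the only standard rule consistent with
  the published interquartile ranges.
- **Wilcoxon signed-rank**: zero differences dropped, absolute differences
  midranked, tie-corrected variance
  `n(n+1)(2n+1)/24 − Σ(t³−t)/48`, two-tailed normal p **without** continuity
  correction. An exact 2ⁿ-enumeration mode serves as the small-sample oracle
  (the asymptotic p lies within ±0.01 of it on all packaged variables).
- **t tests**: paired on differences; two-sample pooled-variance by default
  (Welch available).
- **Normality gate**: Shapiro–Wilk for 3 ≤ n < 50 routes the display
  between mean ± sd and median (IQR).
- **Rounding**: comparisons against published values use round-half-up at
  the published decimal places, since banker's rounding (R's `round`)
  disagrees on exact .5 ties (e.g. 23.625 → 23.63, not 23.62).
- **Missing data**: pairwise exclusion with per-statistic n (one patient's
  change count is missing).

Three published aggregates are intentionally *not* reproduced and are
reported as known discrepancies: a dispersion printed as the variance
instead of the sd, a therapy-duration mean that matches only under an
unstated single-patient exclusion, and aggregate device dimensions that are
not the column means.

# Problem sizes and runtime

Typical sizes on one CPU core: phantom generation at 450,000 points ≈ 2 s;
reconstruction of a 160 × 120 mm patch at 1 mm pitch (~19,000 vertices)
≈ 2 s; adapter generation (256-vertex rings, ~2,000 triangles) < 0.5 s;
the full workflow ≈ 5 s. The statistics surface is trivially fast.

# Limitations

- 2.5-D reconstruction cannot represent undercuts; supply real meshes via
  `read_stl()` when the scanner's own reconstruction is better.
- The ring assembly requires the hole to be a straight extrusion strictly
  inside every cross-section — by design, since that is the device's
  geometry; arbitrary cavities are out of scope.
- Offsets assume star-shaped-ish simple contours; wildly non-convex fistula
  outlines may make large offsets merge lobes (handled by keeping the
  largest offset component, with the area change checked).
- The statistics module implements the conventions of the packaged case
  series, not a general clinical-trials toolbox.
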