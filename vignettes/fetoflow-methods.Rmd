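---
title: "Wall shear in the fetal mouse great arteries: models and methods"
author: "fetoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall shear in the fetal mouse great arteries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetoflow)
```

## The problem

Between embryonic day 14.5 (E14.5) and near-term (E18.5), the great
arteries of the fetal mouse roughly triple their lumen cross-sectional
area while peak blood velocities more than double. The question this
package is built around is what that co-growth does to the hemodynamic
shear environment of the vessel wall: wall shear stress
$\tau = \mu \, \partial V_t/\partial n$ and wall shear rate
$\gamma = \tau/\mu$, the quantities endothelial mechanosensors are
thought to read. If flow scales with the cube of vessel radius across the
tree (Murray's law), Poiseuille mechanics give
$\tau = 4 \mu Q / (\pi R^3)$, which is *independent of vessel size* — a
candidate homeostatic set-point for growth regulation.

`fetoflow` implements the full analysis chain as testable code:
synthetic episcopic-image-like stacks and Doppler-like velocity records
for a parametric great-artery tree; speckle filtering, lumen
segmentation, surface extraction and centerline morphometry; a
hematocrit-dependent blood-property model and Murray's-law boundary
conditions; steady low-Reynolds flow solvers; and wall-shear, helicity
and trend post-processing. Everything runs from seeds — no downloads.

## Physiological inputs and their defaults

| Quantity | Default | Basis |
|---|---|---|
| Heart rate | 216 → 286 bpm over E14.5–E18.5, linear | staged fetal-mouse UBM values |
| Ejection-duration ratio | 0.44 → 0.38, linear | same |
| Hematocrit | 0.20 at E10.5 → 0.438 at term (E19.5), linear | fetal hematocrit schedules |
| Kinematic viscosity | $\nu = A e^{B\,\mathrm{Hct}}$, calibrated to 1.87 cSt at E11.5 and 2.53 cSt at E18.5 | low-shear fetal hemorheology |
| Blood density | 1.06 g/cm³ | whole blood |
| DAo diameter | 0.573 mm near term; 55 % of that at E14.5, linear | near-term imaging anchor |
| DAo peak velocity | $V(t) = 1.25t^2 - 21.25t + 105.3125$ mm/s | see below |

The viscosity law's two constants are fixed in closed form by the two
printed endpoint viscosities under the linear hematocrit schedule; with
that calibration the choice of "term" (E19.0 vs E19.5) does not move the
endpoints. The exponential form is the standard low-shear dependence of
whole-blood viscosity on hematocrit.

The default velocity–age curve is a second-order polynomial (the form
used to set flow boundary conditions from staged Doppler measurements).
Its printed coefficients are not recoverable from the source text, so the
package *re-fits* the quadratic from (synthetic or user) Doppler records;
the default generating coefficients were chosen once to pass through
60 mm/s at E14.5, 95 mm/s at E16.5 and 140 mm/s at E18.5 — magnitudes
typical of high-frequency-ultrasound peak velocities in the fetal mouse
descending aorta. Users replicating a specific published fit can pass its
coefficients to `velocityAgeModel()` directly.

## The synthetic-data generator

`generateVesselTree()` builds a parametric swept-ellipse tube tree with
the anatomy of the fetal great arteries: ascending aorta, arch with
innominate, left common carotid and left subclavian branches, descending
aorta, pulmonary trunk with left/right pulmonary arteries, and the ductus
arteriosus inserting into the descending aorta. Stage dependence enters
through (a) the global dimension scale, (b) the ductus insertion angle,
which moves from near-perpendicular (100°) at E14.5 toward a parallel
merge (150°, with 180° = parallel) near term, realized as a sustained
straight terminal approach course rather than only an endpoint tangent,
and (c) cross-section ellipticity, which dips to 0.70 proximal to each
branch ostium with the elongation axis oriented toward the branch — the
geometric signature of energy-efficient flow division. Per-subject
anatomical variation is a lognormal radius jitter (CV 3 % by default;
8 % in the validation analog, where it plays the role of between-animal
spread). The descending-aorta diameter is never jittered: it is the
anchored reference dimension.

`rasterizeStack()` renders the tree on a voxel grid with lumen/tissue
intensity classes and multiplicative lognormal speckle (mean exactly 1,
so intensities are unbiased), retaining the analytic mask as ground
truth. `generateDoppler()` draws replicated peak-velocity records around
the noiseless curve, again with mean-1 lognormal noise, and keeps the
true curve for recovery tests. Every generator is a pure function of
(parameters, seed).

What the generator does *not* emulate: B-mode speckle physics, transducer
geometry, cardiac-phase gating, wall motion (the real vessels distend
~13 % over the cycle), chamber anatomy, or real biological shape
variation beyond radius jitter and the imposed stage trends. Tests that
pass on these phantoms demonstrate that the *pipeline* recovers what the
generator put in at realistic noise levels — not that it would segment
real episcopic data without parameter adjustment.

## Image processing and morphometry

Filtering is classic Perona–Malik diffusion on the 6-neighborhood with
exponential conductance and zero-flux borders (step ≤ 1/6 for
stability); it preserves the intensity range and conserves total
intensity. Segmentation is a global Otsu threshold with a histogram
valley check (a threshold that does not sit in a valley between two
modes is rejected as single-mode rather than returning an empty mask),
morphological closing, and largest-6-connected-component selection.
These parameter-free choices stand in for the unstated settings of the
original interactive tools.

Surfaces come from marching tetrahedra (Kuhn 6-tet cube decomposition,
translation-invariant face diagonals, hence watertight by construction)
at the 0.5 level of a lightly Gaussian-smoothed occupancy field; the
smoothing recovers sub-voxel surface positions for smooth shapes. On a
sphere sampled at 20 voxels per radius the area is recovered to ~0.1 %
and the volume to ~1 %. Branch clipping removes the surface past an
ostial plane within the branch cylinder and caps each boundary loop with
a centroid fan, traversing each boundary edge opposite to its kept face
so orientation stays consistent.

Centerlines follow the interior distance-transform ridge: an exact
Euclidean distance transform (separable lower-envelope passes), then a
shortest path on the 26-connected voxel graph with weights
$\propto (\mathrm{d}_{max}/\mathrm{d})^4$ pulling the path onto the
maximal-inscribed-sphere centers, then Laplacian smoothing and
resampling. Cross-sections are measured on planes orthogonal to
*radius-scale* tangents (symmetric differences over ± half a local
radius — voxel-scale wobble must not tilt section planes): area by
in-plane sampling of the smoothed occupancy field, Feret diameters as
directional widths of the sub-pixel 0.5-crossing boundary, aspect ratio
$d_{min}/d_{max}$, and the elongation axis as the principal axis of the
region. Sections whose lumen region is truncated by the sampling window
or grid are flagged, not dropped.

Insertion angles are measured between chord directions taken at a
standoff of 0.5–1.6 local radii away from the junction on each vessel,
because inside the junction the merged lumen bends any centerline path.
With this operator the generator's imposed ductus angle trend is
recovered to better than 1° from ground-truth centerlines. From
voxel-path centerlines the trend is recovered monotonically but
attenuated at late stages: a near-parallel ductus hugs the descending
aorta and the two lumens fuse over a length $\sim (r_1+r_2)/\sin(180° -
\theta)$, inside which no centerline-based operator can separate the
vessels. This is a genuine geometric limitation, not an implementation
artifact.

Profile alignment normalizes each subject's arclength to [0, 1] and
warps it piecewise-linearly so that named branch-ostium landmarks land on
the cross-subject mean positions, enabling stage-wise averaging of area,
aspect-ratio and shear profiles.

## Boundary conditions and flow solution

Volumetric flow is set from the descending-aorta peak velocity assuming
a parabolic profile ($Q = V \pi R^2 / 2$); outlet fractions follow
Murray's law $f_i = r_i^3 / \sum_j r_j^3$; outlet peak velocities are
back-computed from parabolic profiles; and the aortic and pulmonary
roots receive equal plug velocities sized so inflow balances outflow.
Only the peak-systole instant is modelled (steady peak-flow solves), and
walls are rigid, impermeable and no-slip.

Two solution paths cover the viscous-dominated regime:

* **Reduced-order network** (`solvePoiseuilleNetwork()`,
  `networkStations()`): every segment carries its Murray-assigned flow;
  Poiseuille relations give $\Delta p = 8\mu L Q/(\pi R^4)$,
  $\tau = 4\mu Q/(\pi R^3)$, $V_{max} = 2Q/(\pi R^2)$, with exact
  junction mass balance. At the Reynolds numbers of these vessels
  (< 30) this is the workhorse for whole-tree stage sweeps.
* **Structured tube-grid solvers** (`solveSteady3D()`): straight tubes
  are solved as developing axisymmetric flow on a staggered
  finite-volume grid (sparse-direct Stokes operator plus Picard
  convection; outlet-face pressure pins the level); curved tubes as
  fully developed Dean flow via a coupled vorticity–streamfunction
  system on a polar cross-section grid (Thom wall vorticity, secondary
  advection of the axial momentum included, secondary-vorticity
  advection neglected — the low-Dean Stokes balance). Both return full
  3D velocity/pressure/vorticity fields on the mesh nodes. The scheme
  is held to closed-form gates rather than prescribed: exit profiles
  within 1 % of Poiseuille, wall shear within 3 % of
  $4\mu Q/(\pi R^3)$, mass conservation to round-off, observed
  convergence order ≥ 1 between refinement levels, and Stokes-limit
  linearity within 1 %.

A general unstructured branched 3D solve (the role of commercial codes
in the original workflow) is out of desk scale here; junction-scale 3D
shear patterns are therefore not produced, and the branch-related
elevation of wall shear distal to ostia enters only through the
geometry (ellipticity dips) and the curved-tube physics.

## Post-processing

Wall shear rate is the one-sided second-order normal gradient of
tangential velocity at the wall on the solver's native grid;
$\tau = \mu\gamma$ holds identically. Unwrapped maps bin wall samples
over (arclength from the root) × (azimuth), mask elliptical holes at
branch-ostium landmarks, and record which anatomical direction azimuth 0
faces; azimuth bins carry a tolerance so samples computed from radians
land in the bin whose edge they nominally sit on. Centerline
hemodynamics evaluate $Re = V_c\,a/\nu$ and $\alpha = a\sqrt{\omega/\nu}$
per station, with $a$ the station radius (the average of the maximum and
minimum cross-sectional radius) and $\omega$ the heart-rate angular
frequency. Normalized helicity $H_n = (\mathbf{V}\cdot\mathbf{w}) /
(|\mathbf{V}||\mathbf{w}|)$ is clamped to 0 where either magnitude is
below a $10^{-9}$ floor (the 0/0 case is otherwise undefined).

Trend statistics pool vessel-by-age rows across vessels and report
Pearson's correlation and the zero-slope regression p value per
(quantity, covariate) contrast; a constant covariate is reported as
undefined rather than silently dropped. The Mann–Whitney U test used in
the Murray validation analog is an exact full-permutation enumeration
for group sizes up to 10 (midranks under ties), falling back to the
tie-corrected normal approximation above that — group sizes in staged
fetal studies are 3–5, squarely in the exact range.

## The two sweep modes, and why both exist

`stageSweep()` has two velocity modes, fixed at design time:

* **empirical** (default): the quadratic velocity–age trend, refit from
  seeded noisy Doppler records. Under this mode vascular area and
  centerline velocity rise steeply with age while wall shear stress
  shows only a weak positive trend and is statistically independent of
  vessel size — the cross-sectional picture a staged experiment sees.
* **shear_preserving**: descending-aorta velocity scaled as
  $V(t) \propto R(t)/\nu(t)$ so that $\tau = 2\mu V/R$ is constant —
  Murray-consistent *growth*. Run longitudinally (the same synthetic
  subject grown across ages, `longitudinal = TRUE`), vessel-mean shear
  is constant to a few per mille while mean area more than triples.
  This is the homeostasis property stated at the level where it is
  literally true of the model; cross-sectional subject scatter
  (different anatomical jitter per age) adds irreducible per-vessel
  variation of order three times the radius CV and is deliberately kept
  out of this property check.

The Murray validation analog compares, per age and subject, branch
velocities predicted from each subject's own descending-aorta flow plus
Murray's law against that subject's "measured" velocities (the
Murray-consistent truth under measurement noise). Because measurement
repeatability (CV 4 %) is smaller than between-subject anatomical
spread (CV 8 %), each measurement ranks adjacent to its own prediction
and the exact rank test behaves as in the paired experimental design it
emulates.

## Problem sizes and numerical defaults

The shipped analyses use desk-scale resolutions chosen once: stage
sweeps run the reduced-order path on ~380 stations per stage (seconds);
straight-tube solves use 16 radial × 64 axial cells (≈ 2 s per solve);
curved-tube solves 20 radial shells × 32 azimuthal sectors; phantom
stacks 10–16 µm voxels on grids up to ~10⁶ voxels. Tolerances quoted
above are the test gates; solver iteration budgets and residuals are
recorded in every `FlowField`.

## Known limitations

* Steady peak-flow only; no pulsatile 3D solution, oscillatory shear
  metrics, or wall compliance.
* The 3D solver classes are straight and constant-curvature tubes;
  branched junction flow is reduced-order only.
* Near-parallel ductus insertion angles cannot be recovered from voxel
  centerlines inside the merged-lumen zone (see above).
* The synthetic stacks are phantoms: pipeline recovery on them bounds
  algorithmic error, not performance on real episcopic data.
* The Womersley numbers of the default configuration reach ~1.0 in the
  largest near-term vessels; the steady-flow approximation rests on the
  low Reynolds number rather than on $\alpha \ll 1$.

## A minimal end-to-end run

```{r example, eval = FALSE}
sw <- stageSweep(seed = 1)
sw$trend          # vessel x age means of tau, gamma, Vc, area, Re
sw$stats          # Pearson rho and zero-slope p per contrast
murrayValidationAnalog(seed = 1)   # rank-test p per age and branch vessel
```
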