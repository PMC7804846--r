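---
title: "Modelling urine flow in the hollowed prostatic urethra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling urine flow in the hollowed prostatic urethra: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After transurethral surgery for benign prostatic hyperplasia the prostatic
urethra (PU) is left as a hollowed cavity between the bladder neck (BN) and
the prostate apex.  Depending on the operation and the gland, the cavity can
be wide and bulging or narrow and tapering.  During voiding, urine driven by
intravesical pressure accelerates from the nearly stagnant bladder through
the BN, crosses the cavity, and jets into the narrow distal urethra.  When
the cavity is wide relative to its openings, the main stream detaches from
the side walls and a recirculation zone — a "vortex" — forms on each flank.
Vortices dissipate fluid energy, so their presence and size are candidate
hydrodynamic markers of how well a resection restored the lumen.

`catsflow` reproduces this modelling chain end to end in two dimensions:

1. **geometry** — parametric construction of an idealized mid-sagittal
   outline of the lower urinary tract for one case, and enumeration of a
   210-case parametric cohort;
2. **meshing** — deterministic triangulation with element-budget control;
3. **flow solver** — steady incompressible RANS (or laminar) finite-volume
   solution with pressure boundary conditions;
4. **post-processing** — outlet midpoint velocity (MV-EUO), streamfunction
   based vortex detection, vortex diameters (TD-V, LD-V), velocity profiles;
5. **cohort statistics** — group summaries, Mann-Whitney comparisons,
   TD-V ~ RPU regressions, and the minimum vortex ratios RPU-1 and RPU-2.

## Geometry

A case is defined by three surgical diameters (cm): LD-PU, the longitudinal
diameter of the PU (BN-plane midpoint to apex-plane midpoint); TD-BN, the
transverse diameter of the bladder neck; and TD-PU, the transverse diameter
of the PU.  Fixed anatomical constants: bladder width 10.0 cm (its lower
half is modelled), distal urethra 0.6 cm wide and 15.7 cm long.  The index
case is (3.8, 3.0, 4.2).

The diameter ratios are

* RPU-1 = TD-PU / TD-BN (dimensionless), and
* RPU-2 = RPU-1 / LD-PU with **LD-PU in millimetres**.

The millimetre convention is forced by the scale on which the published
cohort thresholds live (RPU-2 of order 0.02-0.04); with centimetres the
numbers would be ten times larger.

The outline is assembled from four parts, mirror-symmetric about the axis:

* **Bladder**: a "near-hemispheric" cap.  A true half-circle of radius
  5 cm cannot both span 10 cm at the equator and meet a 3 cm neck opening
  5 cm lower, so the wall is a half-ellipse with horizontal semi-axis
  5 cm and the vertical semi-axis chosen so the wall meets the BN opening
  exactly 5 cm below the inlet chord.  The total height of the model is
  then exactly `bladder_d/2 + LD-PU + RU length`.
* **PU walls**: when TD-PU > TD-BN, each wall is an elliptical arc — a
  near-spherical cavity truncated by the BN and apex planes — passing
  through both plane openings with maximal width exactly TD-PU.  When
  TD-PU <= TD-BN no truncated-sphere arc spans both openings, but the
  cavity is still "near-spherical": the wall is a circular arc of
  diameter TD-PU centred at the PU mid-height (where a transverse
  diameter would be measured on imaging), joined to the BN and apex
  openings by straight tangent segments.  The circle forms a belly that
  protrudes beyond the straight BN-to-apex taper whenever
  TD-PU > (TD-BN + 0.6 cm)/2; it is this residual belly that keeps
  recirculation alive at RPU-1 values below 1, and it shrinks smoothly
  to nothing as TD-PU approaches the trapezoid limit, where the wall
  degenerates to a straight (conic) taper.  A purely conic interpolant
  was tried first and rejected: its near-wall expansion is so gentle
  that the solved flow stays attached for every TD-PU < TD-BN, which
  contradicts the observed persistence of vortices well below
  RPU-1 = 1.
* **Bladder neck**: zero thickness — the bladder arc and the PU arc meet
  at a corner at x = ±TD-BN/2.
* **Distal urethra**: a 0.6 × 15.7 cm rectangle ending in the outlet.

The top chord is tagged `inlet`, the bottom segment `outlet`, everything
else `wall`.  Because both walls are single-valued functions of the axial
coordinate, the outline is simple by construction; the test-suite verifies
simplicity independently with a segment-intersection scan.

## Meshing

No triangulation library ships with the target environment, so the package
meshes the domain itself, exploiting the single-valued walls: node rows
span the local width, and each strip between consecutive rows is
triangulated by an x-ordered merge.  The sizing policy is

* isotropic target size `h0` in the PU and bladder, with the bladder
  coarsened up to 2.5 `h0` toward the inlet (nothing happens in the
  reservoir interior),
* the axial step shrunk where the wall is steep (near the apex and the
  neck) so wall segments stay locally isotropic,
* the distal channel resolved by at least 8 cells across its 0.6 cm
  width, with cells stretched axially threefold (the flow there is nearly
  unidirectional).

A local post-pass (damped Laplacian smoothing plus Lawson edge flips,
applied only around low-quality elements; boundary nodes and edges are
never touched) lifts the steep-wall transition triangles above the 15
degree minimum-angle floor.  Element budgets are met within a few percent
by a secant iteration on `h0`.  The generator is fully deterministic; the
`seed` argument exists so run metadata can echo a complete configuration.

## Flow solver

Cell-centred finite-volume discretization on triangles; SIMPLEC
pressure-velocity coupling with Rhie-Chow flux interpolation to suppress
pressure checkerboarding; least-squares gradients; second-order upwind
convection via deferred correction with a gradient limiter — plain
Barth-Jespersen for turbulent solves (robust against the jet's limit
cycling) and Venkatakrishnan's smooth form for laminar ones, where
Barth-Jespersen's first-order clipping of smooth extrema would blunt the
profile peaks the validation suite measures; linear (second order)
pressure interpolation.  Inner solves are approximate, as is
standard inside SIMPLE-family iterations: symmetric Gauss-Seidel sweeps
for transported scalars and a DIC-preconditioned conjugate-gradient solve
for the pressure correction.

Boundary conditions: static gauge pressure 4958.8 Pa at the inlet (the
estimated mid-voiding intravesical pressure; the intra-abdominal reference
1961.3 Pa is carried as documentation), 0 Pa at the outlet, no-slip walls.
Inflow enters normal to the inlet with the momentum its mass flux carries;
local outflow through the inlet is treated implicitly upwind.  Gravity is
neglected: posture enters the model only through the geometry.

Turbulence: RNG k-epsilon by default (Cmu = 0.0845, C1 = 1.42, C2 = 1.68,
sigma_k = sigma_eps = 0.7194, eta0 = 4.38, beta = 0.012 — the standard
literature constants) with equilibrium wall functions, matching the
no-prism-layer meshing stance; the standard k-epsilon model and a laminar
mode are available for sensitivity runs.  Inlet k and epsilon derive from
5% turbulence intensity and the inlet hydraulic diameter (twice the slot
width).  The wall-function friction was validated against the Blasius
correlation in a straight turbulent channel (within ~2% at Re ≈ 9e4).

Numerical safeguards, chosen once during development on the index case and
then frozen:

* **Pseudo-transient continuation**: a local false-time-step term
  (`ptc_cfl = 3`, time scale `3 h / U_ref` with
  `U_ref = sqrt(2 dP / rho)`) damps the impulsive pressure-driven
  start-up; it multiplies the iteration increment and vanishes from the
  converged solution.
* **Under-relaxation** 0.5 (momentum), 0.3 (pressure correction), 0.3
  (turbulence).  Looser factors limit-cycle on this discretization.
* **Damping schedule**: meshes of 30k cells and above marginally resolve
  the jet shear layer at the distal-channel entrance and use the tighter
  time scale `ptc_cfl = 2`; if a solve still fails to converge, the batch
  drivers retry once with the alternate damping.  Both attempts are
  deterministic and the outcome is recorded per case.
* **Warm start**: a one-dimensional jet estimate (plug axial velocity
  carrying ~80% of the inviscid flux through the local width, a matching
  pressure column, mixing-length turbulence) replaces the inlet-pressure
  ramp when a domain is supplied.
* **Convergence**: scaled residuals below 1e-5 for momentum and 5e-5 for
  continuity, 1e-4 for turbulence.  The continuity norm is an L1 sum of
  cell imbalances scaled by the instantaneous inlet mass flux — stricter
  than a per-cell bound; 5e-5 on this scale keeps the global mass
  imbalance two orders of magnitude below the 0.1% acceptance bound.
  Non-converged solves are returned flagged, never silently; downstream
  observables refuse them.

## Observables

* **MV-EUO**: velocity magnitude linearly interpolated at the geometric
  midpoint of the outlet segment.
* **Streamfunction**: integrated exactly from the conservative face fluxes
  over the edge graph, so each wall is an iso-line up to the solver's mass
  imbalance and the inlet jump equals the volumetric flux.
* **Vortex detection**: a side recirculation zone is the closed region
  bounded by the separatrix streamline (psi at the adjoining wall level).
  Nodes beyond the wall level inside the PU band are grouped into
  connected components; each component's extents are measured through the
  interpolated separatrix crossings (sub-cell accuracy, which is what
  makes TD-V grid-convergent); regions narrower than two local cell
  diameters are discarded as noise.  TD-V and LD-V are the axis-aligned
  extents, averaged over the sides present.  The sign-reversal velocity
  profile across the PU is available as an independent diagnostic
  (`velocity_profile`), not as the detector: pointwise sign tests fragment
  noisy regions.
* **Per-case record**: ids, diameters, ratios, MV-EUO, vortex flags and
  diameters, convergence bookkeeping.

## Cohort statistics

Medians and interquartile ranges use linear interpolation between order
statistics (type 7, the common statistics-package default; the convention
is not dictated by the study design).  The vortex vs non-vortex MV-EUO
comparison is a two-sided Mann-Whitney rank test: exact enumeration with
midranks when the smaller sample has at most 8 observations, otherwise the
tie-corrected normal approximation without continuity correction (the
convention of the commercial statistics package the original analysis
used).  TD-V is regressed on RPU-1 and RPU-2 by ordinary least squares per
LD-PU group and overall.  Cohort thresholds are the minimum RPU-1 and
RPU-2 among vortex-positive cases, reported with the largest non-vortex
ratios for context.  Non-converged cases are excluded from statistics but
always counted and reported.

## Problem sizes

The index-case analyses run at the four study budgets (13k, 18k, 25k, 35k
elements); the headline vortex diameters are read from the ~25k solution,
and grid independence is assessed against the 18k solution, with
non-converged budgets flagged and excluded exactly as the per-case records
report them.  The 210-case cohort sweep runs at 3000 elements per case
with first-order upwind convection and residual targets of 1e-4 (1e-3
turbulence): the package's desk-scale study profile (`cohort_numerics()`).
First order is used because at these budgets the limited second-order
scheme fails to converge on a substantial fraction of the geometries,
while spot checks at 5000 elements show both schemes agreeing on vortex
classification and closely on diameters wherever both converge.  At this
budget the PU holds roughly 20-30 cells across, a recirculation zone of
one centimetre spans 7-9 cells, and the two-cell noise floor of the
detector corresponds to about 0.25 cm — adequate for presence/absence and
TD-V trends, which is what the cohort statistics consume.

## What the synthetic cohort does and does not capture

The generator reproduces the study conditions exactly: idealized symmetric
2D geometry, rigid walls, steady driving pressure, Newtonian urine at
37 °C.  It does not emulate real anatomy: no urethral curvature (the
anterior bending angles are deliberately ignored), no wall compliance or
sphincter dynamics, no transient voiding waveform, and no
three-dimensional swirl.  Passing cohort-level tests therefore validates
the modelling chain, not clinical transferability.

## Known limitations

* Steady RANS of a marginally unsteady separated flow: at the finest
  budgets the jet shear layer at the channel entrance can sustain a small
  residual limit cycle; such solves are flagged non-converged and excluded
  rather than reported.
* The outlet velocity is sensitive to the distal-channel friction model.
  With the k-epsilon closures and wall functions the distal channel is
  fully turbulent and MV-EUO settles near 2.6-2.8 m/s; values at the
  inviscid bound (~3.1 m/s) require effectively laminar channel friction.
  The published velocities sit at that bound, which this implementation
  can only reach in its laminar mode — where a steady solution at these
  Reynolds numbers does not converge.  The discrepancy is reported
  honestly by the test-suite rather than absorbed into the friction model.
* Wall functions with no prism layer: near-wall resolution is deliberately
  coarse (y+ of order 30-60 in the distal channel), mirroring the study's
  meshing stance; wall shear is log-law modelled, not resolved.
* The vortex diameters are axis-aligned bounding-box extents of the
  separatrix region; the measurement protocol behind the published
  diameters is not documented, and other conventions (e.g. widest section
  of the closed contour) would differ at the few-percent level.
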