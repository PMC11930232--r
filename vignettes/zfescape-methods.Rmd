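---
title: "From silhouette movies to swimming energetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From silhouette movies to swimming energetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(zfescape)
```

## What the package computes

`zfescape` quantifies the mechanical energetics of the C-start escape swim
of a zebrafish eleutheroembryo (a hatched, pre-feeding larva, 3–5 days
post-fertilization). The pipeline has five stages:

1. **Movies.** High-speed silhouette movies of the escaping fish, either
   recorded or generated by the package's synthetic C-start generator.
2. **Procrustes isolation.** Each frame is segmented; translation and
   rotation are estimated (centroid + principal second-moment axis with a
   differential continuation) and subtracted, leaving pure body movement.
3. **Midline kinematics.** A 300-segment midline is skeletonized from every
   isolated frame; the signed turning angles give the midline-curvature
   amplitude indicator and the head–tail angle trace, from which the six
   bend/beat maxima (C-bend, counterbend, four fast-swim beats) and the
   kinematic descriptors are derived.
4. **Body reconstruction.** A reference 3D body is built from transverse
   cross-sections by entropic optimal-transport (Sinkhorn) barycenter
   interpolation, meshed with Lagrangian markers (300 axial × 180
   circumferential by default), scaled to the standard length of a live
   5 dpf larva (3.829 mm), and bent along the tracked midlines under the
   Euler–Bernoulli assumption (each transverse slice stays orthogonal to
   the midline).
5. **Flow simulation and energetics.** A penalized incompressible
   Navier–Stokes solver on a uniform MAC grid, two-way coupled to the
   rigid-body equations, produces the hydrodynamic loads, the instantaneous
   mechanical power `P = -∮ (T·n)·u_s dS`, total work `E = ∫P dt`,
   distance, cost of transport `CoT = E/d`, Reynolds number
   `Re = ρ V̄ L/μ`, and the vorticity and Q-criterion wake fields.

Two in-silico experiments mirror the viscosity study design: a *virtual*
sweep (one water-recorded movement simulated at 0.83–15 mPa·s) and a
*realistic* sweep (viscosity-adapted movements, each simulated at its own
viscosity), both summarized by ordinary least-squares regression with
Pearson correlation.

## The synthetic generator and what it does (not) emulate

The generator's defaults encode the study's acquisition and behaviour
conditions: 10,000 frames/s on a 512 × 420 px window covering
13.0 × 10.7 mm², and a three-stage escape — a C-bend (~11 ms, head–tail
angle rising to 110°), a counterbend (~10 ms, swinging to −80°), then four
fast-swimming beats. A "beat" is one unilateral tail flick (half an
oscillation cycle), so the default fast stage lasts
`n_fast_beats/(2 × beat_frequency)` = 4/(2×60 Hz) ≈ 33 ms, and the whole
sequence ~54 ms, matching the stage timings of a typical recorded escape.
The default bend amplitudes (110°, 80°, 35°) were chosen once to match
the amplitude scale of real escapes (near-reversal C-bend, regular
moderate fast-swim beats); in the reduced 2D solver they produce peak
center-of-mass speeds above 100 mm/s, while cumulative displacements stay
well below real 3D values (see the limitations section).

Bending is distributed along arclength as the smoothstep `3u² − 2u³`
(`u = s/L`): curvature concentrates mid-posteriorly and the envelope
saturates toward the tip, so the thin, optically sub-pixel fin-fold tip
carries essentially no head–tail angle and the silhouette-based tracker
can recover bend amplitudes. The fast stage superposes one body wavelength
travelling tailward; the transition from the counterbend posture into the
travelling wave is blended over the first half beat so the midline shape
is continuous in time (an abrupt phase switch would inject unbounded
deformation velocities into the solver). The real functional form of
larval midline waves is unknown to this package; the envelope is a
stand-in with the right stages, amplitudes and rates, not a measured
kinematic. Consequently, passing recovery tests demonstrate that the
pipeline measures what the generator encodes — not that the generator
reproduces any individual fish.

Rasterization sweeps the dorsal half-width profile along the midline, with
a one-pixel linear intensity ramp centred on the exact silhouette
boundary. That choice is deliberate: the mid-edge intensity contour then
coincides with the true outline and survives bilinear resampling without
bias, which is what makes sub-pixel Procrustes round trips meaningful. The
synthetic cross-section stack uses superellipse body sections plus a thin
median fin-fold blade, bilaterally symmetric, with a seeded random subset
of interior slices removed to emulate missing histology sections.

## Segmentation and Procrustes details

Segmentation thresholds *under the lower percentile* of pixel intensity
(default 5%) to detect the fish, then refines the boundary at the
midpoint of the foreground/background intensities: the percentile cut
necessarily sits just under the background level, i.e. at the outer edge
of the blur ramp, while the mid-edge contour tracks the true outline.
Largest-component selection and hole filling complete the mask.

The center of mass used for tracking is darkness-weighted (the linear
edge ramp makes darkness proportional to pixel coverage), giving
sub-pixel stability on a body whose area-to-perimeter ratio is small.
Rotation is the principal second-moment axis, continued differentially:
the axis is defined modulo 180°, and the representative within ±90° of
the previous frame's angle is kept — the closed-form equivalent of
rotating the silhouette by the previous angle and measuring the residual.
Center and angle traces are smoothed with a Savitzky–Golay filter
(window 11 frames, order 3 — the modelled tracking protocol names no specific
function, so both are configuration). The first and last half-window
frames carry the filter's startup transient; tests of per-frame identity
skip them, while the reconstruction round trip (which reuses the same
trace on both legs) is transient-free.

## Optimal-transport body reconstruction

Missing sections are filled by entropy-regularized Wasserstein
barycenters computed with the convolutional Sinkhorn scheme (iterative
Bregman projections with a separable Gaussian heat kernel). Defaults:
`ε = 1e-3 × (slice diagonal)²` in squared pixels, at most 2000
iterations, marginal L1 tolerance 1e-6, and binarization at 0.5 of the
density maximum. The iterations run in double precision with guarded
divisions rather than in log space; for the ε range used here the kernel
stays representable, and much smaller ε mainly needs more iterations.
The interpolated stack reproduces key slices exactly at their own
positions. During bending, slices are transported rigidly in-plane: the
Euler–Bernoulli statement fixes orientation only, and rigid transport is
the simplest consistent choice; the enclosed volume is monitored rather
than constrained.

## The flow solver

The solver integrates the penalized momentum equation
`∂u/∂t + (u·∇)u = −∇p/ρ + ν∇²u + χ_s λ (u_s − u)` with `∇·u = 0` on a
staggered (MAC) grid: explicit second-order upwind-biased advection,
explicit diffusion, implicit penalization
`u ← (u* + λΔt χ u_s)/(1 + λΔt χ)` (unconditionally stable in λ,
default λ = 10⁸ s⁻¹), and an incremental pressure projection solved
exactly by DCT (no-slip) or FFT (periodic) diagonalization of the
discrete Laplacian — the projected field is divergence-free to rounding.
Outer boundaries are homogeneous no-slip on a 12 × 12 mm domain centred
on the initial center of mass (the full-scale study setting fixes the domain
but not the outer boundary condition; periodic boxes are available for benchmarks).
χ_s is mollified over one grid cell, and thin sections keep at least two
grid points across their thickness, the same guard a full-scale 3D
configuration needs for the median fin fold.

Two-way coupling uses momentum projection: after each penalized step the
body's translation and angular velocity are set to the χ-weighted linear
and angular momentum of the velocity field, with levers measured about
the χ centroid. At ρ_s = ρ (a neutrally buoyant larva) the classical
explicit load-driven update is added-mass unstable; the projection form
is the standard remedy in the volume-penalization literature. The
prescribed deformation velocity additionally has its discrete χ-weighted
momentum removed on the solver grid each step, so penalization cannot
inject rigid momentum through discretization mismatches. The
stress-tensor surface integral over the Lagrangian markers remains the
load diagnostic (`hydrodynamic_loads()`), evaluated 1.5 cells outside the
penalized region, and `advance_rigid()` exposes the textbook explicit
update for the rigid-body equations.

Time stepping inside `simulate_escape()` is CFL-adaptive (advective CFL
0.4, diffusive limit 0.2 h²/ν) between output samples at the movie frame
interval.

### The planar body

The desk-scale solver is two-dimensional — the scale at which grid
convergence of this problem is usually assessed. The swimming body is the
midline plus a *depth-averaged* half-width: the dorsal silhouette
blended with 0.35 × the lateral height (body plus median fin fold).
A raw dorsal-view slice of the larva's tail is a few tens of micrometres
wide and produces almost no 2D thrust, whereas the real thrust surface is
the ~0.6 mm-tall fin fold; the effective width restores that surface to
the planar model. 2D quantities are per unit depth and are converted to
watts/joules with an effective depth of 0.6 mm (about the measured
maximum body height of a 5 dpf larva). These are modelling choices of the
reduced 2D setting: magnitudes are indicative, while the comparative
structure across viscosities (linearity, monotonicity, spike phasing) is
the quantitative product.

## Descriptors and conventions

* Six bend/beat maxima are local maxima of the rectified head–tail angle
  (prominence 10°, minimum separation 2 ms).
* The six-movement analysis window ends at the sixth maximum plus half a
  beat period (the endpoint convention is not fixed by the source
  description).
* Tail-beat frequency is the full-cycle rate, computed from the intervals
  between same-side (alternate) beat peaks; it equals the generator's
  `beat_frequency` and the dominant spectral frequency of the signed
  head–tail angle.
* Rotation amplitude is the average of local maxima of |α|; whether this
  descriptor should use absolute-value maxima or per-cycle extrema is
  ambiguous, and this reading is flagged as an interpretation.
* Power is smoothed with a 1 ms moving average (after Savitzky–Golay and
  spline re-interpolation); energies integrate the smoothed power by a
  Riemann sum, with a trapezoidal option.
* The instantaneous power is implemented as the traction-power surface
  integral `P = −∮ (T·n)·u_s dS`; the printed form of this quantity in
  the source description is typographically garbled, and this is the
  standard physical reading of a power "derived from the body boundary
  velocity and the hydrodynamic tensor".
* Image convention, stated once and used everywhere: pixel (row r, col c)
  maps to x = (c−1)·scale rightward, y = (nrow−r)·scale upward (0-based
  indices at pixel centers); angles are degrees, counterclockwise from
  +x; positive bend = leftward in the fish frame.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the paper-scale
*configuration arithmetic* exactly (Nx = 420 spacing, 10 kHz time base,
3.829 mm standard length, 300-segment midline, 300 × 180 markers) and the
*simulations* at a reduced scale chosen for a single desktop core:
tracking fixtures at 2 kHz on 360 × 300 px windows; Taylor–Green at 128²;
escape sweeps at 128² on the 12 mm domain with six (virtual) and four
(realistic) viscosities. The methods are identical at larger sizes; only
grid and movie lengths change.

## Known limitations

* Planar swims only; pitch and roll are assumed negligible, as in the
  modelled experimental setup (a shallow water column suppresses z excursions).
* No elastic or neuromechanical body feedback: deformation is prescribed
  from (synthetic or tracked) imaging; the solver computes only the
  rigid response and the flow.
* The 2D reduced model under-represents three-dimensional flow escape
  around the body; absolute powers and distances are per-depth estimates,
  not calibrated predictions.
* The Froude efficiency helper applies to prescribed harmonic test
  motions; no general useful-work decomposition is attempted for full
  C-starts, where thrust and recoil contributions are entangled.
* Metabolic (chemical) energy is out of scope; the power is mechanical
  work done on the fluid.
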