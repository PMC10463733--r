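---
title: "Quantifying left-atrial blood stasis from chamber wall motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-atrial blood stasis from chamber wall motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atrialstasis)
```

## The problem

Thrombi that cause cardioembolic stroke in atrial fibrillation (AF) form
predominantly in the left atrium (LA) and especially in its appendage
(LAA), and the suspected mechanism is blood stasis: blood that lingers has
time to clot. Stasis cannot be measured directly at clinically relevant
resolution, but it can be computed. If the motion of the endocardial wall
over the cardiac cycle is known, the incompressible flow it drives can be
simulated, and the *residence time* — the mean time the blood at a location
has spent inside the chamber — can be transported through that flow as a
passive scalar. Subjects whose atria empty poorly (low LA ejection
fraction, high ratio of atrial volume to ventricular stroke volume) wash
out slowly and accumulate residence time.

`atrialstasis` implements that full chain at desk scale: synthetic moving
chamber geometries stand in for segmented cardiac CT, a surface-based
non-rigid registration recovers wall motion from segmentation-like masks, a
moving-boundary flow solver driven purely by the wall motion computes the
velocity field, a monotone transport scheme advances the residence time,
and a statistics layer compares AF-like and control-like synthetic cohorts
the way a clinical study would (two-sample t-tests, univariate regression
with confidence bands).

## The synthetic chamber generator

The generator replaces patient imaging. A `chamber_spec()` fixes one
subject: maximum LA body volume and LA ejection fraction, LAA volume and
ejection fraction, LV end-diastolic/end-systolic volume, heart rate, and
body surface area (BSA, used only for indexing). `generate_chamber_series()`
builds closed chamber boundaries at 20 frames per cycle (one per 5% of the
RR interval), with identical vertex count and connectivity at every frame,
so point correspondence — the thing segmentation alone cannot give — holds
by construction, and the true wall motion is available as ground truth for
the tracker.

In the default planar (2D) mode the LA is a disc carrying a neck-plus-pouch
appendage, and the LV is a separate disc; `volume = area x depth` with a
default out-of-plane depth of 20 mm. The appendage neck tapers from 12 mm
at the body to 7 mm at the ostium, so the narrowest point — where the
appendage is split off for regional reporting — is well defined; the
ostium width is clamped automatically when a small drawn LAA could not
accommodate it. Boundary facets carry region labels: `la_body`, `laa`,
`mitral`, four `pv_inlet_k` arcs (pulmonary-vein inflows), and `aortic` on
the LV. A coarse 3D mode revolves the same cross-section into spherical
chambers; it supports the geometric descriptor layer, while tracking and
the flow solvers operate in the 2D desk mode.

Chamber radii at each frame are solved (analytically invertible area
formulas + root finding) so the enclosed areas match prescribed periodic
volume waveforms exactly; the polygonal discretization then recovers
volumes and ejection fractions to well within 1%. Clinical reports give
extreme volumes but not waveforms, so the waveform shapes are package
defaults built from half-cosine segments (C1 and periodic by
construction): LV ejection ends at 35% RR; LV filling is split 70/5/25%
of stroke volume between early filling, diastasis, and the atrial kick
starting at 85% RR; the LA fills during ventricular systole (reservoir
phase, maximum at 35% RR), empties passively, and contracts actively from
85% RR back to its minimum at the cycle start. Phase 0 is pinned to LV end
diastole. These timings represent normal sinus physiology; only the
extremes are subject-specific.

`cohort_spec()`/`generate_cohort()` draw per-subject parameters from
per-group normal distributions. The defaults emulate a small clinical
cohort: controls with indexed LA maximum volume 41 ± 7 ml/m², LA EF
0.53 ± 0.07, BSA 2.13 ± 0.28 m², heart rate 67 ± 7; an AF-like group with
66 ± 15 ml/m², 0.43 ± 0.09, 2.02 ± 0.17 m², 62 ± 8; LAA volumes
3.2 ± 1.3 vs 6 ± 2.7 ml/m² with EF 0.72 ± 0.07 vs 0.62 ± 0.12; LV size and
function comparable between groups (EDV 68 ± 18 vs 78 ± 11 ml/m², EF
0.69 ± 0.06 vs 0.67 ± 0.05). LV end-systolic volume is derived from the
drawn EDV and EF (the three are mutually redundant). Draws violating a
chamber invariant are rejected and redrawn, at most 100 times per subject.
Appendage shape is carried as a categorical label (`chicken_wing` with
probability 7/8 in controls and 16/21 in the AF-like group) and does not
alter the generated topology — the shape label exists so the subgroup
analysis has something to condition on, not because the generator encodes
a shape effect.

What the generator does *not* emulate: real pulmonary-vein anatomy (inlets
are boundary arcs, not vessels), appendage trabeculation (unresolvable
even in CT), beat-to-beat variability, and 3D secondary flows. Passing
tests therefore validate the numerics and the analysis chain, not
anatomical realism.

## Wall motion tracking

`register_nonrigid_icp()` deforms the phase-0 boundary to match another
phase's segmentation (a polygon, or a binary mask that is contoured first
by marching squares). Two stages:

1. a similarity (Procrustes) pre-alignment — iterated closest-point
   correspondences with a closed-form rotation/scale/translation fit —
   which recovers the rigid and bulk-scale part of the motion essentially
   exactly;
2. incremental non-rigid refinement: each iteration finds closest points
   on the target and solves `(I + (lambda + mu) L) step = residual - mu L d`
   per coordinate, where `L` is the graph Laplacian of the closed
   boundary. `lambda` (decreasing geometrically from 100 to 1 over the
   iterations, coarse to fine) smooths each update; `mu` (default 1) is a
   persistent roughness penalty on the accumulated field that suppresses
   tangential vertex sliding. Rigid translations lie in the null space of
   `L` and are never penalized.

Defaults: 50 iterations, convergence at 0.1 mm mean point-to-target
distance. Non-convergence warns and reports the residual rather than
failing silently; masks contoured at 0.5 mm voxels typically converge to
0.1–0.2 mm, limited by contour jaggedness. The deformed boundary is checked
for inversion (signed area) and self-intersection and errors out if either
occurs — detection, not repair. `track_series()` chains phases
(initializing each registration from the previous phase), and tracked
volume curves match the generator's ground truth to within 3% at 0.5 mm
voxels. `wall_velocity()` differentiates periodic cubic splines through
the 20 phases, so velocities are C1 and every vertex returns exactly to
its start after one cycle.

## Descriptors

`compute_descriptors()` extracts per-phase volumes by the divergence
theorem (shoelace area x depth in 2D, signed tetrahedra in 3D; inward
orientation and self-intersection are errors), splits the appendage at the
stored ostium plane with a capped cut (part volumes sum to the total
within 0.5%), and derives: extreme chamber volumes, ejection fractions
`100 (Vmax - Vmin)/Vmax`, LV stroke volume, peak mitral and aortic flow
rates (periodic-spline derivative of the LV volume curve, signed positive
in the physiologic direction), BSA-indexed volumes, and the **LA retention
ratio** `Vmax,LA / SV,LV` — how much blood the atrium holds relative to
how much passes per beat. `la_max_volume` in a `chamber_spec()`, and all LA
descriptors, refer to the LA body *excluding* the appendage, which is
specified and reported separately. End diastole/end systole are identified
as the phases of maximal/minimal LV volume. BSA is an input; no BSA
formula is computed. Ejection fractions and the retention ratio are
invariant to uniform geometric scaling.

## The flow solver

Blood is Newtonian (viscosity 3.5e-3 Pa s, density 1060 kg/m³) and the
flow laminar. The chamber cross-section is meshed with graded triangles
(boundary nodes fixed at the wall edge length; interior nodes relaxed by
truss forces over Delaunay triangulations); near-wall and maximum edge
lengths default to 0.25 mm and 2 mm as in fine-scale practice and are
multiplied by `desk_scale` (default 8) in the 2D desk mode, keeping
meshes in the hundreds-of-nodes range.

Each step of `advance_flow()` is a projection (fractional-step) scheme on
the moving mesh, in arbitrary Lagrangian–Eulerian (ALE) form:

* boundary node motion is interpolated from the tracked wall points by
  inverse distance weighting (5 nearest neighbours, power 2, exact on
  coincident points) and extended harmonically into the interior
  (factorized once per mesh topology);
* momentum: implicit viscous terms plus implicit convection linearized at
  the previous velocity relative to the mesh, with streamline
  (SUPG-type) diffusion `tau = h/(2|a|)` for stability at the high cell
  Peclet numbers of cardiac flow; no-slip walls take the wall velocity;
* pressure: a Poisson solve built from the discrete projection operator
  `G' M^-1 G` (gradient/lumped-mass), with the velocity correction masked
  at no-slip nodes and a small Laplacian stabilization (weight 0.05)
  suppressing the spurious pressure modes of the equal-order P1/P1 pair;
  pressure is fixed at opening nodes, zero-flux elsewhere;
* correction and re-imposition of the wall velocities.

Openings are *pressure boundaries*: pulmonary-vein inlets are always open,
the mitral orifice switches between an opening (while the LV fills,
derived from the sign of the LV volume-curve derivative, or an explicit
schedule) and a no-slip wall (binary valve; facet-level switching, no
geometry change). All openings default to 0 Pa gauge: the flow is driven
entirely by wall motion, and with pure pressure openings only pressure
*differences* matter for the flow split, so the common level is
irrelevant; per-region pressures are exposed in the configuration. The
straight inflow-extension pipes used in full 3D practice are not mirrored
at desk scale. The mesh topology is rebuilt every `remesh_interval_steps`
(default 50) with conservative field transfer: nodal fields by P1
interpolation (exact for representable fields), the cell-centred scalar by
exact overlap-area remapping (conserves the integral to the boundary
resampling sliver, ~0.1%, and preserves boundedness).

Verification: quiescent equilibrium is preserved exactly; a uniform stream
survives pure interior mesh motion to machine precision (free-stream
preservation); plane Poiseuille flow matches the analytic centreline
velocity within 1% at the test resolution; a uniformly contracting box
expels volume at `-dV/dt` within 0.5% at 0.35 mm walls (the residual
concentrates at the wall–opening corners and vanishes with refinement).

Accuracy and operating envelope at desk scale: with `desk_scale = 10` and
150 steps per cycle, the per-step global mass balance (boundary flux
relative to the moving wall vs the rate of area change) holds to a few
percent of the peak volume rate — with short spikes at the binary valve
switches — and the cycle-integrated closure is 1.5–2% of the peak chamber
volume, first order in the mesh size. Very fine desk meshes
(`desk_scale <= 6`) combined with small time steps excite an instability
of the lagged convection linearization; the shipped defaults stay in the
stable coarse regime, and the advective form of the scalar transport
(below) is insensitive to the residual divergence.

## Residence time

The residence time `Tres` obeys a transport equation with unit source:
its material derivative is 1 (blood ages one second per second), it is
advected with the flow, and it diffuses with the molecular diffusivity of
blood, 1.14e-11 m²/s. At that diffusivity the Peclet number is
astronomically large, so the discretization must get advection right and
may treat diffusion as a regularizing afterthought. `advance_residence()`
uses a cell-centred donor-cell upwind scheme in the *advective* ALE form
`dc/dt + (u - w) . grad c = 1` (with `w` the mesh velocity): every update
is a convex combination of the cell value and its inflow donors plus the
source, so the field stays non-negative and never exceeds the elapsed
scalar time — the discrete maximum principle — even where the projected
velocity field carries a small residual divergence. (The conservative
form trades exactly that robustness away, which is why it is not used:
`Tres` is an intensive age, not a conserved density.) Sub-cycling keeps
the scalar CFL below 0.9. Fresh blood enters with `Tres = 0`; outflow is
zero-gradient; walls are no-flux. The price of first-order upwinding is
numerical diffusion, measured on the plug-flow benchmark: the outlet value
of a steady plug flow through a channel is within ~1–2% of the analytic
`L/U` at the test resolution.

`run_residence()` follows the study protocol: 2 initialization cycles of
flow only, then the scalar from zero for 6 cycles (both configurable),
with per-cycle regional means logged as a convergence trace.
`regional_stasis()` reports volume-weighted mean residence times —
volume weighting is the physically consistent reading of an "average
residence time" — in the LA including the appendage, the LA without it,
and the LAA alone, divided by the RR interval to give cardiac cycles (CC).
Evaluation is at end systole (the phase of minimal LV volume, 35% RR in
the synthetic waveforms) of the *final* scalar cycle; the protocol
description does not pin down which cycle's end systole is meant, so the
phase is exposed in the configuration.

Behavioural checks at cohort level: appendage residence time exceeds the
atrial-body residence time within every subject (the pouch is the stasis
hot spot); increasing LA ejection fraction across otherwise comparable
subjects decreases atrial residence time; AF-like cohorts (larger atria,
lower EF, higher retention ratio) show higher mean atrial residence time
than control-like cohorts. In reduced desk runs (2 + 3 cycles, 4 + 4
subjects) the control-like atrial mean is ~0.6–0.7 CC and the AF-like
mean ~0.9–1.2 CC — the same ordering and similar magnitudes as full-scale
practice, though desk-scale 2D values are not calibrated against patient
data. One known divergence: between-group ordering of the *appendage*
residence time is not reproduced reliably at this scale, since the 2D
pouch exchanges volume with the body differently from a trabeculated 3D
appendage.

## Statistics layer

`two_sample_ttest()` defaults to the pooled-variance test (Welch by flag),
flags significance at 5%, and degrades gracefully for zero-variance
samples. `univariate_regression()` is OLS with R², the two-sided slope
p-value, a 95% confidence band evaluable at any predictor value, and a
leave-one-out leverage report that refits without each observation and
flags points whose removal flips significance — the robustness check that
matters when a single extreme subject drives an association.
`group_summary()` emits mean ± SD per group with t-test p-values;
`shape_subgroup_analysis()` summarizes residence times by appendage shape
within groups and only tests where both subgroups have at least two
members. No multiple-testing correction is applied: univariate analyses
are reported individually at the 5% level, matching common practice in
small clinical cohorts. Calibration is tested: the type-I error of the
pooled test is 5% ± 1% over 5000 null replicates, and OLS recovers known
slopes within 3 standard errors.

## Numerical choices, defaults, and problem sizes

* Geometry: mm; solver internals: SI; volumes: ml; stasis: cardiac cycles.
* `solver_config()` defaults carry the fine-scale settings (dt 5e-4 s,
  remesh every 50 steps, wall/max edges 0.25/2 mm, 2 init cycles, IDW
  5/power 2, 0 Pa openings); desk runs override via `desk_scale` and
  `steps_per_cycle`.
* Test-suite problem sizes: meshes of 100–2000 nodes, one- to five-cycle
  runs, a 4 + 4 subject end-to-end cohort with 2 + 3 cycles per subject —
  chosen so the whole suite verifies every oracle in minutes on one CPU.
* Determinism: the generator, mesher (quasi-random golden-ratio seeding,
  no RNG), solver and pipeline are deterministic given the spec; cohorts
  are reproducible from their seed.
* Degenerate inputs error loudly: open or inverted boundaries,
  self-intersections after registration, inverted cells after mesh
  motion, empty masks, empty split regions, constant predictors,
  single-member samples.

## Known limitations

2D desk mode is a model of the *mechanism*, not of any patient: absolute
residence times depend on dimensionality, resolution and cycle count and
should only be compared within a configuration. Tracking and flow are
2D-only (3D geometry supports the descriptor layer). The appendage
shape label carries no geometric consequence. The binary valve switch
injects short mass-balance spikes; the cycle-integrated closure error
(~2% at default desk resolution) bounds their effect. Inflow residence
time is assumed zero (fresh pulmonary blood), and recirculation re-entry
through the mitral orifice during filling is not modelled because the LV
is not part of the flow domain.
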