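---
title: "Modelling nested fluid cushioning of the fetal brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nested fluid cushioning of the fetal brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nestedfsi)
```

## The problem

A fetus is protected from maternal trauma by two nested fluid layers:
amniotic fluid between the uterine wall and the fetal body, and
cerebrospinal fluid (CSF) between the skull and the brain. During a maternal
tonic-clonic seizure the uterus undergoes violent roll-axis oscillation;
the question is how much of that mechanical loading reaches fetal brain
tissue, and how the two layers divide the work. `nestedfsi` implements a
desk-scale, two-dimensional model of this cascade: weakly compressible
smoothed particle hydrodynamics (SPH) fluids coupled by penalty contact to
explicit, lumped-mass, linear-triangle viscoelastic finite element solids,
driven by synthesized seizure kinematics, with the cushioning observables
the field uses — baseline-normalized landmark-to-surface separations at the
outer (fetus–uterus) and inner (brain–skull) level, brain stress scalars,
and protected-versus-unprotected attenuation percentages.

## Model components

### Geometry (synthetic anatomy)

No anatomical dimensions are published for this problem, so the package
builds a parametric stand-in that preserves the nested-layer topology:
concentric ellipses for the uterine wall (cavity 115 × 90 mm, wall 10 mm),
fetal body (95 × 70 mm), skull (42 × 38 mm outer, 5 mm thick) and brain
(31 × 27 mm), with a 20 mm amniotic gap and a 6 mm CSF gap at the axis
poles. The skull and brain cross-sections are deliberately round-ish: in the
transverse plane (the plane of roll rotation) the fetal head is nearly
circular, and strong ellipticity of the brain–skull pair would make the
measured gap spuriously sensitive to the small relative rotation between
them. The CSF gap of 6 mm is at the generous end of normal fetal
subarachnoid spacing; five particle layers fit across it at the default
1.2 mm spacing, which is the least resolution at which the thin-film
dynamics of the inner layer are usably smooth. All dimensions are
configurable (`nested_model_config()`) and are documented as placeholders.

Fluid regions are filled with regular lattices clipped to the gap with a
half-spacing wall offset (the usual SPH wall gap). Landmarks sit at fixed
parametric angles: the four outer distances at the long-axis poles
(frontal/occipital), the short-axis poles (placenta/lower back) of the fetal
surface, and the six inner distances at ±20°, ±160° and ±90° on the brain
surface, mirroring the frontal/occipital/hemisphere convention. For
concentric ellipses the axis-aligned baselines equal the semi-axis
differences, which makes them analytically checkable.

### Fluids

Both fluids are water-like (density 1000 kg/m³, viscosity ≈ 0.001 Pa·s).
The discretization is standard weakly compressible SPH: cubic spline kernel
with support 2h and h = 1.3 × spacing, continuity-equation density evolution
with Shepard reinitialization every 30 steps, symmetric pressure-gradient
momentum equation with Monaghan artificial viscosity (the only dissipative
term; no explicit laminar operator), and the linear equation of state
p = c0²(ρ − ρ0).

The numerical sound speeds are *not* physical. The amniotic domain uses
c0 = 10 m/s, ten times the peak wall speed (≈ 1 m/s), the usual
weak-compressibility sizing. The CSF uses c0 = 10 m/s as well — well above
the weak-compressibility minimum for its local speeds — because in a thin
2-D film the equation-of-state stiffness sets how much the brain–skull gap
must compress before the film transmits the skull's motion to the brain;
with a soft EOS the brain visibly lags. The CSF also uses a higher
artificial viscosity (α = 2 versus 1) representing the squeeze-film
dissipation of the thin layer. Both choices are per-domain parameters
(`sph_params()`, `simulation_config(sph_csf = ...)`).

### Solids

Solids follow the printed linear equation of motion M ü + C u̇ + K u =
F_ext + F_FSI with lumped mass, mass-proportional Rayleigh damping, and
small-strain linear kinematics (plane strain, unit thickness); corotational
large-deformation corrections are out of scope at this scale, which adds a
θ²-order spurious strain to the driven uterine wall but does not affect the
reported ratios. Viscoelasticity is a generalized Maxwell (Prony) model
applied to the deviatoric response only — the standard reading of a shear
relaxation modulus G(t) = G∞ + Σ G_k exp(−t/τ_k) — with a linear-elastic
bulk term. Each Maxwell mode advances by the exponential internal-variable
recurrence; tests verify it against the hereditary integral to within 1% at
dt = τ/100.

No quantitative fetal moduli exist (the source material lists them as
"reduced vs. adult" or "estimated"), so the defaults are explicit
placeholders:

| component  | G∞ (kPa) | G₁ (kPa) | τ₁ (s) | K (kPa) | ρ (kg/m³) |
|------------|---------:|---------:|-------:|--------:|----------:|
| uterus     | 10       | 15       | 0.1    | 150     | 1050      |
| fetal body | 8        | 8        | 0.1    | 100     | 1000      |
| skull      | 400      | 200      | 0.05   | 800     | 1500      |
| brain      | 30       | 30       | 0.05   | 200     | 1040      |

Two of these deserve justification. The **brain** is far stiffer than
physiological fetal brain tissue (which is of order 0.1–1 kPa). The
behaviour this model must reproduce — gap deviations of a few percent and
peak stresses of tens of kilopascals at small strain — implies an effective
brain modulus of order 10–100 kPa; a few-hundred-pascal brain deforms by
millimetres under the ~0.1–1 kPa CSF pressure fluctuations of this scenario
and the brain–skull separation observable dissolves into surface wobble.
The default is therefore an *effective* stiffness matched to the reported
behaviour, not a tissue measurement. The **skull**, conversely, cannot be
made stiff enough: a bone-like ring (E ≳ 100 MPa) forces an explicit time
step near 10⁻⁶ s, and any desk-scale-integrable modulus leaves a thin ring
orders of magnitude too flexible in bending (millimetre ovalization under
kilopascal loads). Since the real cranial vault is rigid relative to every
fluid-pressure scale in the model, the default treatment integrates the
skull as a rigid three-degree-of-freedom body driven by the total force and
torque from its two interfaces (the tied fetal-body ring and the CSF
contact). The viscoelastic finite element path for the skull remains fully
implemented and tested and can be selected with
`simulation_config(rigid_skull = FALSE)` for short runs.

The fetal body and skull share their interface discretization; the
coincident node pairs are tied (combined-mass update), i.e. the skull is
rigidly embedded in the fetal body, and the brain floats in the CSF with no
solid-solid connection.

### Coupling

Fluid-structure interaction is a penalty contact: a particle past a surface
feels F = kc δ n along the outward normal, with the exact opposite force
distributed to the penetrated segment's nodes by its linear interpolation
weights, so global force balance holds to round-off (asserted each step
under `debug = TRUE`). The generic stiffness sizing kc = ρ0 c0² keeps steady
penetrations below a tenth of a spacing at hydrostatic-scale pressures; the
scenario defaults depart from it deliberately (amniotic 3 × 10⁴ N/m per m,
softer, so the driven wall does not re-radiate impact noise into the fluid;
CSF 3 × 10⁵, stiffer, so the brain's film-tracking resonance sits above the
jitter band; direct solid-solid contact of the unprotected scenario
2 × 10⁶, near-rigid, so the counterfactual is not itself a cushion).
Contact detection runs against the current deformed surface through the same
uniform-cell-grid machinery as the SPH neighbor search.

Two documented extensions to the bare normal law apply at fluid-wall
interfaces only:

* **Wall standoff** (half a particle spacing): the contact plane for
  particle *centres* sits half a spacing off the solid surface, matching the
  seeding offset, so the resting lattice touches the wall with zero force
  and any approach immediately builds pressure. Without it the seeding
  margins form a dead band (about ±0.6 mm at the CSF interface) across
  which the film transmits nothing.
* **Wetted (no-separation) walls**: a particle inside the wetted band bonds
  to the wall at its *formation thickness* — the film spring is force-free
  at the distance where the bond forms (the seeded distance for the initial
  layer, the standoff plane for particles arriving later) and sustains
  tension tapered to zero half a spacing beyond it, the thin-film suction a
  wetted layer supports before cavitating. This matters twice over. Without
  any tension the brain is *neutrally stable* inside the CSF annulus (a
  journal bearing has no static centering force) and rectified forcing
  noise makes it random-walk into the skull over a few seconds. And without
  the formation-thickness reference the film would either pre-stress the
  brain at rest (breaking the stress-free start) or bond too sparsely to
  centre it. With formation-thickness bonds the film acts as a bilateral
  spring bed about the initial configuration, the start is exactly
  quiescent, and the brain stays centred without spurious standing loads.
  Disable with `simulation_config(wetted_walls = FALSE)` to recover the
  pure push-only law (the unprotected scenario's solid-solid contact is
  always pure push-only).

### Seizure kinematics

The boundary condition is a roll-angle time series matching the reported
summary statistics of instrumented-mannequin seizure recordings: peak roll
rate 9.5 rad/s, peak-to-peak excursion 0.50 rad, dominant frequency 0.5 Hz,
60 s duration at 100 Hz. These targets are mutually unreachable for any
narrowband signal — a 0.5 Hz sinusoid spanning 0.5 rad peaks at ≈ 0.8
rad/s — so the synthesized signal is a primary sinusoid at the dominant
frequency plus seeded band-limited jitter (2–8 Hz cosines with random
phases, amplitudes rising as f² so the jitter carries angular velocity
while adding little angle). A two-parameter fixed-point calibration scales
the two components until the realized peak rate and excursion hit the
targets; the realized statistics ride along as attributes
(`glance()` on the trace). The reported peak angular *acceleration*
(5 rad/s²) is inconsistent with the other rows — any signal with 9.5 rad/s
peaks above a fraction of a hertz has hundreds of rad/s² — so it is
reported but not calibrated. Angle, rate and acceleration are evaluated
analytically, so the sampled trace is derivative-consistent to the sampling
error.

The trace drives the outer uterine boundary as a rigid rotation about the
model centroid, applied relative to the trace's initial angle so runs start
from the stress-free quiescent state; interior structures respond only
through the physics. A complementary filter
(`fuse_orientation()`, `apply_complementary_filter()`) is provided for
processing user-supplied raw gyroscope/accelerometer records; the synthetic
path produces fused angles directly.

## Scenarios, time stepping, problem sizes

The default scaled scenario is 2-D with ≈ 2500 fluid particles
(amniotic 2.5 mm spacing, CSF 1.2 mm), ≈ 2100 solid elements, and 6 s of
simulated time — three convulsion cycles at the 0.5 Hz dominant frequency —
as a desk-scale surrogate for the original full-resolution 3-D, 60 s
GPU-week run. All claims made of it are ratios and bounds tolerant of that
reduction. The explicit step is
`dt = CFL × min(fluid, solid, contact limits)` with CFL 0.25: per fluid
h / (c0 (1 + 1.2 α)), per deformable solid the minimum element altitude over
the dilatational wave speed, per interface √(m_min/kc). The defaults give
dt ≈ 1.1 × 10⁻⁵ s, about half a million steps for the nested scenario
(roughly ten minutes on one CPU core).

The *unprotected* counterfactual ("no_fluids") is not defined in the source
material; here it removes both fluid layers and transmits load by direct
penalty contact: uterine wall against the fetal body surface, skull against
the brain surface — the minimal counterfactual consistent with comparing
against an unprotected state. Attenuation is
100 × (1 − protected peak / unprotected peak) of peak brain von Mises
stress and of peak brain–skull relative displacement.

## Numerical choices and degenerate inputs

* Density drift under long weakly compressible integration is controlled by
  Shepard reinitialization every 30 steps (configurable).
* Artificial viscosity acts only on approaching pairs; with α = β = 0 and
  zero pressure the momentum equation reduces exactly to gravity.
* Ties use a combined-mass master/slave update so the junction is rigid and
  momentum-conserving; with a rigid skull the rigid body is the master.
* Degenerate (zero-area) elements, infeasible geometry (layers that
  intersect, spacings that do not fit their gap), empty seeding regions,
  too-short traces, filter coefficients outside [0, 1] and negative times
  are all rejected with errors naming the violated quantity. Runaway
  penetration (beyond a per-interface cap) and non-finite state abort with
  the offending step number.
* Everything is deterministic given the configuration and seed; repeated
  runs produce bit-identical metrics.

## What the tests show — and what they do not

The test suite verifies the numerical core against independent oracles
(closed forms, quadrature, brute-force double loops): kernel normalization,
partition of unity, momentum conservation, the hereditary-integral limit of
the Maxwell update, the closed-form oscillator period, hydrostatic
equilibrium of a particle column against a penalty wall within 5%, exact
point-to-segment distances, and the worked stress-scalar example
(principal stresses 115/38/9 kPa giving a truncated von Mises stress of
94 kPa, mean stress 54 kPa, triaxiality 0.57). The scenario-level
acceptance checks assert the *pattern* of hierarchical cushioning on the
default scaled run: the brain–skull separation pinned near baseline while
the fetus–uterus separation swings far more, sub-2 mm brain–skull relative
displacement, and ≥ 90% attenuation of peak brain stress relative to the
no-fluid counterfactual.

Passing those checks shows that the implemented mechanics reproduce the
qualitative hierarchy on a synthetic, parametric, two-dimensional anatomy
with placeholder moduli. It does not validate stress magnitudes (which
scale with the placeholder moduli), does not capture three-dimensional
escape paths for either fluid (2-D confinement overstates hydraulic
coupling at both levels), has no patient-specific geometry, no placenta or
umbilical cord as distinct materials, no multi-axis kinematics (only roll
was recorded in the source data; the contradiction with the
three-component-acceleration figure in the source is resolved in favour of
roll-only), and no biological response of any kind.

## Known limitations

* 2-D plane-strain with unit thickness: masses and forces are per metre of
  depth; absolute magnitudes should be read as scaled quantities.
* The inner-layer observables sit at the resolution limit: five particle
  layers across the CSF film leave percent-level granularity in the
  normalized separations. Over the default 6 s run the *median* worst-landmark
  deviation stays in the low single-percent range, but transient excursions
  during the most violent roll jerks reach tens of percent of the (6 mm)
  gap — about a millimetre of brain lag — because the film's effective
  tracking resonance sits near the top of the 2–8 Hz jitter band in 2-D.
  The brain–skull relative displacement bound (< 2 mm) holds throughout.
* The outer-level excursions are milder than in the original model
  (mean a few percent of the 20 mm gap versus reported swings to 0.2–1.8 ×
  baseline), because a pure roll of a nearly concentric elliptical cavity
  moves the wall radially by only a few millimetres; the original loading
  included three-component linear accelerations that are not part of the
  recorded roll-only boundary condition reproduced here. The hierarchy
  (outer excursions exceeding inner ones) is preserved and is what the
  acceptance checks assert.
* The brain-centring relies on the wetted-wall condition; with push-only
  walls the neutral-equilibrium drift dominates within seconds (this is a
  physical property of frictionless annular films, not a bug, but it means
  the no-separation assumption is load-bearing).
* Small-strain elements make the driven uterine wall "breathe" by O(θ²)
  under finite rotation (≈ 2–3 mm at the ±0.25 rad excursions); this adds
  forcing at the outer level and is accepted as part of the scaled scenario.
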