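---
title: "Modelling channel-assisted HD-tDCS: volume conduction and neuron polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling channel-assisted HD-tDCS: volume conduction and neuron polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-definition transcranial direct current stimulation (HD-tDCS) injects a
weak direct current (here 1 mA) through a 4x1 ring of scalp electrodes. The
skull's low conductivity shunts most of that current away from the target,
so the cortical electric field (EF) is weak and diffuse. A *transcranial
channel* is a biocompatible conductive implant — an I-shaped cylindrical
shaft, or a T-shaped shaft with a hat — that traverses the skull thickness
without breaching the dura and acts as a preferential current pathway.

`tcranchan` models this system in two stages:

1. a quasi-static volume-conduction solve of `div(sigma grad phi) = 0` on a
   parametric voxelized head, giving the potential and the induced EF, its
   radial/tangential decomposition on the cortical surface, the peak EF,
   and Vol_50..Vol_80 focality volumes (cortical volume where |E| exceeds
   50–80% of its peak);
2. a passive compartmental-cable stage in which layer 5 (L5) and layer 3
   (L3) pyramidal neurons, placed perpendicular to the cortical surface,
   are driven by the extracellular potential sampled at their compartment
   centers, yielding steady-state membrane polarization per compartment and
   somatic coupling constants (mV of somatic polarization per mV/mm of
   local field, i.e. mm).

Two experiments are built in: a channel sweep (shapes I/T x shaft diameters
1–9 mm, plus the channel-free reference) and an electrode-displacement
sweep (the montage slides rigidly off the implanted channel in 5 mm steps).

## The synthetic head

The anatomy is deliberately simple and fully parametric: flat scalp
(5 mm), skull (7 mm), dura (0.5 mm) and a CSF gap (2 mm at the crown) above
a gray-matter ribbon (2.5 mm) whose upper surface follows a sinusoidal fold
`z(x) = z_crown + A (cos(2 pi x / W) - 1)` with amplitude `A = 2` mm and
wavelength `W = 28` mm — one crown, a hand-knob-like ridge, sits directly
under the active electrode. White matter fills the rest. The dura thickness
is the one layer dimension the underlying physiology pins down exactly; the
others are typical adult values and all are configurable
(`head_params()`). The montage uses disc electrodes (height 1 mm, radius
4 mm) on gel pads (2 mm, radius 4 mm) with the four returns on a 35 mm
ring, a conventional 4x1 spacing.

What this geometry reproduces: the layered conductivity contrast that
produces skull shunting, a curved crown with a genuine radial/tangential
field structure, and a cortical ribbon into which neurons can be embedded
at physiological depths. What it does not reproduce: sulcal walls facing
each other across narrow CSF clefts, gyral anatomy away from the target,
and subject-specific skull thickness variation. Quantities that depend on
those — the absolute peak EF a subject-specific head model would give (a
real head concentrates current differently) and the absolute Vol_p
magnitudes — are therefore *not* comparable in magnitude; all trend
statements (channel vs none, diameter ordering, T vs I, retention under
displacement) are, and those are what the test suite asserts.

```{r}
library(tcranchan)
head <- head_params()
grid <- build_head_model(head_grid(head, spacing = 0.5), head)
grid <- carve_channel(grid, channel_spec("T", shaft_diameter = 7))
placed <- place_montage(grid, montage_spec())
```

## The volume-conduction solve

Conductivities (S/m) are the standard isotropic literature values: scalp
0.465, skull 0.01, dura 0.065, CSF 1.65, GM 0.276, WM 0.126, gel 0.30,
electrode metal 5.8e7, titanium channel 7.4e5. The discretization is
node-based trilinear finite elements on the voxel grid with per-cell
constant conductivity — a 27-point stencil. Air cells are excluded, which
realizes the insulating external boundary naturally. The active electrode's
exposed top faces carry a uniform Neumann current density summing to 1 mA
(the metal's conductivity makes the result insensitive to that
distribution); all four return-electrode top faces are Dirichlet ground, as
close to the stated montage reference as a voxel model allows.

The system is symmetric positive definite and solved by preconditioned
conjugate gradients to a relative residual of 1e-9. The default
preconditioner is a geometric multigrid V-cycle: vertex-centered 2:1
coarsening, trilinear interpolation, Galerkin (`P^T A P`) coarse operators
— which preserve the 27-band structure exactly — and one symmetric
Gauss-Seidel sweep as pre- and post-smoother, so the V-cycle is itself
symmetric positive definite and safe inside CG. Two refinements matter for
this problem class. First, each connected metal component (the channel and
the five electrodes) carries a near-rigid potential mode that neither the
smoother nor the trilinear coarse space represents — with a 1 mm titanium
shaft the iteration count explodes by an order of magnitude. The
preconditioner therefore adds an exact coarse correction over the
component indicator vectors (a deflation subspace, solved through the
small `W' A W` system), which restores a contrast-independent iteration
count of roughly 120 at 0.5 mm. Second, the entire hierarchy is stored
and applied in single precision, halving its memory traffic; CG's own
residuals and products stay in double precision on the exact operator, so
the achievable accuracy is unaffected — the preconditioner only steers the
search. Jacobi and SSOR preconditioning remain available
(`solver_config(precond =)`); they produce the same fields to print
precision, only slower. Within a sweep, each configuration starts from the
previous configuration's solution; the convergence criterion is unchanged,
so warm starting affects only the iteration count.

Per-cell fields are the exact cell-average gradient of the trilinear
interpolant, `E = -grad phi`. Conservation can be checked independently of
the FEM residual with `current_flux_box()`, which integrates `sigma E . n`
over a voxel box using centered differences of cell-mean potentials and
harmonic-mean face conductivities; on the default head it recovers the
injected 1 mA to better than 1%.

Validation rests on two oracles. A homogeneous conducting sphere with a
surface current source and sink has the classical interior Legendre-series
solution (implemented in `sphere_surface_potential()`, itself verified
against the closed-form limit of its series); the voxelized solve matches
it to about 1% relative L2 over the surface, sampling outside 15-degree
caps around the electrodes where the point-source singularity makes a
patch-electrode comparison meaningless. And a homogeneous slab with fixed
top/bottom potentials reproduces the linear solution to solver precision.

### Channel geometry choices

The hat of the T-shaped channel sits by default on the *outer* skull table
(`hat_side = "outer"`), the natural orientation for a rivet-like implant:
the hat collects current arriving through the gel and scalp and funnels it
into the shaft. With the hat on the dural table instead, the disc spreads
the shaft's output and the T-channel's peak field drops below the
I-channel's — the opposite of the consistently reported T-over-I ordering
— so the outer table is also the orientation the device's observed
behavior implies. Both options are kept.

One trend caveat: on this slab head the peak EF grows steeply with shaft
diameter, saturates, and declines, but its maximum sits at 5 mm rather
than 7 mm. We probed the obvious controls — hat orientation and crown CSF
thickness (a thinner CSF shifts the optimum *earlier*) — and neither moves
the optimum outward; its exact location evidently depends on skull
curvature and sulcal anatomy that the parametric geometry deliberately
omits. Every other ordering (channel vs none, T vs I, decline at 9 mm,
relative-focality ranking) is reproduced.

## Field metrics

Cortical surface normals come from the gradient of a box-smoothed GM
indicator, oriented outward (GM to CSF) and checked against label
adjacency. The radial component is signed positive when the field points
*into* the cortex (the anodal, soma-depolarizing direction); the
tangential component is the cross-product magnitude, so
`Er^2 + Et^2 = |E|^2` holds exactly.

`focality_volumes()` uses the strict inequality `|E| > p * peak` over GM
cells. The peak cell therefore counts toward every Vol_p; the degenerate
exactly-uniform field is reported as all-zero volumes by convention. Ties
at the peak resolve to the lowest linear cell index. Whether "cortex"
includes WM is a modelling choice; we report GM only.

## Neurons and the cable stage

The L5/L3 morphologies are parametric stand-ins built by `build_pn()`:
soma (20 um), apical trunk with a tuft, oblique and descending basal
dendrites, initial segment, and an axon that for L5 crosses the GM/WM
boundary (landmark `b1`), bends (`b2`) and terminates in the white matter,
and for L3 stays within the gray matter. Landmarks mirror the standard
probe set (`d1`, `d2` apical-tip, `d3`, `d4`, `soma`, `iseg`, `b1`, `b2`,
`terminal` for L5). Established reconstructions can be imported through
standard SWC files (`read_swc()`; type code 5 is used for the initial
segment on export).

Placement (`place_neuron()`) aligns the local pia-ward axis with the
outward cortical normal, puts the L5 soma at 0.75 of the local GM
thickness (layer 5) and the L3 soma at 0.4, stretches the apical tree so
its tip reaches the layer-1 band (top 10% of GM), and stretches the L5
axon so `b1` falls on the GM/WM boundary; stretch factors are recorded.
The region of interest is a 5 mm-radius disc on the crown populated on a
deterministic 0.84 mm lattice — about 112 cells, a density typical of
this kind of ROI analysis.

The membrane model is the passive steady-state linearization: for
sub-threshold polarization, which is what DC stimulation produces at these
intensities, the steady state of the full cable equation satisfies the
linear system `(G_axial + G_membrane) dV = -G_axial e`, with axial
conductances from series half-cylinder resistances (`R_a = 150` Ohm cm),
membrane leak `pi d l / R_m` (`R_m = 30000` Ohm cm^2), sealed ends, and
the extracellular potential `e` sampled at compartment centers (mV).
Passive parameters are declared defaults, overridable per part (e.g. the
initial segment); the exact values used with the original reconstructions
are not published, so absolute polarization magnitudes carry that caveat.
A backward-Euler time integrator (`integrate_polarization()`,
`C_m = 0.75` uF/cm^2) is included purely as an independent check that the
linear solve is the correct long-time limit; it agrees to 0.1% after ten
membrane time constants. Compartments are built at 25 um, an order of
magnitude below the smallest electrotonic length constant among the
default calibers, satisfying the l <= 0.1 lambda rule without run-time
subdivision.

Two analytic anchors: a uniform straight fiber polarizes at its sealed
ends by `E lambda tanh(L / 2 lambda)` with
`lambda = sqrt(d R_m / (4 R_a))`, which the solver reproduces to 1% at 250
compartments (the test fiber's root sits at its center so the discrete
problem is exactly antisymmetric and the midpoint polarization vanishes);
and on arbitrary random trees the sparse solve agrees with a dense direct
solve to 1e-10.

### The flatness factor

The morphology-sensitivity experiments vary the soma diameter and a
"flatness" factor emulating flat-dendritic-tree variants. A caution from
passive cable theory: simply compressing the apical tree vertically
*shortens the antenna* and monotonically reduces somatic depolarization —
we verified this numerically across parametrizations. Anatomically,
however, a flat dendritic tree does not discard its arbor; it redistributes
it laterally. The flatness factor therefore compresses the trunk while the
tuft branches spread wider and thicker (span-conserving flattening). In
the electrotonically compact limit the soma then couples to a large
membrane area sitting high in the potential gradient, and somatic
depolarization *increases* with flattening — the behavior reported for
flat-tree pyramidal variants. This is the one generator parameter whose
geometric interpretation was genuinely open; the choice and its rationale
live here.

## Experiments and reporting

`run_sweep()` executes either experiment end to end; each configuration
rebuilds geometry, solves, computes metrics, and polarizes the shared ROI
population (placed once on the base geometry, since the ROI is anchored to
the implanted channel, which never moves). Failures are recorded per
configuration without aborting the sweep. `write_report()` emits
`focality.csv` (peak EF and Vol_50..80 per configuration),
`polarization_stats.csv` (per-landmark median/Q1/Q3/min/max; quantiles use
the linear-interpolation convention, type 7), `coupling.csv`,
`retention.csv` (peak somatic |dV| relative to zero displacement, exactly
1 in the first row) and a JSON manifest with the fully resolved
configuration and a checksum of the base grid labels. Identical
configurations reproduce byte-identical CSVs.

Problem sizes: the channel sweep runs on the default head at 0.5 mm
(about 1.6M cells, 11 configurations); the displacement sweep defaults to
1 mm on a laterally wider head (126 mm, so the displaced montage stays on
the scalp), where the 5 mm displacement steps are resolved by 5 cells and
the retention trend is insensitive to the finer grid. The sphere oracle uses a
25 mm sphere at 1 mm. These sizes keep a full validation run on a single
CPU core in the tens of minutes while leaving every trend assertion
comfortably clear of discretization noise.

## Known limitations

- Absolute peak EF and Vol_p magnitudes depend on real anatomy (sulci,
  skull curvature, subject-specific segmentation) and are not reproduced —
  only trends and machinery are.
- Conductivities are isotropic; skull anisotropy is out of scope.
- The cable stage is passive; no active conductances, synapses, or spike
  threshold prediction.
- Electrode-tissue interface impedance, heating and electrochemistry are
  not modelled.
- The voxel hat/shaft are staircase approximations of cylinders; at
  0.5 mm the smallest (1 mm) shaft spans two cells, the stated design
  minimum.
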