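---
title: "Methods: a reduced model of cation permeation through a channel pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced model of cation permeation through a channel pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`poreflux` analyzes ion permeation through a membrane channel pore.  Its
analysis stages — permeation-event counting and conductance, HOLE-style
pore-radius profiling, 3D ion-density mapping, coordination counting, and
umbrella-sampling/WHAM free-energy estimation — operate on any trajectory
in the package's formats.  Because all-atom trajectories of a full
channel/membrane system are produced on supercomputers and are not
generally redistributable, the package ships a reduced Brownian
(overdamped Langevin) simulator that emulates the statistical structure
such trajectories present to these analyses.

The channel is modelled as a 1D free-energy landscape along the pore axis
z (z = 0 at the intracellular reference plane, +z extracellular):

* three Gaussian binding wells **A** (z = 24 Å), **B** (19 Å) and **C**
  (9 Å), mirroring the selectivity-filter sites (A, B) and the site just
  above the gate (C), with the B–C spacing fixed at ~10 Å;
* one Gaussian **gate barrier** at z = 4 Å, the rate-limiting
  constriction;
* a linear **membrane-field** term on the pore interval, derived from the
  membrane potential (−100 mV by default for conduction runs);
* a screened-Coulomb **pair repulsion**
  `q_i q_j · 332.06/(ε_r r) · exp(−r/λ)` between ions.

Well depths and the gate height are not free knobs: they are calibrated
numerically (`default_channel_potential()`) so that the single-ion inward
barrier out of each well equals the target heights 0.71, 6.37 and
7.52 kcal/mol at A, B and C — the benchmark values for this channel in
its open, agonist-bound state.  Calibration runs at zero field (the
targets describe the intrinsic landscape); the field is overlaid
afterwards, which can legitimately wash out the shallow outer well A in
the total potential.

### Repulsion parameters

The screening length defaults to λ = 7.9 Å, the Debye length of a 150 mM
1:1 electrolyte at 310 K (computed, not fitted).  For the relative
permittivity we use ε_r = 4, a standard protein-interior value, rather
than the bulk-water 80: the pore lumen is protein-lined and largely
dehydrated, and with ε_r = 80 the pair term at the B–C separation
(~0.12 kcal/mol, far below kT) could not produce the cooperative
knock-off conduction the model is meant to express.  With ε_r = 4 a
restrained ion at site B lowers the site-C escape barrier by
~1.5 kcal/mol (analytic), qualitatively reproducing multi-ion barrier
lowering without being tuned to any published magnitude.  Inside the
simulator the pair force is soft-core regularized below ~1 Å separation
(r → √(Δz² + 1 Ų)), a standard Brownian-dynamics device that is
irrelevant at binding-site separations (≥ 4 Å) but removes the axial
singularity when two confined ions cross.

### Dynamics and boundaries

Ions follow the overdamped Euler–Maruyama update
`Δr = F·(D/kT)·Δt + √(2DΔt)·ξ` with D = 0.1 Å²/ps (sodium-like) and
Δt = 0.01 ps; a guard aborts if any step exceeds 2 Å (the remedy is a
smaller Δt — needed, e.g., for restraints stiffer than
k·D·Δt/kT ≈ 0.1).  At 0 K the noise vanishes and the update degenerates
to gradient descent (the 310 K mobility is used).  In-plane (x, y) motion
is confined by a flat-bottom harmonic wall of radius 2.5 Å inside the
pore region and 12 Å in the reservoir.  The default box is
30 × 30 × 60 Å with z ∈ [−10, 50]; 6 ions approximate 150 mM in this
volume.  The top of the box reflects; an ion crossing the bottom
(intracellular) wall is logged as a **raw exit** and re-injected one box
height up, sustaining a steady conduction flux without imposing a
sawtooth correction on the field term.  For true-equilibrium checks
(Boltzmann inversion) the bottom wall can instead reflect
(`bottom_wall = "reflect"`).  A single master seed drives R's RNG through
the compiled integrator, so trajectories are bitwise reproducible.

## Permeation counting and conductance

`detect_permeations()` runs a three-compartment state machine per ion
(extracellular > 40 Å, pore, intracellular < −5 Å; both planes
configurable).  An event requires the full ordered passage through the
pore, and an ion must re-enter from a bulk compartment before it can
count again, so boundary dithering is never double-counted.  Transits
containing an inter-frame jump larger than half the box height are
re-injection/wrap bookkeeping, not passages, and are ignored.  The event
balance (inward − outward = raw exits + ions finishing below) is exact on
every synthetic run.  Conductance follows
`G = N·Q_ion/(t·|V_membrane|)` per run with the mean and the sample
(n−1) SD across runs — the n−1 convention is the one that reproduces the
benchmark ±2.2 pS spread, and is therefore fixed package-wide.

The knock-off statistic `cooperativity_fraction()` is an
artifact-defined metric (the phenomenon is usually shown qualitatively):
the fraction of inward events for which, within ±1 ns of the event ion's
release from site C, the previous site-B occupant becomes the site-C
occupant.

## Pore profiling

`slice_radius()` maximizes the clearance `min_i(|p − atom_i| − vdw_i)`
over in-plane centers p using a deterministic 1 Å start grid within 3 Å
of the axis guess plus Nelder–Mead refinement; 3D distances make
off-plane spheres intersect the slice plane with effective radius
`√(vdw² − dz²)` automatically.  Seeding near the axis (and walking the
previous slice's center up the pore in `profile_over_frames()`) keeps the
search in the lumen instead of jumping outside the wall; a sphere
reaching the 15 Å cap marks bulk.  Radii default to H 1.20, C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å (a small built-in table, overridable
per call — deliberately not a verbatim copy of HOLE's radius file, so
absolute radii on real structures may differ slightly).  Minimum-radius
thresholds 1.4 Å (water) and 2.0 Å (hydrated cation) classify profiles
as closed / water-only / cation-permeable.

## Density, binding sites, coordination, RMSD

`density_grid()` histograms selected particles on 0.5 Å voxels and
normalizes by frames × voxel volume (Å⁻³); the integral equals the mean
per-frame particle count inside the bounds to 1e−9 by construction.
`find_binding_sites()` thresholds at 0.005 Å⁻³ and groups voxels by
26-neighbor connectivity with density-weighted centroids — stated
explicitly because isosurface pictures usually leave both choices
implicit.  `coordination_count()` counts (oxygen) atoms within 3 Å.
`rmsd_series()` reports per-frame RMSD; Kabsch superposition is optional
and off by default, as membrane-embedded systems are usually analyzed in
a fixed frame.

## Umbrella sampling and WHAM

Windows sit at 0.5 Å spacing (81 windows over the 40 Å reaction
coordinate; 31 over the 15 Å gate-region coordinate used for multi-ion
configurations), with a 5 kcal/mol/Å² tagged-ion restraint.  Each window
runs 10⁶ steps (10 ns) and discards the first 30% (the analogue of
keeping the last 7 ns of a 10 ns window); saved every 70 steps this
yields 10⁴ samples per window.  Windows are initialized at their centers
rather than from a pulling run — only the stationary window distribution
enters WHAM.  Extra upstream ions (knock-off configurations) are
restrained at their sites with 2.5 kcal/mol/Å²; their bias is *not*
unbiased out, so the multi-ion PMF is by definition the tagged ion's free
energy in the field of its restrained neighbors.

`wham_pmf()` iterates the standard coupled WHAM equations (stated in its
help page) until the largest shift change falls below 1e−6 kcal/mol
(default; cap 1e5 iterations), bins at 0.1 Å, anchors min F = 0, flags
empty interior bins instead of interpolating, and reports the adjacent
histogram overlap `Σ min(p_i, p_j)`.  `barrier_heights()` measures, for
each site, max F between the site's minimum and the next inward site's
minimum (or the grid edge) minus the site minimum; a monotone profile
yields NA, never 0.  Anchoring the inward segment on the supplied site
ranges keeps the extraction robust to bin-level noise.

## Problem sizes and what the tests show

The shipped tests and the acceptance script use the study-scale umbrella
plan (81 × 10⁴ samples) but deliberately short conduction runs (tens to
hundreds of ns): with the calibrated 7.5 kcal/mol gate, spontaneous
events arrive roughly once per 50 ns under −100 mV, so short runs
exercise the full pipeline while keeping a complete analysis in minutes
on one core.  Parameter-recovery results (PMF RMS < 0.3 kcal/mol,
site centroids within 1 Å, site-C barrier within 0.3 kcal/mol of its
7.52 target, multi-ion lowering in 5/5 paired seeds) validate the
*analysis machinery* against the generator's known ground truth.  They do
not validate the reduced model against real channels: the simulator has
no explicit water, protein flexibility, or grand-canonical ion exchange,
its field acts on a fixed interval, and pair interactions are projected
on the axis.  Conductance from the reduced model is therefore not
expected to match patch-clamp values; the conductance *arithmetic* is
instead verified against the benchmark run counts.

## Known limitations

* 1D energetics: no radial structure inside the wells; site A
  multi-occupancy emerges only through axial crowding.
* The weak-field regime: −100 mV tilts the 40 Å pore by ~2.3 kcal/mol,
  so field effects on event counts are modest and statistically
  expensive to resolve at short run lengths.
* WHAM uncertainties are not bootstrapped; overlap diagnostics and
  paired-seed replication stand in for error bars.
* PMF gaps are reported, not interpolated; disconnected ladders converge
  per segment with arbitrary relative offsets.
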