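---
title: "Coarse-grained simulation of lipid nanoparticle self-assembly with lnpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation of lipid nanoparticle self-assembly with lnpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpsim)
```

## The model

`lnpsim` simulates the self-assembly of tripalmitin lipid nanoparticles
(LNPs) in water, optionally coated by the nonionic surfactant Tween 20
(polysorbate 20), with a Martini-style coarse-grained (CG) representation:
roughly four heavy atoms and their hydrogens map to one interaction bead of
72 amu, regardless of type. Five bead types appear in these systems:

* **C1** — apolar chain bead (alkyl tails, hydrophobic linker carbons);
* **Na** — intermediate-polarity bead with hydrogen-bond-acceptor character
  (ester groups);
* **P3** — polar bead (polyoxyethylene arms of the surfactant);
* **P4** — CG water, one bead for four real water molecules;
* **AF** — "antifreeze" water bead whose enlarged size against P4
  frustrates the artificial crystallisation that a pure P4 lattice
  undergoes near room temperature; one AF bead accompanies every ten P4
  beads.

All species here are nonionic, so there are no charges and no
electrostatics; cohesion and hydrophobic separation arise entirely from the
graded Lennard-Jones matrix.

**Tripalmitin** (glycerol tripalmitate) maps to 19 beads: three C16 tails
of four C1 beads each, one Na bead per ester group, and a four-bead C1
glycerol/linker region. The Martini mapping rules fix the bead census
(16 C1 + 3 Na) but depicts connectivity only pictorially; the 4 + 4 + 4
tail / 3 ester / 4 linker graph used here is the assignment consistent with
a 4:1 heavy-atom mapping of the 155-atom molecule. **Tween 20** maps to
30 beads: a five-bead sorbitan ring modelled at finer resolution (one heavy
atom plus hydrogens per bead), four polyoxyethylene arms of P3 beads
(21 in total, one arm carrying the ester Na bead and a three-bead C1 lauryl
tail). The exact per-arm lengths of the PEG-like arms are a documented
convention (6 + 5 + 5 + 5 ethoxylate beads); only their total is
constrained by the 30-bead census.

The ring geometry must stay near-rigid. Rather than holonomic constraints,
the ring is held by stiff harmonic bonds (r0 = 0.33 nm,
k = 20000 kJ mol^-1 nm^-2) along the pentagon edges plus harmonic distance
restraints across all five diagonals (k = 2000). This keeps the integrator
contract simple (everything is a bond), and at the 20 fs time step the
scheme is comfortably stable: the stiffest mode has a period of roughly
0.4 ps, about 21 steps, and the thermal root-mean-square bond-length
fluctuation `sqrt(kT/k)` is about 3.5% of r0. A dedicated test verifies
that the mean ring bond-length deviation stays below 5% over 10^4 solvated
MD steps at 310 K.

## Force-field parameters

CG models of this family take their interaction matrix from the standard
Martini tables, which this package does not redistribute verbatim. The
shipped defaults (`inst/extdata/martini_cg.yaml`) use documented
Martini-2.0-like magnitudes: sigma = 0.47 nm for regular pairs, 0.43 nm
between ring beads (with epsilon scaled by 0.75), epsilon levels from 2.0
to 5.6 kJ/mol graded by polarity, chain bonds r0 = 0.47 nm with
k = 1250 kJ mol^-1 nm^-2, and cosine-harmonic chain angles with
theta0 = 180 deg and k = 25 kJ/mol. The AF bead interacts as a P4 bead
except for an enlarged sigma of 0.57 nm against P4 — the antifreeze
mechanism. Everything lives in the YAML file; users wanting an exact
published table substitute their own, and `load_forcefield()` validates any
table against three requirements: symmetry, positivity, and the
*hydrophobic ordering* `eps(C1,P4) < eps(C1,C1)` and
`eps(C1,P4) < eps(P4,P4)` without which hydrophobic collapse — the physics
this package exists to reproduce — cannot occur.

The angle potential is the cosine-harmonic form
`V = k/2 (cos(theta) - cos(theta0))^2` rather than a harmonic in theta:
it is the conventional CG choice and is regular at theta = 180 deg, the
equilibrium of every chain angle here. Dihedrals are omitted: the two
modelled molecules are flexible chains for which no dihedral parameters
are specified, and the ring — the one place torsional stiffness
matters — is held by the distance restraints instead.

## Molecular dynamics methodology

The integrator is velocity Verlet with a Langevin thermostat in the BAOAB
splitting (half kick, half drift, Ornstein-Uhlenbeck velocity refresh, half
drift, half kick). The O-step uses the exact OU solution, so
fluctuation-dissipation holds at any friction; with gamma = 0 the scheme
reduces *exactly* to NVE velocity Verlet, which the energy-conservation
tests exploit. The friction default is 1 ps^-1 (the value is not dictated
by the model; it sets thermostat coupling strength, not equilibrium
averages).

Lennard-Jones interactions use the 12-6 form truncated at 1.4 nm with a
C1-continuous switching function applied to the potential from 1.0 nm:

    S(r) = (rc^2 - r^2)^2 (rc^2 + 2 r^2 - 3 ron^2) / (rc^2 - ron^2)^3

whose value and first derivative vanish at the cutoff and match the
unswitched potential at the onset. Forces include the dS/dr term, so they
are the exact negative gradient of the implemented energy — verified by
finite differences and by NVE drift below 0.5% of the mean kinetic energy
over 10^4 steps at the 20 fs production time step. First and second bonded
neighbours (1-2, 1-3) are excluded from LJ interactions; the minimum-image
convention applies throughout in the cubic periodic box. Neighbour search
uses a Verlet pair list built through fine linked cells (skin 0.15 nm,
rebuilt when any bead moves half a skin).

Pressure control is an isotropic weak-coupling barostat: the box and all
coordinates are rescaled each step by
`mu = (1 - dt/tau * beta * (P0 - P))^(1/3)` with tau = 2 ps and
beta = 4.5e-5 atm^-1, using the virial pressure. Its contract is that the
*mean* pressure equals the target; it does not reproduce the correct
volume-fluctuation spectrum of an extended-Lagrangian piston, which none of
the structural observables here depend on. Units are the GROMACS-style
set — nm, ps, amu, kJ/mol — in which kinetic energy needs no conversion
constant; temperature is `2 Ekin / (3 N kB)` and pressures are reported in
atm (1 kJ mol^-1 nm^-3 = 16.388 atm).

All reported times are *nominal* (step count times dt). CG dynamics are
known to run faster than physical time — the conventional correction for
Martini-class models multiplies nominal time by about 4 — but, as in the
reference work, no correction is applied anywhere in this package.

## System construction

`build_system()` places solute molecules on a cubic lattice centred in the
box, drawing a seeded random orientation per molecule, and picks the
smallest lattice spacing at which no intermolecular bead pair comes within
0.3 nm under minimum image. At desk-scale compositions, where the solute
fraction is deliberately high, a rigid lattice can be infeasible; the
builder then falls back to seeded random sequential insertion with overlap
rejection before resorting to enlarging the box. Water fills the remaining
volume on a jittered lattice at 8.3 beads/nm^3 (the liquid-like density at
1 atm for these parameters), with AF beads interspersed at random among the
P4 sites at the configured ratio. Velocities are Maxwell-Boltzmann at the
target temperature with the net momentum removed. Everything is a pure
function of the spec and its seed: identical inputs give bit-identical
states.

The five full-scale presets `s1`-`s5` reproduce the reference study compositions
exactly (64-392 lipids, up to 221 surfactants, tens of thousands of water
beads) and initialise the box at the reference equilibrium side so the
barostat only has to fine-tune the density. One bookkeeping note: the S1
reference composition lists 462 AF beads against 4176 P4
beads, a ratio of 9.04 rather than the stated one-in-ten rule
(`water_composition(4176)` gives 418). The presets follow the printed
table verbatim; the helper implements the stated rule; the discrepancy is
recorded rather than resolved.

Energy minimisation is normalised steepest descent with step-size
backtracking (trust step 0.02 nm, growing 1.2x on acceptance, halving on
rejection). It is slower than conjugate gradients but robust on
hard-overlap starts, and minimisation cost is negligible at every scale
this package runs.

## The desk-scale preset

The `desk` preset is the package's reduced self-assembly experiment: 24
tripalmitin molecules with a thin water shell (1500 P4 + 150 AF beads,
about 2100 beads in a 6.35 nm box) run for 2 x 10^5 steps (4 ns nominal)
under the production thermostat and barostat. The composition was chosen
once so that a single CPU core completes the run in minutes while the
lipid volume fraction (about 20%) keeps diffusion-limited encounter times
short enough for all lipids to coalesce into one cluster within the run.

What the desk run demonstrates: spontaneous hydrophobic collapse into a
single liquid-like aggregate, with a lipid number density near one molecule
per nm^3 when measured as `3N/(4 pi Rg^3)`. What it cannot show: the
interior water droplet (which appears only in particles several times
larger), near-zero asphericities (a 24-lipid droplet has large relative
surface fluctuations), surfactant stripe patterns, or quantitative
agreement with the full-scale radii — those require the `s1`-`s5`
compositions at full scale and hundreds of nanoseconds
(`inst/experiments/full_scale_s1.R` is the documented long-run entry
point).

## Analysis definitions

* **Radius of gyration** — mass-weighted RMS distance from the centre of
  mass. Aggregates are made whole first: each molecule is unwrapped over
  its bond graph, then molecules are shifted by whole box lengths along a
  breadth-first traversal of the intermolecular contact graph
  (`make_whole()`), since the shape formulas assume a connected cluster and
  wrapped coordinates would inflate every moment.
* **Asphericity** — the gyration tensor is diagonalised; with principal
  radii R1 >= R2 >= R3 (square roots of the eigenvalues, so
  Rg^2 = R1^2 + R2^2 + R3^2), `Delta = 3/2 sum_i (Ri - Rm)^2 / (sum Ri)^2`
  where Rm is their mean. Delta is 0 for an isotropic configuration and
  exactly 1 for any collinear one; degenerate (planar/collinear) inputs
  yield zero eigenvalues, not errors. Two printed-formula ambiguities in
  the source material are resolved the only dimensionally consistent way:
  the sum runs over the three principal radii (not N beads), and the third
  term of the Rg^2 identity is R3 squared.
* **Lipid number density** — `3 N / (4 pi Rg^3)`, i.e. molecules per unit
  volume of the sphere whose radius is taken as Rg itself; reported to two
  decimals as in the reference tables. Because a uniform sphere of radius
  R has Rg = sqrt(3/5) R, this convention overstates the geometric density
  by a fixed factor — it is used as a *consistency index* across particle
  sizes, not as a physical density.
* **Aggregate detection** — two molecules are connected when any
  intermolecular bead pair lies within 0.6 nm (just above the regular bead
  sigma; the choice is configurable and no published value exists);
  aggregates are connected components of that graph.
* **Interior water** — the box is voxelised (0.35 nm default), voxels
  within one bead radius (0.47 nm) of any lipid bead are blocked, and the
  unblocked space is flood-filled with periodic 6-connectivity, seeded
  from the unblocked voxel farthest (minimum image) from the aggregate's
  circular-mean centre of mass — a seed that always lies in the exterior
  when one exists, even when the aggregate straddles a box face; water
  beads in unreached voxels are interior. This
  volumetric definition is robust to non-spherical water pockets, is
  translation invariant, and recovers exact counts on constructed
  hollow-shell fixtures for any voxel size between 0.2 and 0.5 nm. A water
  bead landing in a *blocked* voxel (possible in dense interfacial
  regions) inherits the label of the nearest unblocked voxel. Because
  "inside the nanoparticle" has no unique operational definition, interior
  counts are a stated convention of this package, and full-scale
  comparisons against reference interior-water counts are soft checks.
* **Exchange events** — per-frame interior labels are scanned per bead;
  a flip counts only when the new label persists for at least the debounce
  window (default 2 frames), suppressing grazing excursions of the
  interface.
* **Surface coverage** — surfactant beads within a radial shell of the
  aggregate's surface (95th percentile of lipid radial distances, plus the
  shell tolerance) are binned into equal-area patches built from latitude
  bands split into longitude sectors — exactly equal areas with no
  external tessellation machinery. Reported are the fraction of patches
  containing at least one bead and the coefficient of variation of patch
  counts as the inhomogeneity summary.

## Equilibrium detection and reports

`run_experiment()` treats the trailing half of the logged series as the
equilibrium window and accepts it when linear fits of total energy and box
side against time have slopes statistically indistinguishable from zero at
95% confidence; otherwise the report is flagged (never silently dropped).
Observables are averaged over the trailing half of the stored frames, and
every average names its frame window. Because slow structural relaxations
(droplet compaction after the initial collapse) can still be under way in
the first part of that window, reports additionally carry an *end-state*
summary — the same observables averaged over the trailing quarter of the
trajectory, with its frame count named — which is the number to quote for
"what the run ended as". Reports are reproducible to the bit from the
preset and seed, and `analyze_trajectory()` recomputes them identically
from a stored trajectory.

## Problem sizes used by the test suite

The suite runs entirely at desk scale, chosen to exercise every code path
at meaningful physics: force-oracle comparisons on 100 random 20-50-bead
systems; NVE conservation over 10^4 steps on a ~290-bead solvated lipid
system; thermostat and barostat checks on a ~530-bead bulk water box over
2-3 x 10^4 steps; ring stability on one solvated Tween 20; and the full
desk self-assembly preset (~2100 beads, 2 x 10^5 steps). Full-scale runs
are deliberately excluded from the suite and scripted separately.

## Known limitations

* The shipped interaction table is Martini-*like*, not a verbatim published
  matrix; quantitative observables (densities, radii) carry the
  corresponding systematic uncertainty, while the qualitative phenomenology
  (collapse, liquid droplet, surfactant adsorption) is robust to it.
* No electrostatics, no polarizable water, no Q-type beads: adequate for
  these nonionic species only.
* The weak-coupling barostat yields correct mean densities but not correct
  volume fluctuations; compressibility-type observables are out of scope.
* Small aggregates (desk scale) have strong surface fluctuations: their
  asphericity is orders of magnitude above the near-zero full-scale
  values, and the Rg-based density reads low relative to large particles.
* Nominal time only; no rescaling toward physical dynamics.
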