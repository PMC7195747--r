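---
title: "Molecular fragment DPD with dpdfrag: models, parameters and design"
author: "dpdfrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular fragment DPD with dpdfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdfrag)
```

## The model

Dissipative particle dynamics (DPD) is a mesoscopic simulation method for
isothermal complex fluids. Particles are soft blobs; the total force on
particle *i* from particle *j* inside the interaction radius $r_c$ has
three parts:

$$
\mathbf F_{ij}^C = a_{ij}\,(1 - r/r_c)\,\hat{\mathbf e}_{ij}, \qquad
\mathbf F_{ij}^D = -\gamma\,(1 - r/r_c)^2 (\hat{\mathbf e}_{ij}\!\cdot\!
  \mathbf v_{ij})\,\hat{\mathbf e}_{ij}, \qquad
\mathbf F_{ij}^R = \sigma\,(1 - r/r_c)\,\theta_{ij}\,\Delta t^{-1/2}\,
  \hat{\mathbf e}_{ij},
$$

with the fluctuation–dissipation constraint $\sigma^2 = 2\gamma k_BT$
(the weight functions obey $w_D = w_R^2$). The dissipative and random
forces are pairwise antisymmetric, so together they act as a thermostat
that conserves total momentum exactly. All quantities are in reduced
units: $r_c = 1$, $k_BT = 1$, reference particle mass 1.

In the molecular-fragment variant, a particle is a small fragment
molecule of roughly 100 Da (a water bead, a methanol bead, an amino-acid
backbone bead, ...). Larger molecules are graphs of such fragments held
together by harmonic springs,
$\mathbf F = -k\,(r - r_0)\,\hat{\mathbf e}$, which stand in for covalent
connectivity. The physical size of $r_c$ follows from the smallest
fragment volume $V_{min}$ and the number density $\rho$:
$r_c = (\rho V_{min})^{1/3}$, e.g. $(3 \times 30\,\text{Å}^3)^{1/3}
\approx 4.48$ Å for a 30 Å³ water bead at $\rho = 3$.

## Parameters that matter

| parameter | default | unit | notes |
|---|---|---|---|
| $\rho$ (density) | 3 | particles / $r_c^3$ | links particle count to box volume |
| $a_{ij}$ | from the particle set | $k_BT/r_c$ | 25 for water-like self-repulsion at $\rho = 3$ |
| $\sigma$ | 3 | — | random force magnitude; $\gamma = \sigma^2/2k_BT = 4.5$ is derived, never set directly |
| $\Delta t$ | 0.04 | DPD time | the conventional operating point; see the artifact notes below |
| bond $k$, $r_0$ | 4, 1 $r_c$ | reduced | for SPICES connectivity; protein shape springs default $r_0$ to the start-geometry distance so the PDB-derived fold does not collapse |
| shell radius (neighbor census) | 1 $r_c$ | — | the "vicinity" of a particle |

## Integration

The engine uses the Groot–Warren modified velocity Verlet: positions are
advanced with the carried force, the dissipative force for the next force
evaluation is computed at the $\lambda$-predicted velocity
($\lambda = 0.5$ by default, integrator token `GWMVV`), and the velocity
is corrected with the mean of old and new forces. An alternative
(`SCMVV`) iterates the velocity/dissipative-force pair to
self-consistency (5 iterations).

Two numerical choices deserve explanation:

* **Counter-based pair noise.** $\theta_{ij}$ is not drawn from a
  sequential stream but computed as a hash of (seed, step, unordered pair
  index), uniform on $[-\sqrt 3, \sqrt 3]$ (zero mean, unit variance —
  the standard cheap replacement for a Gaussian in DPD). Trajectories are
  therefore independent of pair iteration order, of any parallel
  decomposition of the force loop, and of where a run was split for a
  restart: `run(n)` is bitwise identical to `run(k)` followed by
  `restart(n-k)`.
* **Restart-exact carried force.** Modified velocity Verlet carries the
  force evaluated at the predicted velocity across the step boundary. The
  final state of a run therefore stores the evaluation velocity alongside
  positions and velocities, so a restart recomputes exactly the force the
  uninterrupted run would have carried.

Runs have three phases: optional steepest-descent minimization of the
conservative + bond potential (per-step displacement capped at 0.05 $r_c$,
with backtracking halving so the energy series is monotonically
non-increasing), optional initial velocity-scaling steps (velocities are
rescaled after every step so the instantaneous $k_BT = 2E_{kin}/(3N-3)$
equals the target exactly), and free DPD dynamics. Coincident particle
pairs ($r = 0$) contribute potential energy but no force, since the
direction is undefined; this only occurs in deliberately degenerate
inputs. Divergence (non-finite coordinates or velocities) aborts with the
step number.

Movement constraints are applied after each step: fixed molecules have
their positions restored and velocities zeroed; caged molecules are
reflected at the cage walls (position mirrored, normal velocity negated,
before periodic wrapping); fixed-velocity molecules have their velocity
overwritten; kicked molecules receive a velocity increment every *n*-th
step. Electrostatics is off by default; when enabled it is a truncated
Coulomb force with linear charge smearing (finite at $r = 0$, tapered to
zero at a 3 $r_c$ cutoff, evaluated all-pairs because the cutoff exceeds
the cell size). Gravity adds $m\mathbf g$ per particle.

## Line notation and molecule building

Molecules are written in a SPICES-style line notation: `Me-MeOH` is
ethanol as two beads, `TriMeNP[START]-DMPN(MeAc-6Et)(MeAc-6Et[END])` is
the DMPC lipid (16 beads, 15 bonds; the bracketed tags mark the
orientation axis used for directed placement in vesicle shells). The
grammar subset implemented here: chains with `-`, parenthesized branches,
integer repeat prefixes (expanded as linear chains, matching the lipid
tail reading), `[START]`/`[END]` tags, bracketed integer backbone
indices, bracketed charges (`[+]`, `[-2]`), and ring closures via matched
`{n}` labels. The charge and ring-closure token syntax is this package's
dialect choice — the notation's full grammar is defined elsewhere and was
not available to verify against, so anything outside this subset is
rejected with a character position rather than guessed at. Multi-line
peptide notations are handled by stripping whitespace before parsing.
The writer emits a canonical depth-first form whose reparse is isomorphic
to the input; this canonical form is also what the round-trip tests pin
down.

Peptides are assembled residue-by-residue from the particle set's
amino-acid table, chained backbone-to-backbone; cyclic peptides add one
backbone ring closure, disulfides bond the cysteine side-chain beads.
Protonation is a step function: an acidic side chain is charged when
pH > pKa, a basic one when pH < pKa, with textbook pKa values shipped in
the toy fixture table. Fractional (Henderson–Hasselbalch) charges are
deliberately not used — DPD particle charges are integral, and a
population-averaged fractional charge would misrepresent the
electrostatics of any single molecule.

Proteins enter through PDB files: one bead per residue anchored at the
CA position (the standard coarse-grain anchor; the source format carries
no finer mapping), alternate locations resolved by occupancy, SSBOND
records turned into disulfides, REMARK 350 transforms applied on request
(the asymmetric unit is the default). Mutations change residue identity
only — coordinates and counts are untouched. Probe replacement relabels a
backbone bead for display/analysis while a probe-to-original map carried
with the model guarantees identical physical interactions. For start
configurations, side-chain beads are collapsed onto their backbone bead
(within a 0.01 $r_c$ jitter to avoid coincident pairs) and the whole
molecule is shrunk into a virtual sphere whose volume is the summed bead
volume; that sphere excludes all other placements, so the protein starts
slightly compressed and relaxes during simulation.

## Start configurations

`build_start_configuration` realizes a composition at exactly
$\mathrm{round}(\rho V)$ particles. Molecules are placed as randomly
oriented tubes (bond spacing 0.86 $r_c$, the mean equilibrium spring
length at the default parameters) at random positions; rejection sampling
honors compartment ownership and protein exclusion spheres, with a
$10^4$-attempt cap per molecule so a pathological overfill errors instead
of hanging. Overlapping spheres are resolved innermost-first — a point
belongs to the smallest enclosing compartment — which is what a
concentric-shell vesicle construction needs. Directed sphere contents are
rotated so the END→START axis is radial and the START/END midpoint sits
on the anchor; both tagged ends then lie exactly on the radial axis and
the inward/outward predicate holds by construction, for amphiphiles whose
START tag sits mid-graph just as for linear molecules. Layer compartments
may instead use simple cubic lattice placement (single-bead molecules
only), e.g. to build a solid wall together with molecule fixation. A
designated filler species absorbs the rounding remainder so the global
count is exact. Initial velocities are Maxwell–Boltzmann at the target
temperature with the net momentum removed — the standard choice.

Cyclic molecules are laid out on a circle (circumference = ring length),
other molecules along a straight main chain (the tree diameter path) with
branches adjacent to their attachment bead; a few sweeps of bond-length
relaxation then guarantee every bonded distance is at most
2 $\times$ the bond spacing, which keeps fresh configurations integrable
at $\Delta t = 0.04$.

## Trajectory evaluation

* $k_BT = 2E_{kin}/(3N-3)$ — three degrees of freedom are removed because
  the thermostat conserves momentum.
* Surface tension uses the virial route with a z-normal planar-interface
  convention, $\gamma = (L_z/2)\,(P_{zz} - (P_{xx}+P_{yy})/2)$; the
  factor $L_z/2$ accounts for the two interfaces of a periodic slab. The
  pressure tensor takes the kinetic term plus the conservative (pair +
  bond) virial. For a homogeneous fluid the estimate is zero within
  sampling noise, which the tests verify self-calibratingly (against the
  standard error measured from the same series, not a hand-picked bound).
* RDFs are minimum-image pair histograms normalized by ideal-gas shell
  counts; `r_max` beyond half the smallest periodic edge is refused.
* Radii of gyration unwrap each molecule by minimum image against its
  first bead before taking the center of mass — correct as long as a
  molecule does not span more than half the box.
* The nearest-neighbor analysis reports both readings of "vicinity":
  the single nearest neighbor per particle, and a shell census (mean
  count of each type within a configurable radius, default 1 $r_c$),
  aggregated by particle type or molecule type.

## What the synthetic data do and do not show

The test fixtures are fully synthetic: a 4-bead toy particle set with a
5-residue amino-acid table, a 3-residue CA-trace peptide PDB, uniform
random fluids, and a two-slab solute configuration. They exercise every
code path — parsing, building, integrating, evaluating — at the canonical
DPD operating point ($\rho = 3$, $a = 25$, $\sigma = 3$,
$\Delta t = 0.04$), and the physics checks (momentum conservation to
$10^{-10}$, thermostat accuracy to 3%, harmonic-dimer period to 1%,
ideal-gas $g(r) = 1 \pm 0.02$, force–potential consistency to $10^{-6}$)
pin the engine against closed forms and independent brute-force oracles.
They do not validate chemistry: the toy repulsion table is not a
parameterized force field, so the fixtures say nothing about whether a
particular lipid really forms a vesicle — that depends on a particle set
calibrated against experimental partitioning data, which users must
supply.

Two known discretization artifacts are worth stating. At
$\Delta t = 0.04$ the modified velocity Verlet thermostat equilibrates
slightly warm (measured $k_BT \approx 1.025$–1.03, the documented
behavior of this scheme; it vanishes as $\Delta t \to 0$). Second, the
pairwise thermostat imprints a small structure (a few percent) on the
pair correlations of an otherwise interaction-free fluid at finite
$\Delta t$; the ideal-gas RDF limit is therefore checked with all forces
off, where free streaming preserves the exact uniform distribution.

## Problem sizes used in the checks

The physics suites run the canonical fluid at $N = 3000$ for 6000 steps
(1000 equilibration + 5000 production), the ideal-gas RDF at $N = 3000$
over 101 frames, oracle equivalence at $N \le 200$, and the workflow
suites at $N$ of a few hundred. These sizes put every statistical
tolerance well above its sampling noise while keeping a full test cycle
around a minute on one core; larger systems change nothing structurally
(the force loop is linked-cell $O(N)$).

## Known limitations

No pressure coupling (NVT only), no angle or dihedral potentials, no
Ewald-type electrostatics (the smeared truncated Coulomb is a documented
pluggable stub), no GPU path. The job-definition text format is this
package's own; it does not read or write any external engine's command
files — the in-process engine stands where a kernel adapter would plug
in. Lattice placement is restricted to layers with single-bead molecules.
Orientation semantics for [START]/[END] are defined for spheres
(inward/outward) and fixed axes; other compartment kinds fall back to
random orientation.
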