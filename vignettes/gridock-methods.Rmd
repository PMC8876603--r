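---
title: "Grid-potential docking and screening triage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-potential docking and screening triage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridock)
```

gridock is a structure-based virtual-screening engine for rigid-receptor,
flexible-ligand docking, built around the workflow used to discover
small-molecule inhibitors of trypsin-like serine proteases such as
coagulation factor XIIa: precompute interaction potentials on a docking
cube, search ligand poses globally with a genetic algorithm, judge search
reliability by clustering independent runs, rescore shortlisted poses with
a thermodynamic-cycle binding enthalpy, and triage compounds through a
score/cluster/pocket/ADME funnel. This vignette documents the models, the
tunable parameters, and the numerical decisions, in the order the pipeline
runs them.

## Molecular model

Receptors are read from PDB. Preparation is rule-based at a fixed pH
(default 7.4): waters and undeclared hetero groups are removed, alternate
locations other than "A" are dropped, and the dominant protonation states
are assigned (Asp/Glu anionic, Lys/Arg cationic, His neutral at pH 7.4;
the switches flip at approximate side-chain pKa values if another pH is
requested). Polar hydrogens are added geometrically: 1.0 Å from the donor
heavy atom, directed away from the mean of its bonded neighbours, with
multi-proton donors fanned around that direction. Nonpolar hydrogens are
not added (a united-atom-style receptor). Protomer enumeration is *not*
performed; callers supply pre-enumerated protomers as separate ligand
records.

Parameterization is deliberately compact and data-driven: partial charges
for ligands come from the Gasteiger–Marsili iterative
electronegativity-equalization scheme (8 damped iterations, hybridization
inferred from bond orders, formal charges as seeds); receptor charges come
from a per-residue template (ionized side chains plus a reduced backbone
dipole). Van der Waals parameters are a per-element Lennard-Jones table
(homonuclear `rmin`, arithmetic/geometric Lorentz–Berthelot combination).
A full force-field atom typing such as MMFF94 can be substituted by
editing these tables; nothing downstream assumes their values.

Ligand topologies carry the bond graph, perceived rings (non-bridge edges
plus the shortest cycle through each), rotatable torsions (acyclic single
bonds between heavy atoms that each have a further heavy neighbour; amide
C–N excluded), and a reference 3-D conformer. A pose is (translation,
unit quaternion, torsion deltas); torsion values are *deltas relative to
the reference conformer*, applied in listed order about each rotatable
bond, followed by the rigid rotation about the reference centroid and the
translation. The identity pose is therefore exactly the identity map.
Pose RMSD is the plain all-atom root-mean-square deviation with no
superposition or symmetry correction — during clustering it must
distinguish placements, not conformers.

## Interaction grids

Three potential families are tabulated on a cubic grid (default edge 22 Å,
spacing 0.22 Å, i.e. 101 nodes per axis, centred on the geometric centre
of the native ligand when one is present):

* **Electrostatics**: Coulomb sum `332.06 q_i / (ε_in r)` per unit probe
  charge, interior dielectric `ε_in = 1`.
* **Van der Waals**: Lennard-Jones 12-6 per probe element.
* **Desolvation**: a generalized-Born self-energy penalty per unit charge
  squared. Each grid point is treated as a probe charge with intrinsic
  Born radius 1.5 Å whose effective radius is grown by
  Hawkins–Cramer–Truhlar pairwise descreening from the receptor atoms
  (descreening scale 0.8); the stored value is
  `166.03 (1/ε_in − 1/ε_solv)(1/ρ − 1/B) ≥ 0` with `ε_solv = 78.5`.
  Burying a charge therefore always costs energy, never pays. These
  dielectric constants are configuration defaults; the absolute scale of
  the resulting scores is specific to this package's force field.

Two numerical choices matter here. First, stored values are **softly
saturated** rather than hard-clamped: the map stores `g(E)` with
`g(E) = E` for `|E|` below a documented threshold (200 kcal/mol for
electrostatics, 50 for VdW) and a smooth tanh compression bounded by
±1000 kcal/mol above it. The same `g` is applied by the exact
(ungridded) evaluator, so grid and oracle agree even inside clashes,
while the search landscape stays finite and the physically meaningful
range is stored exactly.

Second, the VdW maps are stored in a **distance-like transform**: the
repulsive sum `A = Σ ε (rm/r)^12` as `A^(−1/12)` and the attractive sum
`B = Σ 2ε (rm/r)^6` as `B^(−1/6)`. Near an atom both transforms are
almost linear in distance, so interpolation in the transformed variable
is far more accurate than interpolation of the raw field, whose value
changes fourfold across one 0.22 Å spacing inside the repulsive wall. The
transforms are interpolated tricubically (Catmull–Rom, exact for cubics)
and the energy `E = A − B` is reconstructed and soft-capped per
evaluation point; electrostatic and desolvation maps, which are smooth at
the relevant scale, are interpolated trilinearly. With raw trilinear
storage the 95th-percentile disagreement against the direct pairwise
oracle on toy pockets is ~18%; with the transformed tricubic scheme it is
~0.6%, which is what makes the 1% fidelity target meaningful. Ligand
atoms outside the cube each add a configurable penalty (default +10^6
kcal/mol). Grids serialize to a versioned container (`write_grid` /
`read_grid`) with an exact round trip.

## Global search

The docking objective is the grid interaction energy plus the ligand's
internal strain: a torsion restraint `k_t (1 − cos Δφ)` per rotatable
torsion (`k_t` = 1.5 kcal/mol) plus the change in intramolecular
nonbonded energy (Coulomb + LJ over pairs more than three bonds apart)
relative to the reference conformer, so the reference pose has zero
strain. The reported *score* of a pose is the interaction component
alone, in kcal/mol (more negative is better); score and objective differ
by exactly the strain.

The genetic algorithm operates on the genome (translation, quaternion,
torsions): tournament selection (size 3), uniform crossover (rate 0.8),
per-gene Gaussian mutation (rate 0.05; σ = 0.5 Å translation, 0.1
quaternion perturbation with renormalization, 15° torsion), elitism of
one. Quaternions rather than Euler angles avoid gimbal artifacts; every
decoded quaternion is renormalized, so mutated genomes always encode
proper rotations. Production defaults mirror the full campaign scale
(population 30,000, 1,000 generations, 50 independent runs); all tests
and examples run a scaled-down configuration (population ~200, ~100
generations, ~10 runs) that recovers planted global minima on the toy
fixtures in well over 90% of cases. Per-run seeds are derived
deterministically from the master seed, making `dock()` bit-reproducible.

The run-best poses are clustered greedily in energy order: the
lowest-energy unassigned pose seeds a cluster and captures every
unassigned pose within the RMSD threshold (default 1 Å); ties break by
input order. Docking is flagged *successful* when the first cluster holds
at least `success_min_population` poses (default 10) — a reproducibility
proxy, not an accuracy claim. The screening funnel applies a separate,
stricter population cut (default > 12) because reliability for selection
is a harder requirement than reliability of the optimizer.

## Binding enthalpy

Rescoring uses the thermodynamic cycle
`ΔH_bind = ΔH_complex − (ΔH_protein + ΔH_ligand)`, with `ΔH_protein`
evaluated at the docking conformation, `ΔH_ligand` as the minimum backend
enthalpy over a supplied pool of unbound conformers (the pool is the
caller's choice; the campaign default is the reference conformer), and
`ΔH_complex` evaluated after local optimization of *all ligand atom
coordinates* in the rigid receptor (L-BFGS-B with analytic gradients,
projected-gradient tolerance 10⁻³ kcal/mol/Å, at most 2000 steps; the
result never has higher energy than the start).

Enthalpies come from a pluggable backend. The builtin force-field backend
uses the same Coulomb/LJ terms as the grid module, computed pairwise with
a CHARMM-style switching cutoff (10–12 Å), plus harmonic bond and 1–3
restraints that keep the ligand intact during optimization; the rigid
receptor's internal enthalpy is defined as the zero of the cycle, which
is exact because the identical conformation appears in the complex and
protein terms. The cutoff makes the backend size-consistent: at large
separation the interaction vanishes identically and `ΔH_bind → 0`. An
adapter for an external semiempirical quantum-chemistry program
(`external_backend`) is provided for installations that have one; all
shipped tests use the builtin backend, and no attempt is made to
reproduce the absolute enthalpies of any particular quantum method.

Interaction fingerprinting is geometric: hydrogen bonds require
donor–acceptor ≤ 3.5 Å and D–H⋯A ≥ 120°; π-stacks require ring-centroid
distance ≤ 5.5 Å and interplane angle ≤ 30° (parallel) or 60–90°
(T-shaped); a reactive proximity is flagged when a Michael-acceptor
β-carbon (α,β-unsaturated carbonyl substructure) comes within 4 Å of a
catalytic Ser/Cys nucleophile. Each hydrogen bond also carries an
empirical energy: a 12-10 radial profile with optimum −E₀ (default −5
kcal/mol) at 2.8 Å, an angular factor that vanishes at the 120°
detection boundary, and a smooth taper to zero at the distance cutoff, so
the energy is continuous and ≈0 at both detection boundaries. Bonds
weaker than −1 kcal/mol are labelled as not energetically real — a
classification threshold for reports, reflecting the observation that
geometrically plausible bonds can be energetically negligible.

## Screening funnel and descriptors

The funnel is order-fixed: stage 1 discards compounds scoring worse than
the cutoff (default −5.00 kcal/mol); stage 2 discards compounds whose
first cluster holds fewer than `min_first_cluster` poses (default 13,
i.e. "population > 12"); stage 3 discards poses that fail required-pocket
occupancy (a pocket counts as occupied when at least 5% of ligand heavy
atoms — at least one atom for typical ligands — are within 4.5 Å of its
residues); stage 4 ranks survivors by ΔH_bind. Every compound exits at
most once and the audit trail records where. Pocket definitions ship as
an editable YAML file with approximate factor XIIa subsites (S1 around
the Asp-189 specificity anchor, the catalytic His-57/Ser-195 region,
S2–S4); pocket occupancy is the declared computable proxy for
"visual pose inspection", which has no algorithmic definition.

Descriptors: monoisotopic [M+H]⁺ from a most-abundant-isotope mass table
plus the proton mass (1.007276 Da); logP is Wildman–Crippen and TPSA is
Ertl's method, both through OpenBabel; hydrogen-bond donors/acceptors use
the original Lipinski definitions (OH+NH, N+O); rotatable bonds are
acyclic single bonds between non-terminal heavy atoms with amide C–N
excluded. Lipinski violations and the Pfizer 3/75 flag (logP < 3 and
TPSA > 75 Å²) are computed from these values and are explicitly
model-dependent: a different logP model can move borderline compounds
across these thresholds, which is why reports carry the raw values
alongside the flags. The package ships the thirteen screening compounds
of the factor XIIa campaign as in-house SMILES encodings of their
published names; each encoding is verified against the published
molecular formula, and the computed [M+H]⁺ values match all thirteen
published HRMS calculations to within 0.001 Da.

## Synthetic fixtures and oracles

Every stage is testable without downloads. `make_toy_pocket()` builds a
concave hemispherical shell of neutral carbons with one negatively
charged oxygen anchor at the base — the minimal geometry that mimics a
buried specificity pocket with an electrostatic anchor. The companion
ligand is a small rigid chiral core with a cationic head complementary to
the anchor (branches differing in element and charge so that poses are
energetically distinguishable and mirror-image ambiguities cannot arise),
optionally extended by a kinked chain that contributes exactly one
rotatable torsion per added atom. Toy energies use the production
force-field terms — the fixtures validate the real code path, not a mock.

`brute_force_search()` enumerates a translation lattice (default 0.5 Å),
a quasi-uniform quaternion set (Halton low-discrepancy construction on
the 3-sphere, avoiding pole bias; ~140 orientations at 30° resolution)
and a torsion grid, for ligands with at most two torsions.
`make_planted_complex()` keeps the 16 best lattice basins, polishes each
in the continuum (Nelder–Mead over all pose degrees of freedom) and
plants the lowest — polishing several basins guards against the lattice
misranking energetically close orientations in the steep Coulomb well.
The planted energy is therefore a continuum minimum that the lattice
optimum brackets from above (by up to a few kcal/mol of lattice
resolution error); verification asserts the one-sided global-minimum
bound against the lattice oracle.

What the fixtures do *not* emulate: real protein chemistry beyond
concavity plus one anchor charge — no hydrogen-bond networks, no buried
waters, no receptor flexibility, no rugged multi-pocket landscapes.
Passing the recovery tests shows the search machinery finds well-defined
global minima reliably; it does not certify pose accuracy on real
proteins, for which redocking a crystallographic ligand (supported via
`read_receptor(native=)` + `dock()`) is the appropriate check.

## Problem sizes and determinism

The shipped tests use toy receptors of ~30 atoms, an 11 Å fixture cube at
the production 0.22 Å spacing, GA populations of 100–300 over 25–100
generations with 4–12 runs, and 20 planted complexes for the recovery
suite — sizes chosen so the full suite exercises every stage in a few
minutes on one core while leaving the production defaults at campaign
scale. All randomness flows from explicit seeds (master seed → per-run
seeds by a fixed derivation); `dock()`, campaigns and the fixture
generator are bit-reproducible on one platform for a fixed seed.

## Known limitations

* Score scale: scores are in kcal/mol on this package's force field; they
  are not numerically interchangeable with any external docking program's
  scores, and thresholds (e.g. the −5.00 kcal/mol cutoff) should be
  recalibrated when the parameterization changes.
* The receptor is rigid everywhere; implicit allowance for induced fit is
  limited to the soft saturation of repulsive potentials.
* Rule-based protonation and template charges are crude compared to
  dedicated pKa/charge machinery; the interfaces accept externally
  prepared structures for serious campaigns.
* The builtin enthalpy backend has no electronic structure: covalent
  chemistry (e.g. Michael addition to the catalytic serine) is only ever
  *flagged* geometrically, never simulated.
* `ΔH_ligand` depends on the supplied conformer pool; with only the
  reference conformer the ligand reorganization term is underestimated.
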