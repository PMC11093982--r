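---
title: "Methods: mechanistic analysis of a type III polyketide synthase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic analysis of a type III polyketide synthase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnsmech)
```

## The problem

Type III polyketide synthases (PKSs) are homodimeric enzymes that build
polyketide scaffolds by iteratively condensing malonyl-CoA-derived ketide
units onto an acyl-CoA starter bound to a catalytic cysteine. A quinolone
synthase of this family (a quinolone/acridone synthase, with catalytic
triad Cys164-His303-Asn336) can release its product after one ketide
insertion (quinolone) or carry on to three insertions and a larger ring
closure (acridone). Which path dominates is a question about *kinetic
barriers along each reaction step* and about *steric contact between the
growing intermediate and the active-site walls*.

qnsmech implements the computational workflow around that question as
reusable, tested components:

1. **Active-site cluster models** — truncated quantum-chemistry-style
   clusters centred on the catalytic cysteine.
2. **Constrained reaction-coordinate scans** — stepwise approach of the
   reacting atom pair with local relaxation, transition-state (TS)
   location and barrier/enthalpy extraction, over pluggable energy
   backends.
3. **Probe-based contact maps** — residue-substrate contact areas from
   Shrake-Rupley surfaces, classified minor/major, traced across
   reaction states, and perturbed by in-silico point mutations.
4. **Interface descriptors** — buried surface area, salt bridges,
   hydrogen bonds, nonbonded and polar contacts of the functional dimer.
5. **SPR kinetics** — 1:1 Langmuir sensorgram simulation and global
   fitting, with the equilibrium constant reported as the exact rate
   ratio K_D = k_d/k_a.
6. **Synthetic generators** — seeded fixtures with planted ground truth
   standing in for deposited crystal structures and raw sensorgrams.

## Cluster model construction

`extractActiveSite()` keeps every residue with at least one
non-hydrogen atom within the inclusion radius (default **12.0 Å**) of
the catalytic residue, whole residues only, the catalytic residue
always included.

Two choices here were genuinely open:

* **Sphere centre.** The protocol defines the sphere around "the
  catalytic cysteine" — a residue, not an atom. We therefore measure to
  *any* non-hydrogen atom of the catalytic residue by default; a
  single-atom variant (e.g. only SG) is available via the `centerAtom`
  argument for users who prefer the thiolate sulfur as the centre.
* **Granularity.** Residues are included whole (no atom-level
  clipping), matching the "set of all amino acids" reading and keeping
  capping chemistry simple.

Chain breaks created by the truncation are neutralised by
`neutralizeTermini()`: N-side breaks become neutral amines (H at
1.01 Å along the severed N-C direction) and C-side breaks become
aldehydes (H at 1.09 Å along the severed C-N direction), all caps with
zero formal charge. A cap landing within 0.8 Å of an existing atom is
displaced along the bisector with a warning; original coordinates are
never moved. Hydrogens present in the input are kept; none are ever
added to the protein itself, and no protonation-state prediction is
attempted.

`truncateLigand()` reduces a CoA-thioester ligand to its reactive
anchor — the thioethyl group plus acyl head — deleting the bulky
pantetheine/nucleotide moiety and capping severed valences with H at
1.09 Å. The exact atom content of the retained anchor is not tabulated
anywhere authoritative, so the keep-set is an explicit argument; the
synthetic pseudo-CoA records its anchor in the fixture manifest.

`assignMobility()` implements the rigidity convention of the scan
protocol: all backbone atoms rigid, all side chains rigid except those
participating directly in the reaction; mobile atoms are the ligand,
the reactive side chains and any caps. The protocol source does not
enumerate its mobile side chains, so the sensible default reactive set
is the catalytic triad (C164, H303, N336) plus user additions.

## Constrained scans and transition states

The reacting pair distance is driven through the schedule of
`scanSchedule()`: from the start distance in **0.4 Å** steps while more
than **1.0 Å** above the expected covalent distance, then **0.1 Å**
steps down to exactly the covalent target. Covalent targets default
from a covalent-radius sum table (C-S 1.81 Å, C-C 1.52 Å, C-N 1.47 Å)
when the user gives none.

At each scheduled distance `constrainedMinimize()` relaxes the mobile
atoms. The constraint is enforced by **exact projection** of the pair
onto the target distance inside the objective — not by a stiff spring —
so the constraint residual is at numerical precision regardless of any
force constant. Minimisation is quasi-Newton (BFGS) with numerical
gradients when the backend provides none, outer-iteration convergence
at 1e-4 kcal/mol energy decrease, and a 2000-iteration cap; none of
these numbers is prescribed by the protocol source, so they are
documented defaults. Rigid atoms are returned bit-identical.

The TS is the profile maximum, refined by one bisection pass at half
the fine step around the discrete maximum, followed by a single
parabolic-vertex evaluation through the three best points (the vertex
distance is actually minimised, never interpolated — every reported
energy is a computed one). The parabolic step was added because
sharply peaked barriers lose more than the grid resolution under the
bisection pass alone; with it the driver stays within 0.1 kcal/mol and
0.1 Å of dense-grid truth across the generator's full parameter range.
No eigenvector following or Hessian confirmation is attempted — the
discrete protocol does not describe any. Activation energy is E(TS) − E(first state); reaction
enthalpy is E(last) − E(first); both differences are invariant to
constant shifts of the backend energy.

### Energy backends

Production-grade semi-empirical engines are external programs. The
package treats them as a contract (`PESBackend`): any function mapping
coordinates to kcal/mol. `externalBackend()` adapts a command-line
engine (XYZ deck in, final heat of formation parsed out) and fails
cleanly when the executable is absent.

The built-in analytic backend (`toyBackend()`) makes the TS machinery
testable at desk scale: a two-state avoided crossing along the reacting
pair,

$$E(d) = \tfrac12\,(E_1+E_2) - \sqrt{\tfrac14 (E_1-E_2)^2 + W^2},$$

with a harmonic reactant channel, a Morse product channel, harmonic
tethers on the remaining mobile atoms and optional Lennard-Jones /
Coulomb terms (off by default so that the profile along the pair
distance is exactly the closed-form adiabat). With zero coupling the
expression reduces to min(E₁, E₂) with a cusp at the crossing; any
positive W yields a single smooth barrier whose true height and
position a dense grid over the closed form can measure independently.
`makeScanSystem()` fixes the coupling at max(2, 0.12·height) — scaled
with the height so the planted barrier stays a genuinely smooth single
maximum rather than degenerating toward a cusp — and then solves the
remaining shape parameters by nested monotone 1-D root finds: the
product-channel offset pins the barrier position (inner root, monotone),
and the reactant-channel stiffness sets the height at that position
(outer root, monotone). The solved system is verified against its own
dense grid and refused if it misses the request by more than
0.05 kcal/mol or 0.02 Å. Planted barriers are placed in the fine-step
window (within 1.0 Å of the covalent distance), which is where the
stepwise protocol is designed to resolve them.

What this does **not** show: agreement with any published activation
energy. Those numbers require the external semi-empirical engine and
hand-built intermediate geometries that are not deposited; the package
validates the *driver* (schedule, constrained relaxation, TS location,
barrier ordering) against analytic oracles instead, including the
qualitative ordering claim that later ketide insertions carry higher
barriers (planted 50 vs 40 kcal/mol systems must always rank
correctly).

## Contact maps and in-silico mutagenesis

`sampleSurface()` places deterministic golden-spiral points (default
**960/atom**; no RNG, so areas are exactly reproducible) on spheres of
radius (vdW + probe), probe **1.5 Å**, and removes points buried inside
any other atom's expanded sphere — the Shrake-Rupley construction. Van
der Waals radii come from a single hard-coded Bondi-style table; an
unknown element is an error, never a silent default.

`residueContactAreas()` assigns each exposed substrate surface point
lying within **3.0 Å** of a receptor atom to the residue owning the
*nearest* such atom; per-residue area is the sum of assigned point
weights. Two interpretive choices are documented and configurable:

* "Proximity < 3.0 Å" is read as *surface-point to receptor-atom-centre*
  distance (the probe-inflated surface is what the protocol measures);
* nearest-residue assignment prevents double counting and makes
  per-residue areas an exact partition of the contacted area. A
  count-for-every-residue-in-range variant is available via
  `assign = "all"`.

Classification is exact at the stated thresholds: zero area is none,
area < **0.5 Å²** is a minor contact, area ≥ 0.5 Å² is major.
`contactTrace()` tabulates these across labelled reaction states — the
nine-step quinolone/acridone sequence in the motivating analysis — and
`screenMutation()` reports per-state wild-type vs mutant areas with
sign-change flags (the TS-vs-product clash logic).

`applyMutation()` supports the mutation set expressible as terminal
heavy-atom deletions and/or one ideal-geometry methyl addition
(C-C 1.52 Å, direction anti to existing substituents): L→A, L→V, L→I,
S→G, S→T, N→S. N→S is the one stretch: Ser's hydroxyl has no Asn
counterpart, so the edit deletes the amide O/N and retypes the CG
carbon to a hydroxyl oxygen in place — a documented approximation that
keeps the contact geometry conservative. Mutations that add rings
(V→F) are rejected explicitly. No rotamer rebuilding or ΔΔG scoring is
attempted.

## Interface metrics

SASA uses the same Shrake-Rupley sampler with the **1.4 Å water
probe** — deliberately distinct from the 1.5 Å contact probe, because
published interface areas follow solvent conventions. Buried interface
area per protomer is (SASA(a) + SASA(b) − SASA(a∪b))/2.

Pair finders are plain O(n²) scans (fixture sizes make spatial indexing
unnecessary, and the brute-force form is its own specification):

* **salt bridges** — carboxylate O (Asp OD1/OD2, Glu OE1/OE2) to
  protonatable N (Lys NZ, Arg NE/NH1/NH2, His ND1/NE2) across the
  partition at ≤ 4.0 Å, His included as a potential cation;
* **hydrogen bonds** — N/O to N/O heavy pairs at ≤ 3.35 Å, with a
  D-H···A ≥ 90° angle requirement that activates automatically when
  hydrogens exist (deposited structures usually lack them, so the
  criterion is distance-only there);
* **nonbonded contacts** — heavy-atom pairs at ≤ 3.9 Å minus the
  hydrogen-bond pairs;
* **polar contacts** — ligand N/O/S to protein N/O/S at ≤ 3.5 Å.

The exact criteria behind published interface counts are not printed in
any one place; these defaults are therefore documented, configurable,
and validated against planted-count fixtures rather than against
deposited entries.

## SPR kinetics

The 1:1 Langmuir model: dR/dt = k_a·C·(R_max − R) − k_d·R during
association, giving R(t) = R_eq(1 − e^{−(k_aC+k_d)t}) with
R_eq = R_max·C/(C + K_D), and exponential decay at rate k_d after the
association phase. `fitLangmuir()` is a global nonlinear least-squares
fit of (k_a, k_d, R_max) on log scale across all concentrations of a
series, with one shared R_max (a single immobilised surface). K_D is
reported as k_d/k_a *exactly* — the ratio is computed from the fitted
rates, never fitted separately. Bulk-shift and drift terms are omitted:
the workflow assumes reference-channel subtraction has already been
applied. Single-concentration fits warn: k_a and R_max are nearly
confounded there.

No attempt is made to reproduce published K_D values — raw sensorgrams
are not deposited — so validation is recovery of planted truth:
noiseless fits recover parameters to ~1e-13 relative, and at 2% of
R_max Gaussian noise the median K_D error across 20 seeded replicates
stays well under 5%.

## Synthetic generators, and what they do not emulate

All fixtures are generated in code with idealised geometry: scripted
distances, canonical bond lengths, single-atom interaction partners
placed on a 12 Å grid. This is intentional — the fixtures exist to make
cutoff logic and oracles *exact* (a planted salt bridge at 3.95 Å is
inside the 4.0 Å salt-bridge cutoff and outside the 3.9 Å nonbonded
cutoff by construction), not to look like proteins. Consequences to
keep in mind:

* passing tests demonstrate correct geometry/cutoff/optimisation logic,
  not biological realism; real structures bring altlocs, insertion
  codes, missing atoms and crowded near-cutoff distances that the
  planted fixtures deliberately avoid (the reader handles the first
  three; near-cutoff behaviour is specified exactly and tested at the
  boundary);
* the toy receptor's catalytic residue is compact and its shell
  residues radially arranged so that each residue's minimum distance to
  the catalytic residue equals its scripted value exactly;
* the analytic energy surface has one barrier by construction; real
  semi-empirical surfaces have many stationary points, which is exactly
  why the production protocol steps coarsely first and finely near the
  covalent distance.

All randomness flows through one seeded generator (default seed
20240514); regeneration from the same seed is bit-reproducible, which
the suite asserts at file level.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties to the first in
  file — deterministic and conventional.
* Surface point exactly on a neighbour's expanded sphere: counted as
  buried (so two coincident identical atoms fully occlude each other).
* Empty selections are empty structures (logged), not errors; a missing
  substrate in a contact-trace state *is* an error naming the state.
* Scan schedules are capped at 500 points; a start distance equal to
  the covalent target is a single-point schedule.
* `classifyContact()` rejects negative areas; 0.5 Å² is major.
* The functional dimer of a one-molecule-per-asymmetric-unit crystal
  needs a symmetry operator; when the file carries REMARK 350 operators
  they are parsed, otherwise the user must supply a `Transform` — the
  operator is not guessable from the coordinates alone.

## Problem sizes

The shipped suite and the acceptance script run entirely from generated
fixtures at desk scale: ~40-residue toy receptors (~200 atoms),
718-atom dimer fixtures for the planted (6, 32, 318) interface
scenario, 10-14-point scan schedules over 8-atom reactive systems, and
5-concentration × 301-point sensorgram series with 20 noisy replicates.
These sizes make every oracle exhaustively computable while exercising
the same code paths a full-size structure would.

## Known limitations

* No Hessian/frequency confirmation of saddle points; TS position is
  grid-plus-bisection accurate only.
* No free-energy corrections; profile energies are backend potential
  energies.
* H-bond detection without hydrogens is distance-only; with hydrogens
  the angle test is a coarse 90° screen, not a full geometric H-bond
  definition.
* `applyMutation()` is limited to the deletion/methyl edit algebra;
  mutations that add rings or require rotamer search are out of scope.
* mmCIF support covers atom records and cell parameters; assembly
  operators are parsed from PDB REMARK 350 only.
* PDB fixed-width fields limit chain ids to one character on output.
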