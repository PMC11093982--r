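# qnsmech

Mechanistic analysis toolkit for type III polyketide synthase (PKS)
catalysis, built around the workflow used to dissect a plant
quinolone/acridone synthase: why does a homodimeric PKS with the
Cys-His-Asn catalytic triad stop after one ketide insertion (quinolone)
instead of three (acridone), and which active-site residues control
that choice?

The package is for structural bioinformaticians and enzymologists who
want the computational layer of that question as tested, reusable
pieces rather than one-off scripts:

* **Active-site cluster models** — every residue with a non-hydrogen
  atom within 12.0 Å of the catalytic cysteine, truncation breaks
  neutralised to amine/aldehyde caps, ligands reduced to their
  thioester anchor, backbone and non-reactive side chains held rigid.
* **Constrained reaction-coordinate scans** — the reacting atom pair is
  stepped from the start distance in 0.4 Å increments until within
  1.0 Å of the expected covalent distance, then in 0.1 Å increments,
  with local relaxation under an exactly projected distance constraint;
  the transition state (TS) is the profile maximum refined by one
  bisection pass. Activation energy E(TS) − E(reactant) and reaction
  enthalpy E(product) − E(reactant) come out per profile, and profiles
  rank by barrier. Energy backends are pluggable: an adapter wraps
  external command-line engines, and a built-in analytic
  avoided-crossing backend

  E(d) = (E₁+E₂)/2 − √((E₁−E₂)²/4 + W²)

  provides single-barrier systems whose exact height and position a
  dense grid can measure independently.
* **Contact maps and in-silico mutagenesis** — Shrake-Rupley probe
  surfaces (1.5 Å probe, 960 points/atom, deterministic golden-spiral
  sampling), per-residue substrate contact areas from points within
  3.0 Å of receptor atoms, classified none / minor (< 0.5 Å²) / major
  (≥ 0.5 Å²), traced across reaction states, and re-measured under
  point mutations (L→A/V/I, S→G, S→T, N→S) expressed as terminal-atom
  deletions plus ideal methyl additions.
* **Interface metrics** — buried dimer interface area
  ((SASA(a)+SASA(b)−SASA(ab))/2, 1.4 Å water probe), salt bridges
  (carboxylate O to Lys/Arg/His N ≤ 4.0 Å), hydrogen bonds (N/O-N/O
  ≤ 3.35 Å, angle-screened when hydrogens exist), nonbonded contacts
  (heavy pairs ≤ 3.9 Å minus H-bonds) and ligand polar contacts
  (≤ 3.5 Å).
* **SPR kinetics** — 1:1 Langmuir sensorgram simulation and global
  nonlinear least-squares fitting of (k_a, k_d, R_max) across analyte
  concentrations; K_D is reported as the exact ratio k_d/k_a.
* **Synthetic generators** — seeded fixtures with planted ground truth
  (inclusion distances, interaction counts, barrier heights, rate
  constants) so the whole pipeline is testable offline.

Structures are read from PDB/mmCIF (via bio3d) into S4 containers with
validity checks; symmetry mates for the functional dimer come from
REMARK 350 operators or an explicit `Transform`.

## Worked example

Plant a 40 kcal/mol barrier at 2.40 Å on an analytic active-site
system, scan it, and compare it with a 50 kcal/mol system — the
first-vs-later ketide insertion ordering:

```r
library(qnsmech)

sys <- makeScanSystem(barrierHeight = 40, barrierPosition = 2.4, seed = 1)
profile <- runScan(sys$model, sys$backend, sys$protocol, label = "k1")
profile
#> ReactionProfile 'k1' with 14 states
#>   TS at 2.400 A (state 8), activation 40.000 kcal/mol, enthalpy -24.569 kcal/mol

later <- makeScanSystem(barrierHeight = 50, barrierPosition = 2.4, seed = 2)
p2 <- runScan(later$model, later$backend, later$protocol, label = "k2")
compareProfiles(list(p2, profile))
#>   label activation_energy reaction_enthalpy
#> 1    k1                40         -24.56945
#> 2    k2                50         -21.28563
```

The 14 states are the constraint schedule (4.00 → 2.80 Å in 0.4 Å
steps, then 0.1 Å steps to the 1.81 Å C-S covalent distance); the
scanned barrier reproduces the planted truth to well under
0.1 kcal/mol, and the lower-barrier step ranks first.

Interface counting on a dimer fixture planted with the apo-interface
profile (6 salt bridges, 32 hydrogen bonds, 318 nonbonded contacts):

```r
dm <- makeDimerFixture(kBridges = 6, mHbonds = 32, pContacts = 318, seed = 1)
head(findSaltBridges(dm$a, dm$b), 3)
#>   resA resB dist
#> 1  A/1  B/1 3.95
#> 2  A/2  B/2 3.95
#> 3  A/3  B/3 3.95
```

Kinetic fitting of noisy synthetic sensorgrams (truth:
k_a = 2e5 1/(M s), k_d = 5e-3 1/s, R_max = 150 RU, so K_D = 25 nM):

```r
set <- makeSensorgramSet(ka = 2e5, kd = 5e-3, Rmax = 150, noiseSd = 3, seed = 1)
fitLangmuir(set$sensorgrams)
#> Langmuir 1:1 fit: ka = 2.015e+05 1/(M s), kd = 0.00501 1/s, Rmax = 149.7 RU
#>   KD = kd/ka = 2.487e-08 M; RSS = 1.351e+04 RU^2 over 1505 points
```

An end-to-end run (`runPipeline(readPipelineConfig())`) writes
model/profile/contact-trace/mutation reports with an embedded config
hash, seed and version; reruns with the same config and seed are
byte-identical. A thin command-line wrapper lives at
`inst/scripts/qnsmech.R` (`info`, `active-site`, `interface`,
`spr-fit`, `synth`, `run`).

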