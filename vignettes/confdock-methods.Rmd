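---
title: "Conformational diversity, ensemble docking and drug-likeness with confdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational diversity, ensemble docking and drug-likeness with confdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdock)
```

## The problem

Proteins deposited in the PDB many times over — small GTPases such as Rac1
are a canonical example — form an *ensemble of conformers*: the same chain
crystallized in different nucleotide states, complexes and space groups.
Before committing to a small-molecule campaign against a surface site, two
questions matter:

1. **Is the site itself rigid across the ensemble?** A pocket that deforms
   between conformers is a poor anchor for a single designed ligand.
2. **Does the ligand bind robustly to *every* conformer**, or only to the
   one structure it was designed against?

confdock implements the computational workflow for both questions, plus the
standard oral drug-likeness panel for the ligand, against any set of local
PDB files. Everything is testable without downloads through seeded
generators of synthetic conformer ensembles and toy protein–ligand
complexes with known ground truth.

## Conformational diversity analysis

### Superposition and the RMSD matrix

For two paired coordinate sets the optimal rigid superposition is computed
with the Kabsch algorithm: the rotation comes from the SVD of the 3×3
cross-covariance matrix of the mean-centred coordinates, with the smallest
singular vector flipped when the determinant would be −1, so the result is
always a proper rotation (no reflection). The minimized quantity is

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} \lVert a_i - (R b_i + t)\rVert^2}.$$

`pairwise_rmsd()` applies this to every unordered pair of C-alpha traces.
Residues are paired by author numbering (plus insertion code) where residue
names agree; when under half of the shorter trace pairs that way — different
entries of one protein frequently use different numbering — a global
sequence alignment with identity scoring and affine gaps takes over. Each
pair is superposed on *its own* common-residue set, so matrix entries can
rest on slightly different atom counts; the counts are kept in the
`n_common` attribute. The maximum-diversity pair is the arg-max over the
strict upper triangle, ties broken lexicographically (deterministic, with a
warning).

### Per-residue Z-scores

For the maximum pair, one **global** superposition over all common
C-alphas is performed and the per-residue displacement
$d_i = \lVert a_i - (R b_i + t) \rVert$ recorded. The profile is the
standardization

$$z_i = \frac{d_i - \bar d}{\sigma(d)},$$

with the **population** standard deviation (`ddof = 0`): the profile
describes a fixed, fully observed residue set, not a sample from a larger
population, so no degrees-of-freedom correction applies. Residues with
$z_i < 0$ move less than the average residue of that pair. A candidate
binding site is flagged `"low-mobility site"` only when **every** site
residue has $z_i < 0$.

Two numerical choices deserve note. A windowed or per-residue local fit
would measure internal rearrangement instead of displacement within the
globally aligned frame; the global fit is what the per-residue mobility
reading requires, and it has a known bias: very mobile loops pull the fit,
inflating the apparent displacement of a rigid core by a few tenths of an
Angstrom. The Z-score is invariant to the *ranking* consequences of that
inflation in practice (the tests assert rigid-core/loop separation, not
absolute core levels). Second, when all $d_i$ are numerically equal
(identical conformers), the SD is zero up to floating-point noise; below
$10^{-9}(1+\bar d)$ the profile degenerates to all-zero Z-scores with a
warning rather than amplifying rounding error.

## Ensemble docking

`ensemble_dock()` orchestrates `n_repeats` docking runs of one ligand
against every conformer through a pluggable engine contract, records the
**best (lowest) score of each run** — the standard per-run statistic of
stochastic docking engines — and aggregates:

* per conformer: mean, **sample** SD (`ddof = 1`, the convention behind
  "mean energy ± SD" error bars), and n;
* pooled over all runs: mean, SD and a relative-frequency histogram whose
  percentages sum to 100.

The seed of repeat $r$ against conformer $c$ is
`base_seed + (c − 1) · n_repeats + (r − 1)`: deterministic, disjoint across
runs, and reproducible — rerunning with the same base seed gives a
byte-identical affinity table for any deterministic engine.

### Engines

The **external adapter** writes receptor and ligand as PDBQT (charges
written as 0.000 — receptor preparation pipelines vary and belong upstream
of this package), invokes an AutoDock-Vina-dialect executable with the box
and seed, and parses `REMARK VINA RESULT` scores. Every failure mode
(missing executable, non-zero exit, unparseable output) is a distinct
error; a fallback engine is never substituted silently.

The **mock engine** exists because absolute scores from an external engine
are not reproducible across engine versions and receptor preparations, and
therefore carry no test value. It samples rigid-body placements inside the
box from a seeded RNG (uniform centroid, uniform random orientation via
quaternions) and scores with a transparent clash/contact potential over
protein–ligand heavy-atom pairs:

$$f(d) = \begin{cases} +10 & d < 2\,\text{Å} \\ -0.1 & 2 \le d \le 4\,\text{Å} \\ 0 & \text{otherwise,}\end{cases}$$

summed over pairs (lower is better). A `method = "grid"` mode enumerates an
exhaustive translational grid with no rotation, which an independent
brute-force scorer can verify exactly — that agreement, plus byte-identical
reruns, is what the orchestration tests assert. Mock scores are in
kcal/mol-like units only in the sense that the aggregation treats them as
such; they have no physical meaning.

The docking box is an axis-aligned cube (default edge 14 Å) centred exactly
on the C-alpha of a chosen residue — the geometry used to re-dock an
inhibitor at a binding-site hot spot.

## Interaction analysis

* `contact_residues()`: residues with any heavy atom within a cutoff
  (default 4.0 Å — the 2D interaction diagrams this feeds have no published
  criterion, so the cutoff is configurable) of any ligand heavy atom,
  sorted by minimum distance.
* `detect_hbonds()`: donor and acceptor are N/O heavy atoms with
  donor–acceptor distance ≤ 3.5 Å; when an explicit hydrogen sits on the
  donor, the D–H⋯A angle must be ≥ 120°. Crystal structures usually lack
  hydrogens, so without one the criterion is distance-only and flagged as
  such. Protein carbonyl/carboxylate oxygens are never treated as donors;
  protein donors are nitrogens and hydroxyl-bearing side-chain oxygens.
* `pose_rmsd()` / `substructure_rmsd()`: binding-mode comparison across two
  receptor conformers. The receptors are superposed first and that
  transform applied to the second pose; the ligand is **not** re-fitted, so
  a rigid shift of the whole binding mode shows up in full (a fitted
  variant sits behind `fit = TRUE`). Per-group RMSDs over a named
  substructure map (e.g. `ring_A`, `ring_B`, `guanidine`) obey the exact
  partition identity $\mathrm{RMSD}^2 = \sum_g n_g\,\mathrm{RMSD}_g^2 / \sum_g n_g$
  when the groups partition the heavy atoms — asserted to $10^{-9}$ in the
  tests.

## Drug-likeness panel

`druglikeness()` computes, from a SMILES or SDF input parsed through
OpenBabel/ChemmineR:

* **MW** from standard atomic weights including implicit hydrogens;
* **HBD/HBA** in the Lipinski convention: donors are N/O atoms bearing ≥ 1
  hydrogen (heavy atoms counted, not hydrogens), acceptors are all N + O;
* **rotatable bonds**: single, non-ring bonds between two non-terminal
  heavy atoms, excluding amide-like C–N bonds where the carbon carries a
  double bond to O or N. The extension of the amide exclusion to
  amidine/guanidine C–N reflects their comparable rotational hindrance from
  partial double-bond character (for a diaryl guanidine it is also what the
  count of three printed for such inhibitors implies — a plain
  non-terminal/non-ring rule would count the guanidine C–N link too);
* **TPSA** by Ertl fragment contributions over N/O environments (the
  original N/O parameterization; S and P contribute zero). An N/O
  environment missing from the table is an error, never silently zero;
* **logP** by Wildman–Crippen atomic contributions (`"crippen"`, default),
  with OpenBabel's model available as `"openbabel"`. The method is recorded
  in the output because atomic-contribution logP is strongly
  method-dependent — for the bundled guanidine inhibitor fixture the two
  methods straddle a full log unit — and no published panel states its
  method. The Crippen typing was validated atom-by-atom against an
  independent implementation of the same published table across a 58-
  molecule battery spanning the covered chemistry (frozen whole-molecule
  values remain in the test suite).

Verdicts: Lipinski pass iff MW ≤ 500 ∧ logP ≤ 5 ∧ HBD ≤ 5 ∧ HBA ≤ 10;
Veber pass iff rotatable bonds ≤ 10 ∧ TPSA ≤ 140 Å². Both are recomputable
from the reported fields.

Known limitations of the chemistry layer: aromaticity is perceived by a
simplified Hückel count on 5–7-membered rings of the Kekulé structure
(fused bicyclics and quinoid exclusion work; exotic mesoionic systems are
out of scope); charged nitro groups keep their charged-form TPSA rather
than the neutralized special case; no tautomer or pKa modelling.

## Structure I/O policies

PDB parsing (via bio3d) applies three deterministic policies: only the
first `MODEL` of multi-model files is read (the workflow targets crystal
structures); alternate locations resolve to the highest-occupancy altloc,
ties to `"A"`; waters and HETATM groups never enter C-alpha traces but stay
available, flagged, for interaction analysis. Malformed coordinate fields
fail with the offending line number. Ligand poses are accepted as PDB,
PDBQT (charge/type columns parsed but unused beyond element + coordinates)
or SDF V2000.

## The synthetic-data generators

`generate_ensemble()` emulates the statistical structure that the
diversity analysis assumes: a common chain observed repeatedly with
heterogeneous per-residue mobility. The base chain is a self-avoiding
random walk with the physical 3.8 Å C-alpha spacing; conformer $k$ adds
independent isotropic Gaussian noise with per-residue SD
$\sigma_i \cdot s_k$ and then a random global rotation + translation, which
carries no signal and must be removed by superposition. Defaults — 100
residues, rigid core at $\sigma = 0.1$ Å, two mobile loops at
$\sigma = 2$ Å, TRP at residue 56 — mirror a small GTPase-sized chain with
sub-Angstrom core variability and loop excursions of a few Angstrom, the
regime crystal ensembles of flexible signalling proteins show. With
distinct per-conformer scales $s_k$ the expected maximum-diversity pair is
the two largest scales, since the expected squared displacement of a pair
is proportional to $s_a^2 + s_b^2$; the recovery tests use scales
(0.1, 0.3, 0.6, 1.4, 2.2), whose top pair is separated from the runner-up
by ~20% in expected RMSD — far outside the few-percent sampling noise of an
RMSD over 60 residues.

What the generator does **not** emulate: correlated or hinge-like domain
motions, sequence heterogeneity (chains are poly-ALA with one TRP), side
chains, crystal-packing artefacts, and missing density. Passing tests
therefore demonstrate the statistical machinery — superposition, ranking,
standardization, aggregation — not robustness to every pathology of real
crystallographic data.

`generate_complex()` plants exact interaction geometry: one ligand carbon
at the requested distance above each pocket residue of a straight-line
chain (neighbouring residues are provably outside the 4 Å cutoff by
construction), and optionally a donor–H⋯acceptor triple realizing a
requested distance and angle exactly (the hydrogen position is solved, not
approximated). Ground-truth tables accompany every output.

## Problem sizes and verification scale

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep the full suite under two minutes on one CPU
while leaving comfortable statistical margins: ensembles of 40–100 residues
and 2–30 conformers; 20-seed recovery batteries; 100 random superposition
instances against a brute-force rotational search (multi-start BFGS over
axis-angle space, agreement within $10^{-4}$ Å); a 5-conformer × 100-repeat
mock docking run (500 placements per run) for determinism and aggregation
checks, verified against streaming (Welford) and two-pass references to
$10^{-12}$. The per-residue mobility recovery check averages displacements
over all pairs of a 12-conformer ensemble — roughly the scale at which
real crystal ensembles support stable per-residue statistics.

One check requires real data: the C-alpha RMSD of the published
maximum-diversity conformer pair of Rac1 (entries 1E96 chain A vs 2YIN
chain C, expected ≈ 2.5 Å; accepted 2.2–2.8 Å since the original
superposition protocol is not fully specified). The corresponding test
fetches the two entries when a network or local copy is available and
fails otherwise; it is the only test with an external data dependency.

## Decisions on open interface questions

* Multi-chain entries: the chain must be user-specified per entry
  (`"PDBID:CHAIN"` labels); no heuristic picks one.
* Substructure group names are user-supplied labels; the bundled fixtures
  follow the ring-A = trifluoromethylphenyl convention.
* Docking scores are reported as signed kcal/mol throughout; the package
  never reinterprets whether a more negative mean is "better" across
  receptor variants.
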