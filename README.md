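# confdock

Conformational-diversity analysis and ensemble docking for drug-binding
sites, with a drug-likeness panel for the ligand.

## What problem this solves

A protein that has been crystallized many times — small Rho-family GTPases
such as Rac1 are the motivating case — exists in the PDB as an *ensemble of
conformers*. Before targeting a surface site (for Rac1, the GEF-interaction
hot spot around tryptophan 56) with a small molecule, two questions need
quantitative answers:

1. **Is the binding site in a rigid or mobile region of the ensemble?**
   confdock superposes every conformer pair (Kabsch, SVD with reflection
   correction), builds the pairwise C-alpha RMSD matrix, finds the
   maximum-diversity pair, and standardizes its per-residue displacements
   into Z-scores: for residue *i*,

   z_i = (d_i − mean(d)) / sd_pop(d),

   where d_i is the C-alpha displacement after one global superposition.
   Residues with z < 0 move less than average; a candidate site is reported
   "low-mobility" only when *all* its residues satisfy z < 0.

2. **Does the ligand bind every conformer, not just one?** confdock
   orchestrates repeat docking of one ligand against each conformer through
   a pluggable engine contract (an AutoDock-Vina-dialect adapter for real
   engines; a deterministic seeded mock engine for testing), records the
   best score per run, and aggregates mean ± sample SD per conformer plus
   the pooled affinity distribution. Docked poses are compared across
   conformers by in-frame RMSD (receptors superposed, ligand *not*
   re-fitted), overall and per named substructure, and protein–ligand
   contacts and hydrogen bonds are detected with explicit geometric
   criteria.

For the ligand itself, `druglikeness()` computes the oral drug-likeness
panel — molecular weight, Crippen logP (method-tagged), Lipinski H-bond
donors/acceptors, rotatable bonds, Ertl TPSA — with Lipinski and Veber
verdicts.

Synthetic-data generators (`generate_ensemble()`, `generate_complex()`)
produce seeded conformer ensembles with known per-residue mobility and toy
complexes with planted contacts/H-bonds, so the entire pipeline is testable
offline with ground truth.

## Worked example

```r
library(confdock)

## Drug-likeness of a diaryl guanidine inhibitor (drawn from its SMILES)
prof <- druglikeness(parse_molecule("NC(=Nc1ccccc1C(F)(F)F)Nc1cc(C)cc(C)c1"))
prof
#> <druglikeness> C16H16F3N3  MW 307.32 g/mol  logP 4.38 (crippen)  HBD 2  HBA 3  RotB 3  TPSA 50.41 A^2
#>   Lipinski: pass   Veber: pass
```

MW 307.32 g/mol, two donors, three acceptors, three rotatable bonds and
TPSA 50.41 Å² — all inside the Lipinski and Veber limits (MW ≤ 500,
logP ≤ 5, HBD ≤ 5, HBA ≤ 10; rotatable ≤ 10, TPSA ≤ 140 Å²).

```r
## A synthetic 5-conformer ensemble with a rigid core, two mobile loops
## (residues 15-25 and 40-50) and increasing per-conformer displacement
ens <- generate_ensemble(
  n_residues = 60, n_conformers = 5,
  sigma = list(core = 0.1, loop = 2, loop_ranges = list(c(15, 25), c(40, 50))),
  conformer_scale = c(0.1, 0.3, 0.6, 1.4, 2.2),
  site_residue = 56, seed = 1
)

m <- pairwise_rmsd(ens$traces)
m
#> <rmsd_matrix> pairwise C-alpha RMSD (Angstrom), 5 conformers
#>        conf01 conf02 conf03 conf04 conf05
#> conf01  0.000  0.697  1.427  3.193  4.386
#> conf02  0.697  0.000  1.532  3.301  4.552
#> conf03  1.427  1.532  0.000  3.284  4.288
#> conf04  3.193  3.301  3.284  0.000  5.512
#> conf05  4.386  4.552  4.288  5.512  0.000

(pair <- max_diversity_pair(m))
#> # A tibble: 1 × 3
#>   conformer_a conformer_b  rmsd
#>   <chr>       <chr>       <dbl>
#> 1 conf04      conf05       5.51
```

The two most-displaced conformers (scales 1.4 and 2.2) are recovered as the
maximum-diversity pair. Is a site on the rigid core flexible?

```r
zprof <- zscore_profile(ens$traces[[pair$conformer_a]],
                        ens$traces[[pair$conformer_b]])
glance(site_flexibility(zprof, c(5, 10, 30, 55, 56)))
#> # A tibble: 1 × 4
#>   n_site fraction_below_zero verdict           n_missing
#>    <int>               <dbl> <chr>                 <int>
#> 1      5                   1 low-mobility site         0
```

All five site residues sit below the ensemble-average mobility (z < 0):
the generator's rigid core is correctly read as a low-mobility site.
`autoplot(zprof, site = c(5, 10, 30, 55, 56))` draws the profile with the
site highlighted.

```r
## Ensemble docking with the deterministic mock engine
lig <- new_ligand_pose(tibble::tibble(
  atom_name = c("C1", "C2", "C3", "N1", "O1"),
  element   = c("C", "C", "C", "N", "O"),
  x = c(0, 1.5, -0.7, -0.7, 0.8),
  y = c(0, 0, 1.3, -1.3, 0.9),
  z = c(0, 0, 0.3, 0.3, -1.1)))

tab <- ensemble_dock(ens$structures, lig,
                     function(s) docking_box(s, "A", 56, edge = 14),
                     engine = list(type = "mock", n_samples = 200),
                     n_repeats = 20, base_seed = 1)
tab
#> <affinity_table> 100 runs over 5 conformers (20 repeats, base seed 1)
#>   pooled: -1.562 +/- 0.239 kcal/mol (n = 100)
#> # A tibble: 5 × 4
#>   conformer  mean    sd     n
#>   <chr>     <dbl> <dbl> <int>
#> 1 conf01    -1.57 0.227    20
#> 2 conf02    -1.47 0.172    20
#> 3 conf03    -1.58 0.293    20
#> 4 conf04    -1.55 0.219    20
#> 5 conf05    -1.64 0.258    20
```

Per-conformer means within a fraction of an SD of each other: the mock
ligand "binds" all five conformers comparably (mock scores are unitless
stand-ins; swap in `engine = list(type = "external", executable =
"/path/to/vina")` for real energies). `tidy(tab)` returns the per-conformer
table, `glance(tab)` the pooled summary, `autoplot(tab)` the affinity
histogram, and `affinity_histogram(tab)` the binned relative frequencies.

Workflow wrappers `run_diversity()`, `run_dock()` and `run_druglikeness()`
write TSV/JSON reports from a config list or YAML file; a thin command-line
wrapper lives at `inst/cli/confdock.R` with subcommands `diversity`,
`dock`, `pose-compare`, `contacts`, `druglikeness` and `simulate`.

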