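# pepint

Dissecting a protein–peptide interface and grading docked peptide models,
in plain R.

`pepint` was built around a concrete structural-biology problem: the
ubiquitin-like protein Hub1 binds the spliceosomal protein Snu66 through a
flat, largely featureless interface whose binding energy concentrates in a
few hot-spot residues. Turning that peptide interaction into a
small-molecule starting point requires a chain of computational steps that
this package implements as one tested pipeline:

* **Interface characterization** — Shrake–Rupley solvent-accessible surface
  area (SASA) with a deterministic spiral quadrature, buried surface area
  (BSA = ASA_isolated − ASA_complex), interface residue/atom calling,
  an atomic-solvation-parameter estimate of the solvation free-energy gain
  ΔᵢG = Σ σ(class)·ΔASA, and geometric hydrogen-bond / salt-bridge
  detection.
* **Interaction network** — cross-interface contact typing (apolar-carbon
  hydrophobic contacts plus polar bonds), per-receptor-residue interaction
  counts, a network cooperativity score
  `S = Σ_c w(kind)·(1 + β·deg(c))` in which spatially clustered contacts
  reinforce each other, and hot-spot ranking with the top-k share of all
  interactions.
* **CAPRI-style model quality** — Kabsch superposition, fraction of native
  contacts (Fnat), ligand backbone RMSD after receptor fit (LRMS),
  interface backbone RMSD (IRMS), the standard
  Acceptable/Medium/High threshold ladder, and cohort summaries
  (fraction of models below an RMSD threshold).
* **Peptide design** — truncation-scan libraries: stepwise N-terminal
  deletions, then C-terminal deletions, then one double-end truncation.
* **Pharmacophore** — typed features (hydrophobic side-chain centroids,
  positive-ionizable charged-group centroids) with the full pairwise
  distance matrix.
* **Synthetic data** — ideal-helix toy complexes with ground-truth
  contacts, rigid-body decoys with closed-form RMSD, and synthetic
  interaction tables, so everything above is testable offline.

## Worked example

```r
library(pepint)

# the published truncation series of the Snu66 parent peptide
lib <- truncation_library("LSIEETNEIREKLGMKPI")
lib$entries[lib$entries$id %in% c("Peptide-11", "Peptide-14"), ]
#>            id   sequence length scheme
#> 12 Peptide-11    IREKLGM      7  C-del
#> 15 Peptide-14 TNEIREKLGM     10 double

# hot spots from the packaged per-residue interaction counts
tab5 <- load_fixture("table5")
rank_hotspots(tab5, k = 5)
#> hotspot_ranking: top 5 = VAL-30, ASP-26, ASP-22, LEU-33, LYS-29
#>   top-k fraction: 68 %

aggregate_scores(tab5, paste0("Peptide-", 8:13))$mean
#> [1] 4.925

# docked-model accuracy cohorts (CA representation, IRMS < 1 A)
tab4 <- load_fixture("table4")
summarize_cohort(tab4$CA_Lowest, 1.0, "lowest")
#> cohort lowest: 10/15 below 1.00 A (67%)

# a toy complex end to end: interface, decoy, CAPRI grade
toy <- make_toy_complex(toy_complex_params("LSIEETNEIREKLGMKPI",
                                           receptor_size = 36, gap = 3))
interface_report(toy$model, toy$spec, n_points = 240)
#> interface_report (probe 1.4 A, BSA floor 0.01 A^2)
#>   receptor [A]: 6/36/36 interface/surface/total residues; interface area 79.0 A^2; solvation gain -1.26 kcal/mol
#>   ligand   [C]: 2/18/18 interface/surface/total residues; interface area 102.7 A^2; solvation gain -0.79 kcal/mol

decoy <- make_decoy(toy$model, decoy_spec(translation = c(0.5, 0.5, 0)),
                    toy$spec)
capri_assess(decoy, toy$model, toy$spec)
#> capri_result: Fnat 1.000  LRMS 0.71 A  IRMS 0.23 A  -> High (backbone)
```

The interface residue counts read: six of the receptor slab's 36 residues
bury surface against the peptide, and two helix residues carry most of the
peptide side's burial; both solvation gains are negative, i.e. the contact
is hydrophobic. The decoy shifted by |t| = 0.71 Å keeps all native
contacts and grades "High" on the Fnat/LRMS/IRMS ladder.

## Command line

A thin CLI wraps the same API (installed at `inst/cli/pepint`):

```sh
pepint design --sequence LSIEETNEIREKLGMKPI --out library.tsv
pepint synth toy --sequence LSIEETNEIR --out toy.pdb
pepint interface toy.pdb --receptor A --ligand C --out interface.tsv
pepint hotspots --fixture table5 -k 5
pepint capri --model decoy.pdb --reference toy.pdb --receptor A --ligand C
pepint run --config pipeline.cfg
```

Exit codes: 0 ok, 2 validation error, 3 runtime error.

## Scope notes

The package does not run docking simulations, does not recompute the
proprietary interaction scores that the packaged count table came from,
and does not model interface P-values; see `vignettes/methods.Rmd` for the
model assumptions, parameter defaults and known limitations.
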