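Package: pepint
Title: Protein-Peptide Interface Analysis, Docking Model Quality and
    Pharmacophore Derivation
Version: 0.1.0
Authors@R:
    person("pepint", "developers", email = "pepint@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect a protein-peptide interface from PDB
    coordinates: Shrake-Rupley solvent-accessible surface area and buried
    surface area with interface residue calling, an atomic-solvation-parameter
    estimate of the solvation free-energy gain, geometric hydrogen-bond and
    salt-bridge detection, cross-interface contact typing with per-residue
    interaction counts, a network-style cooperativity score and hot-spot
    ranking, CAPRI-style model quality assessment (Fnat, ligand and interface
    backbone RMSD, quality classes), truncation peptide library design, and
    typed-feature pharmacophore models with centroid distance matrices.
    Includes deterministic synthetic-data generators (ideal-helix toy
    complexes, rigid-body docking decoys with closed-form RMSD, synthetic
    interaction tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
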