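---
title: "Methods: interface analysis, model grading and pharmacophore derivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface analysis, model grading and pharmacophore derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pepint` implements the computational arc that takes a receptor–peptide
crystal structure to a small-molecule pharmacophore hypothesis: interface
characterization, truncation-library design, docked-model quality
assessment, interaction-network hot-spot analysis, and feature extraction.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The structural data model

A `structure_model` is a flat atom table keyed on
`(chain, res_seq, icode)` with PDB numbering preserved verbatim — the
Hub1/Snu66 literature mixes peptide-local and construct numbering, so the
package never renumbers and leaves any mapping between schemes to the
user. Hydrogens are dropped on reading by default: every geometric
criterion here (contacts, polar bonds, SASA) is heavy-atom based.
Alternate locations collapse to the highest-occupancy conformer (ties to
file order). Van der Waals radii come from a single packaged Bondi-style
table (`vdw_radii()`, C 1.70 / N 1.55 / O 1.52 / S 1.80 Å), used
consistently by SASA and contact geometry; unknown elements fall back to
1.70 Å with a warning. Coordinates are Å throughout.

## Solvent-accessible and buried surface area

SASA uses the Shrake–Rupley construction: points on the extended sphere
of radius `r + probe` of each atom are rejected when inside a neighbour's
extended sphere; the accessible fraction scales the analytic sphere area.

* **Probe**: 1.4 Å (water) by default.
* **Quadrature**: a deterministic generalized-spiral point set,
  default 960 points/atom, minimum 32. Determinism makes every
  SASA-derived number exactly reproducible and testable against analytic
  spheres: a lone atom's ASA error is bounded by one point's area,
  `4π(r+p)²/n`.
* **BSA**: per-residue `ASA_isolated − ASA_complex`, computed from one
  complex-wide SASA pass and one pass per isolated side. The conservation
  identity (chain interface area = Σ residue BSA) is exact by
  construction and asserted at 1e-6 relative tolerance.
* **Interface calls**: a residue is interface when `BSA > 0.01 Å²`
  (suppressing quadrature dust), an atom when its own ΔASA > 0, a surface
  residue when `ASA_isolated > 0`.

One numerical consequence is worth stating plainly: the quadrature sphere
is fixed in space, so rotating a complex realigns points against
neighbours and moves per-residue BSA by up to a few point-areas
(measured ≈2 Å²/residue at 240 points on the toy complex). Interface
*sets* are therefore rigid-motion invariant only outside that noise band;
the tests assert exact agreement for residues buried beyond it and
confine any flips to grazing residues within it. Users comparing
interface calls across superpositions should either fix the frame or
raise `n_points`.

## Solvation free-energy gain

The ΔᵢG estimate is an atomic-solvation-parameter model:
`ΔᵢG(residue) = Σ_atoms σ(class) × ΔASA(atom)`, with burial-gain signs —
apolar carbon/sulfur negative (−0.016 / −0.021 kcal·mol⁻¹·Å⁻²), polar N/O
positive (+0.006), charged side-chain nitrogens/oxygens most costly
(+0.050 / +0.024). The magnitudes follow the classic octanol/water
transfer scale; they are **not** calibrated against any interface server,
and only the sign structure (negative = hydrophobically driven interface)
and relative ordering are asserted anywhere in the package. The
isolated-chain "solvation energy" reported in chain totals is the energy
that would be gained were the whole exposed surface buried — a convenient,
always-comparable summary, not a folding energy.

## Polar bonds

Hydrogen bonds are called on heavy atoms: donor–acceptor distance
≤ 3.5 Å, and, when the donor's antecedent atom is present (e.g. CA for
backbone N, CZ for Arg NH1), antecedent–donor–acceptor angle ≥ 90°; the
angle test is skipped when the antecedent is unresolvable rather than
guessed. Salt bridges pair Arg/Lys/His side-chain nitrogens with Asp/Glu
side-chain oxygens at ≤ 4.0 Å. Only cross-interface pairs are reported,
and a close Arg–Asp pair legitimately appears as both hydrogen bond and
salt bridge, as interface servers also report it.

## Contact typing, cooperativity and hot spots

A hydrophobic contact is a pair of apolar carbons across the interface at
≤ 4.5 Å. "Apolar carbon" is a packaged per-residue table (e.g. Leu
CB/CG/CD1/CD2 in; Ser CB and other polar-adjacent carbons out), so an
all-polar contact at the same distance counts zero by construction.

The cooperativity score is a deliberately simple, documented surrogate for
proprietary interaction-network scores:
`S = Σ_c w(kind)·(1 + β·deg(c))` with weights 0.5 (hydrophobic), 1.0
(hydrogen bond), 1.5 (salt bridge), neighbour radius 6 Å on receptor
atoms and bonus β = 0.1. It rewards spatially clustered networks over
scattered ones with the same contact count, is zero on the empty set, and
never increases when a contact is removed. The packaged per-residue count
table ships with its published scores precisely because the original
scoring function is closed-source: those printed values feed the
aggregation operations and are never claimed to be reproduced by the
surrogate.

Hot-spot ranking sorts receptor residues by total count (ties to the
lower residue number, so output order is deterministic) and reports the
top-k share of all counts to the nearest integer percent. On the packaged
table the top five residues carry 68% of all interactions — the number the
pharmacophore rests on.

## CAPRI-style model quality

* **Fnat**: native contacts are cross-interface residue pairs with any
  heavy-atom distance ≤ 5 Å in the reference (the standard convention;
  the source analysis does not state its cutoff); Fnat is the preserved
  fraction in the model, with no superposition. A reference without
  contacts yields an explicit undefined flag, never 0.
* **LRMS**: superpose on receptor backbone (N, CA, C, O), report ligand
  backbone RMSD. A pure ligand translation by `t` gives exactly `|t|`.
* **IRMS**: interface residues are those within 10 Å of the partner in
  the reference; superpose on their backbone atoms and report that set's
  RMSD.
* **CA-only models**: the backbone silently reduces to the CA
  intersection, recorded in `atoms_used`, and Fnat carries a
  low-confidence flag instead of being forced to zero — coarse-grained
  models can still share residue-level contacts under an any-atom rule,
  and the package exposes both facts rather than guessing which the
  original assessment intended.
* **Classification** requires *all three* conditions of a class
  (Acceptable < 5.0 / < 2.0 / > 0.2; Medium < 2.0 / < 1.0 / > 0.5;
  High < 1.0 / < 0.5 / > 0.8); per-criterion flags are returned so users
  wanting a two-of-three reading can apply it themselves. The ladder is
  monotone: improving one metric never lowers the class.
* **Cohort summaries** use strict `<` and half-up integer rounding —
  the convention that makes 2/15 → 13% and 10/15 → 67%.

Superposition is Kabsch via SVD with the determinant correction;
degenerate (collinear) point sets and n < 3 are errors. The test suite
checks it against an independent quaternion-grid minimizer to 1e-3 Å.

## Truncation-library design

From a parent sequence: phase 1 deletes one N-terminal residue at a time
down to length 10; phase 2 continues from that peptide deleting
C-terminal residues down to length 5; phase 3 adds one double-end
truncation (5 N-terminal + 3 C-terminal residues removed from the
parent). The stopping lengths and double cut are read off the published
library and exposed as parameters. Where the narrative description of the
scheme and the printed library disagree about which peptide is the double
truncation, the printed library is taken as ground truth. The
preconditions admit the degenerate one-peptide case
(`n_stop = c_stop = 1`), which the strict reading of the scheme would
forbid but its own minimal example requires.

## Pharmacophore features

Hydrophobic features average all side-chain heavy atoms (CB onward — CB
carries the side-chain direction); positive-ionizable features average
the charged-group atoms (Arg NE+CZ+NH1+NH2, Lys NZ, His ND1+NE2), falling
back to coarse side-chain pseudo-atoms when a reduced representation
lacks them. Anchors are user-supplied (`chain:res_seq:kind`): the source
analysis is ambiguous about whether features sit on peptide anchors or
receptor hot spots, so the package does not guess. Published feature
distances (5.6/4.9/4.7/8.7 Å) name four distances for four features
without naming pairs; the package reports the full 6-entry matrix and
asserts no match to those numbers. The matrix is rigid-motion invariant
and independent of anchor order (features sort canonically).

## Synthetic data: what it emulates, what it does not

* **Toy complexes**: an ideal α-helix (φ = −57°, ψ = −47°, the textbook
  helix the designed peptides are meant to retain) with idealized CB and
  single side-chain centroid pseudo-atoms (`SC1`), over a rigid
  glycine/alanine slab. The helix is spun about its long axis so its
  apolar face points at the slab — without that, an arbitrary rotation can
  leave zero hydrophobic contacts and nothing downstream to analyse. The
  closest-approach gap is met exactly (root-finding to machine
  precision), and the ground-truth contact list is by construction.
* **Decoys**: rigid-body rotation about the ligand centroid plus
  translation. No internal flexibility — flexible docking is out of
  scope, and rigidity is what buys closed-form oracles (pure translation
  ⇒ LRMS = |t| to 1e-9).
* **Interaction tables**: seeded Poisson / negative-binomial / uniform
  count matrices for exercising ranking and aggregation.

A green test on these toys establishes that the *operations* implement
their definitions — contact enumeration, RMSD algebra, conservation
identities, invariances. It does not establish realism: toy side chains
have no rotamers, the slab is not a protein fold, packing densities and
polar-bond geometry are idealized, and SASA magnitudes on toys say
nothing about crystal-structure interfaces. Structure-derived claims
about the real Hub1/Snu66 complex are checked only against the deposited
entry itself, which must be downloaded at run time (the package does not
redistribute PDB data); in offline environments that acceptance check
reports failure rather than silently passing.

## Known limitations

* The SASA/BSA implementation is a surrogate for interface servers whose
  exact radii, quadrature and interface criteria are unpublished;
  residue counts on real structures can differ near the calling
  threshold, and solvation magnitudes are not comparable.
* Interface p-values, docking itself, ensemble clustering and the
  proprietary interaction scoring are all out of scope by design.
* π-stacking and cation-π interactions are not typed; contact typing is
  distance-geometric, with no energetics.
* The pipeline treats a single static structure; no conformational
  ensembles or flexibility.
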