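# Packaged chemistry tables shared by the geometry modules: van der Waals
# radii, apolar-carbon definitions, hydrogen-bond donor/acceptor topology and
# atomic solvation parameters. All values live here (not in external data
# files) so they are versioned with the code and trivially auditable.

#' Van der Waals radii
#'
#' Bondi-style van der Waals radii (in Angstrom) used for SASA and contact
#' geometry. The table is deliberately small: protein heavy atoms plus the
#' elements that occur in common ligands. Unknown elements fall back to
#' `default` with a per-atom warning at parse time.
#'
#' @return Named numeric vector of radii in Angstrom, with a `default` entry.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, MG = 1.73, CA = 2.31, MN = 1.97, FE = 1.94, "NA" = 2.27,
    K = 2.75, default = 1.70
  )
}

std_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

aa1_to_aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

backbone_atom_names <- c("N", "CA", "C", "O")

# Apolar (aliphatic/aromatic) carbons per residue: carbons not bonded to N or
# O. Ser CB, Lys CE, Arg CD, Tyr CZ and similar polar-adjacent carbons are
# excluded. "SC1" is the side-chain centroid pseudo-atom emitted by the toy
# generator; it inherits the hydrophobicity of its residue.
apolar_carbons <- list(
  ALA = c("CB", "SC1"),
  VAL = c("CB", "CG1", "CG2", "SC1"),
  LEU = c("CB", "CG", "CD1", "CD2", "SC1"),
  ILE = c("CB", "CG1", "CG2", "CD1", "SC1"),
  MET = c("CB", "CG", "CE", "SC1"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "SC1"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2", "SC1"),
  PRO = c("CB", "CG", "SC1"),
  GLY = character(0),
  SER = character(0),
  THR = c("CG2"),
  CYS = c("CB"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  ASN = c("CB"),
  GLN = c("CB", "CG"),
  ASP = c("CB"),
  GLU = c("CB", "CG"),
  LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"),
  HIS = c("CB")
)

is_apolar_carbon <- function(res_name, atom_name) {
  tab <- apolar_carbons[res_name]
  mapply(function(t, a) !is.null(t) && a %in% t, tab, atom_name,
         USE.NAMES = FALSE)
}

# Hydrogen-bond donors on heavy atoms: donor atom plus the antecedent heavy
# atom used for the antecedent-donor-acceptor angle test. Backbone amide N
# (antecedent CA) is a donor for every residue except proline.
side_chain_donors <- list(
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  LYS = list(NZ = "CE"),
  HIS = list(ND1 = "CG", NE2 = "CD2"),
  TRP = list(NE1 = "CD1"),
  ASN = list(ND2 = "CG"),
  GLN = list(NE2 = "CD"),
  SER = list(OG = "CB"),
  THR = list(OG1 = "CB"),
  TYR = list(OH = "CZ")
)

# Hydrogen-bond acceptors on heavy atoms (backbone carbonyl O and OXT are
# acceptors for every residue).
side_chain_acceptors <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = c("OD1"),
  GLN = c("OE1"),
  SER = c("OG"),
  THR = c("OG1"),
  TYR = c("OH"),
  HIS = c("ND1", "NE2")
)

# Salt-bridge partners: basic side-chain nitrogens vs acidic side-chain
# oxygens.
basic_n_atoms <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")
)
acidic_o_atoms <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

#' Atomic solvation parameters
#'
#' Coefficients (kcal/mol per Angstrom^2 of buried area) for the
#' atomic-solvation-parameter estimate of the solvation free-energy gain on
#' complex formation. The magnitudes follow the classic
#' octanol/water-transfer scale; the signs are expressed as *burial gains*:
#' burying apolar carbon or sulfur is favourable (negative), burying polar
#' nitrogen/oxygen costs energy (positive), and charged groups cost most.
#' Only the sign structure and relative ordering are meaningful; absolute
#' values are not calibrated against any particular interface server.
#'
#' @return Named numeric vector: `C`, `N`, `O`, `S`, `N_charged`,
#'   `O_charged`.
#' @export
solvation_params <- function() {
  c(C = -0.016, N = 0.006, O = 0.006, S = -0.021,
    N_charged = 0.050, O_charged = 0.024)
}

charged_atom_class <- function(res_name, atom_name, element) {
  cls <- element
  cls[!cls %in% c("C", "N", "O", "S")] <- "C"  # treat exotic atoms as apolar
  charged_n <- (res_name == "ARG" & atom_name %in% c("NE", "NH1", "NH2")) |
    (res_name == "LYS" & atom_name == "NZ")
  charged_o <- (res_name == "ASP" & atom_name %in% c("OD1", "OD2")) |
    (res_name == "GLU" & atom_name %in% c("OE1", "OE2"))
  cls[charged_n] <- "N_charged"
  cls[charged_o] <- "O_charged"
  cls
}

# Charged-group atoms used for positive-ionizable pharmacophore centroids.
positive_group_atoms <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")
)
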