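# Core structural data model. A structure_model is a flat atom table (one
# row per atom) plus a source identifier; the flat layout keeps all geometry
# vectorised while (chain, res_seq, icode) keys preserve the PDB hierarchy.

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `serial`, `chain`, `res_seq`,
#'   `icode`, `res_name`, `atom_name`, `alt_loc`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `vdw`, `het`.
#' @param source_id Free-text identifier (e.g. a PDB code or file name).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, source_id = "") {
  required <- c("serial", "chain", "res_seq", "icode", "res_name",
                "atom_name", "alt_loc", "element", "x", "y", "z",
                "occupancy", "vdw", "het")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite coordinates in atom table")
    }
    if (!all(atoms$vdw > 0)) stop("non-positive van der Waals radius")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  chains <- unique(a$chain)
  cat("structure_model", if (nzchar(x$source_id)) paste0("[", x$source_id, "]"),
      "\n  chains:", paste(chains, collapse = ", "),
      "\n  residues:", nrow(unique(a[, c("chain", "res_seq", "icode")])),
      "  atoms:", nrow(a), "\n")
  invisible(x)
}

#' Number of residues per chain
#' @param model A `structure_model`.
#' @return Named integer vector (names are chain identifiers).
#' @export
chain_sizes <- function(model) {
  a <- model$atoms
  key <- unique(a[, c("chain", "res_seq", "icode")])
  tab <- table(key$chain)
  setNames(as.integer(tab), names(tab))
}

#' Receptor/ligand chain specification
#'
#' @param receptor_chains,ligand_chains Character vectors of chain
#'   identifiers. Must be non-empty and disjoint.
#' @return Object of class `complex_spec`.
#' @export
#' @examples
#' complex_spec("A", "C")
complex_spec <- function(receptor_chains, ligand_chains) {
  receptor_chains <- as.character(receptor_chains)
  ligand_chains <- as.character(ligand_chains)
  if (length(receptor_chains) == 0 || length(ligand_chains) == 0) {
    stop("receptor and ligand chain sets must be non-empty")
  }
  if (length(intersect(receptor_chains, ligand_chains)) > 0) {
    stop("receptor and ligand chain sets overlap: ",
         paste(intersect(receptor_chains, ligand_chains), collapse = ", "))
  }
  structure(list(receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains),
            class = "complex_spec")
}

infer_element <- function(atom_name, col1314 = NULL) {
  nm <- toupper(trimws(atom_name))
  # strip leading digits (e.g. "1HB" remnants) and primes
  stripped <- sub("^[0-9']+", "", nm)
  el <- substr(stripped, 1, 1)
  # two-letter elements occasionally seen in protein files
  two <- substr(stripped, 1, 2)
  el[two %in% c("SE", "CL", "BR", "ZN", "MG", "MN", "FE", "NA")] <-
    two[two %in% c("SE", "CL", "BR", "ZN", "MG", "MN", "FE", "NA")]
  # 4-character names starting with H-like pattern are hydrogens
  el[grepl("^[0-9]*H", nm)] <- "H"
  el
}

assign_radii <- function(element, radii = vdw_radii(), warn = TRUE) {
  r <- unname(radii[element])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (warn) {
      warning("no van der Waals radius for element(s) ",
              paste(unique(element[unknown]), collapse = ", "),
              "; using default ", radii[["default"]], call. = FALSE)
    }
    r[unknown] <- radii[["default"]]
  }
  r
}

#' Read a PDB file into a structure model
#'
#' Parses fixed-column ATOM/HETATM records. Alternate locations are resolved
#' to the highest-occupancy conformer (ties break to the first in file
#' order), waters are always dropped, and hydrogens and HETATM records are
#' dropped unless requested. Elements missing from columns 77-78 are
#' inferred from the atom-name columns; van der Waals radii are assigned
#' from [vdw_radii()].
#'
#' @param path Path to a PDB file.
#' @param keep_hydrogens Keep hydrogen atoms (default `FALSE`).
#' @param keep_het Keep non-water HETATM records (default `FALSE`).
#' @param radii Named radius table, see [vdw_radii()].
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE, keep_het = FALSE,
                     radii = vdw_radii()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  rec <- trimws(rec[keep])
  if (length(lines) == 0) stop("no ATOM records in ", path)

  f <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    atom_name = f(13, 16),
    alt_loc = f(17, 17),
    res_name = f(18, 20),
    chain = f(22, 22),
    res_seq = suppressWarnings(as.integer(f(23, 26))),
    icode = f(27, 27),
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = f(77, 78),
    het = rec == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  no_el <- !nzchar(atoms$element)
  atoms$element[no_el] <- infer_element(atoms$atom_name[no_el])
  atoms$element <- toupper(atoms$element)

  atoms <- atoms[!(atoms$res_name %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_het) atoms <- atoms[!atoms$het, , drop = FALSE]
  if (!keep_hydrogens) {
    atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no atoms left after filtering in ", path)

  # altloc resolution: highest occupancy wins, ties go to file order
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$atom_name,
               sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  atoms <- atoms[order(atoms$serial, na.last = TRUE), , drop = FALSE]
  atoms$alt_loc <- ""

  atoms$vdw <- assign_radii(atoms$element, radii)
  atoms$res_name <- toupper(atoms$res_name)
  atoms <- atoms[, c("serial", "chain", "res_seq", "icode", "res_name",
                     "atom_name", "alt_loc", "element", "x", "y", "z",
                     "occupancy", "vdw", "het")]
  structure_model(atoms, source_id = basename(path))
}

#' Write a structure model to a PDB file
#'
#' Emits standard fixed-column ATOM/HETATM records (coordinates to three
#' decimals), a TER record after each chain, and END.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  if (nrow(a) == 0) stop("cannot write an empty structure model")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
    stop("coordinates exceed the PDB fixed-column field width")
  }
  fmt_name <- function(nm) {
    # atom names of 1-3 chars start in column 14; 4-char names in column 13
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (a$het[i]) "HETATM" else "ATOM", serial %% 100000L,
        fmt_name(a$atom_name[i]), substr(a$alt_loc[i], 1, 1),
        a$res_name[i], a$chain[i], a$res_seq[i] %% 10000L,
        substr(a$icode[i], 1, 1), a$x[i], a$y[i], a$z[i],
        a$occupancy[i], 0, a$element[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d%1s",
                              serial %% 100000L, a$res_name[last], ch,
                              a$res_seq[last] %% 10000L,
                              substr(a$icode[last], 1, 1)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms as a coordinate matrix with an index map
#'
#' @param model A `structure_model`.
#' @param chains Chain identifiers to select, or `NULL` for all chains.
#' @param atom_names Either a character vector of atom names, or one of the
#'   shorthands `"heavy"` (all non-hydrogen atoms), `"backbone"`
#'   (N, CA, C, O) or `"all"`.
#' @return List with `coords` (n x 3 matrix) and `map` (data.frame with
#'   `chain`, `res_seq`, `icode`, `res_name`, `atom_name` per row).
#' @export
select_atoms <- function(model, chains = NULL, atom_names = "heavy") {
  a <- model$atoms
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(a$chain))
    if (length(absent) > 0) {
      stop("chain(s) not in model: ", paste(absent, collapse = ", "))
    }
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  sel <- if (identical(atom_names, "heavy")) {
    !a$element %in% c("H", "D")
  } else if (identical(atom_names, "backbone")) {
    a$atom_name %in% backbone_atom_names & !a$het
  } else if (identical(atom_names, "all")) {
    rep(TRUE, nrow(a))
  } else {
    a$atom_name %in% atom_names
  }
  a <- a[sel, , drop = FALSE]
  if (nrow(a) == 0) {
    stop("empty atom selection (chains = ",
         paste(if (is.null(chains)) "*" else chains, collapse = ","),
         ", atoms = ", paste(atom_names, collapse = ","), ")")
  }
  list(coords = as.matrix(a[, c("x", "y", "z")]),
       map = a[, c("chain", "res_seq", "icode", "res_name", "atom_name")])
}

# Restrict a model to a chain subset (keeps atom order).
subset_chains <- function(model, chains) {
  a <- model$atoms
  absent <- setdiff(chains, unique(a$chain))
  if (length(absent) > 0) {
    stop("chain(s) not in model: ", paste(absent, collapse = ", "))
  }
  structure_model(a[a$chain %in% chains, , drop = FALSE], model$source_id)
}

# Apply a rigid transform x -> x R + t to all atoms (or a chain subset).
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0),
                            chains = NULL) {
  a <- model$atoms
  idx <- if (is.null(chains)) seq_len(nrow(a)) else which(a$chain %in% chains)
  xyz <- as.matrix(a[idx, c("x", "y", "z")]) %*% rotation
  a$x[idx] <- xyz[, 1] + translation[1]
  a$y[idx] <- xyz[, 2] + translation[2]
  a$z[idx] <- xyz[, 3] + translation[3]
  structure_model(a, model$source_id)
}

residue_key <- function(df) paste(df$chain, df$res_seq, df$icode, sep = "\r")

res_label <- function(res_name, res_seq) {
  paste0(toupper(res_name), "-", res_seq)
}
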