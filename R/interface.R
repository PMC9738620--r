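# Interface characterization: per-residue ASA/BSA with interface calling,
# chain-level totals, an atomic-solvation-parameter energy model, and
# geometric hydrogen-bond / salt-bridge detection.

#' Characterize a receptor-ligand interface
#'
#' Computes solvent-accessible surface area for each side in isolation and
#' in the complex, derives per-residue buried surface area
#' (BSA = ASA_isolated - ASA_complex), flags interface residues
#' (BSA > `bsa_floor`) and interface atoms (per-atom dASA > 0), and
#' aggregates chain-level totals: atom/residue counts for interface, surface
#' and total, interface area (sum of BSA), total area, and
#' solvation-energy estimates from [solvation_params()].
#'
#' @param model A `structure_model` containing both chain sets.
#' @param spec A [complex_spec()].
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param bsa_floor Minimum per-residue BSA (Angstrom^2) to call an
#'   interface residue; the small default suppresses quadrature noise.
#' @param n_points Quadrature points per atom for [compute_sasa()].
#' @param asp_table Atomic solvation parameters, see [solvation_params()].
#' @return Object of class `interface_report`: list with `per_atom`,
#'   `per_residue`, `per_chain` data.frames plus `spec` and `params`.
#' @export
interface_report <- function(model, spec, probe = 1.4, bsa_floor = 0.01,
                             n_points = 960, asp_table = solvation_params()) {
  stopifnot(inherits(spec, "complex_spec"))
  if (length(intersect(spec$receptor_chains, spec$ligand_chains)) > 0) {
    stop("receptor and ligand chain sets overlap")
  }
  both <- c(spec$receptor_chains, spec$ligand_chains)
  complex_model <- subset_chains(model, both)
  asa_cplx <- compute_sasa(complex_model, probe, n_points)

  sides <- list(receptor = spec$receptor_chains, ligand = spec$ligand_chains)
  per_atom_list <- list()
  for (side in names(sides)) {
    iso <- subset_chains(model, sides[[side]])
    asa_iso <- compute_sasa(iso, probe, n_points)
    at <- iso$atoms
    at$side <- side
    at$asa_isolated <- as.numeric(asa_iso)
    # align complex ASA rows by atom identity
    key_iso <- paste(at$chain, at$res_seq, at$icode, at$atom_name, sep = "\r")
    ca <- complex_model$atoms
    key_cplx <- paste(ca$chain, ca$res_seq, ca$icode, ca$atom_name, sep = "\r")
    at$asa_complex <- as.numeric(asa_cplx)[match(key_iso, key_cplx)]
    per_atom_list[[side]] <- at
  }
  per_atom <- do.call(rbind, per_atom_list)
  rownames(per_atom) <- NULL
  per_atom$d_asa <- per_atom$asa_isolated - per_atom$asa_complex
  per_atom$is_interface <- per_atom$d_asa > 1e-9
  per_atom$is_surface <- per_atom$asa_isolated > 0
  per_atom$asp_class <- charged_atom_class(per_atom$res_name,
                                           per_atom$atom_name,
                                           per_atom$element)
  sigma <- asp_table[per_atom$asp_class]
  missing_cls <- is.na(sigma)
  if (any(missing_cls)) {
    warning("no solvation parameter for class(es) ",
            paste(unique(per_atom$asp_class[missing_cls]), collapse = ", "),
            "; contributing zero", call. = FALSE)
    sigma[missing_cls] <- 0
  }
  per_atom$sigma <- as.numeric(sigma)
  per_atom$delta_i_g <- per_atom$sigma * per_atom$d_asa

  key <- residue_key(per_atom)
  first <- !duplicated(key)
  per_residue <- per_atom[first, c("side", "chain", "res_seq", "icode",
                                   "res_name")]
  per_residue$asa_isolated <- as.numeric(tapply(per_atom$asa_isolated, key,
                                                sum)[key[first]])
  per_residue$asa_complex <- as.numeric(tapply(per_atom$asa_complex, key,
                                               sum)[key[first]])
  per_residue$bsa <- per_residue$asa_isolated - per_residue$asa_complex
  per_residue$is_interface <- per_residue$bsa > bsa_floor
  per_residue$is_surface <- per_residue$asa_isolated > 0
  per_residue$delta_i_g <- as.numeric(tapply(per_atom$delta_i_g, key,
                                             sum)[key[first]])
  rownames(per_residue) <- NULL

  per_chain <- do.call(rbind, lapply(names(sides), function(side) {
    at <- per_atom[per_atom$side == side, ]
    rs <- per_residue[per_residue$side == side, ]
    data.frame(
      side = side,
      chains = paste(sides[[side]], collapse = ","),
      n_interface_atoms = sum(at$is_interface),
      n_surface_atoms = sum(at$is_surface),
      n_total_atoms = nrow(at),
      n_interface_residues = sum(rs$is_interface),
      n_surface_residues = sum(rs$is_surface),
      n_total_residues = nrow(rs),
      interface_area = sum(rs$bsa),
      total_area = sum(rs$asa_isolated),
      # energy that would be gained were the whole exposed surface buried;
      # negative for the apolar-dominated surfaces typical of proteins
      solvation_isolated = sum(at$sigma * at$asa_isolated),
      solvation_gain = sum(rs$delta_i_g),
      stringsAsFactors = FALSE)
  }))
  rownames(per_chain) <- NULL

  structure(list(per_atom = per_atom, per_residue = per_residue,
                 per_chain = per_chain, spec = spec,
                 params = list(probe = probe, bsa_floor = bsa_floor,
                               n_points = n_points, asp_table = asp_table)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report (probe", x$params$probe, "A, BSA floor",
      x$params$bsa_floor, "A^2)\n")
  pc <- x$per_chain
  for (i in seq_len(nrow(pc))) {
    cat(sprintf(
      "  %-8s [%s]: %d/%d/%d interface/surface/total residues; interface area %.1f A^2; solvation gain %.2f kcal/mol\n",
      pc$side[i], pc$chains[i], pc$n_interface_residues[i],
      pc$n_surface_residues[i], pc$n_total_residues[i],
      pc$interface_area[i], pc$solvation_gain[i]))
  }
  invisible(x)
}

#' Solvation free-energy gain from buried surface area
#'
#' Recomputes the atomic-solvation-parameter energy of an
#' [interface_report()] under a (possibly different) parameter table:
#' per-residue gain is the sum over atoms of sigma(class) x dASA(atom);
#' chain gain is the sum over residues. Apolar classes carry negative
#' coefficients (burial gain), polar and charged classes positive ones.
#'
#' @param report An `interface_report`.
#' @param asp_table Named coefficient vector, see [solvation_params()].
#' @return List with `per_residue` (data.frame incl. `delta_i_g`) and
#'   `per_chain` (named numeric vector of chain gains, kcal/mol).
#' @export
solvation_gain <- function(report, asp_table = solvation_params()) {
  stopifnot(inherits(report, "interface_report"))
  at <- report$per_atom
  sigma <- asp_table[at$asp_class]
  if (any(is.na(sigma))) {
    warning("no solvation parameter for class(es) ",
            paste(unique(at$asp_class[is.na(sigma)]), collapse = ", "),
            "; contributing zero", call. = FALSE)
    sigma[is.na(sigma)] <- 0
  }
  gain_atom <- as.numeric(sigma) * at$d_asa
  key <- residue_key(at)
  first <- !duplicated(key)
  per_residue <- at[first, c("side", "chain", "res_seq", "icode", "res_name")]
  per_residue$delta_i_g <- as.numeric(tapply(gain_atom, key, sum)[key[first]])
  rownames(per_residue) <- NULL
  per_chain <- tapply(per_residue$delta_i_g, per_residue$side, sum)
  list(per_residue = per_residue,
       per_chain = setNames(as.numeric(per_chain), names(per_chain)))
}

#' Detect cross-interface hydrogen bonds and salt bridges
#'
#' Geometric criteria on heavy atoms: a hydrogen bond requires a donor
#' heavy atom within `hb_dist` of an acceptor and, when the donor's
#' antecedent atom is resolvable, an antecedent-donor-acceptor angle of at
#' least `hb_angle`; a salt bridge requires a basic side-chain nitrogen
#' (Arg/Lys/His) within `sb_dist` of an acidic side-chain oxygen (Asp/Glu).
#' Only pairs spanning the receptor/ligand interface are reported; a pair
#' may appear both as hydrogen bond and salt bridge.
#'
#' @param model A `structure_model`.
#' @param spec A [complex_spec()].
#' @param hb_dist Donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param hb_angle Minimum antecedent-donor-acceptor angle in degrees
#'   (default 90; skipped when the antecedent atom is absent).
#' @param sb_dist Salt-bridge N-O distance cutoff (Angstrom, default 4.0).
#' @return data.frame of class `polar_bonds`: `kind`, donor and acceptor
#'   atom references, `distance`, `angle` (NA when unresolvable).
#' @export
detect_polar_bonds <- function(model, spec, hb_dist = 3.5, hb_angle = 90,
                               sb_dist = 4.0) {
  stopifnot(inherits(spec, "complex_spec"))
  a <- model$atoms
  a$row <- seq_len(nrow(a))
  side_of <- function(ch) {
    ifelse(ch %in% spec$receptor_chains, "receptor",
           ifelse(ch %in% spec$ligand_chains, "ligand", NA))
  }
  a$side <- side_of(a$chain)
  a <- a[!is.na(a$side), , drop = FALSE]

  donor_rows <- donor_table(a)
  acceptor_rows <- acceptor_table(a)
  out <- list()

  if (nrow(donor_rows) > 0 && nrow(acceptor_rows) > 0) {
    for (i in seq_len(nrow(donor_rows))) {
      d <- donor_rows[i, ]
      acc <- acceptor_rows[acceptor_rows$side != d$side, , drop = FALSE]
      if (nrow(acc) == 0) next
      dist <- sqrt((acc$x - d$x)^2 + (acc$y - d$y)^2 + (acc$z - d$z)^2)
      hit <- which(dist <= hb_dist & dist > 1e-6)
      for (j in hit) {
        ang <- NA_real_
        if (!is.na(d$ante_x)) {
          v1 <- c(d$ante_x - d$x, d$ante_y - d$y, d$ante_z - d$z)
          v2 <- c(acc$x[j] - d$x, acc$y[j] - d$y, acc$z[j] - d$z)
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        }
        if (!is.na(ang) && ang < hb_angle) next
        out[[length(out) + 1]] <- data.frame(
          kind = "hydrogen_bond",
          donor_chain = d$chain, donor_res_seq = d$res_seq,
          donor_res_name = d$res_name, donor_atom = d$atom_name,
          acceptor_chain = acc$chain[j], acceptor_res_seq = acc$res_seq[j],
          acceptor_res_name = acc$res_name[j], acceptor_atom = acc$atom_name[j],
          distance = dist[j], angle = ang, stringsAsFactors = FALSE)
      }
    }
  }

  # salt bridges
  bn <- a[mapply(function(rn, an) rn %in% names(basic_n_atoms) &&
                   an %in% basic_n_atoms[[rn]],
                 a$res_name, a$atom_name), , drop = FALSE]
  ao <- a[mapply(function(rn, an) rn %in% names(acidic_o_atoms) &&
                   an %in% acidic_o_atoms[[rn]],
                 a$res_name, a$atom_name), , drop = FALSE]
  if (nrow(bn) > 0 && nrow(ao) > 0) {
    for (i in seq_len(nrow(bn))) {
      opp <- ao[ao$side != bn$side[i], , drop = FALSE]
      if (nrow(opp) == 0) next
      dist <- sqrt((opp$x - bn$x[i])^2 + (opp$y - bn$y[i])^2 +
                     (opp$z - bn$z[i])^2)
      hit <- which(dist <= sb_dist)
      for (j in hit) {
        out[[length(out) + 1]] <- data.frame(
          kind = "salt_bridge",
          donor_chain = bn$chain[i], donor_res_seq = bn$res_seq[i],
          donor_res_name = bn$res_name[i], donor_atom = bn$atom_name[i],
          acceptor_chain = opp$chain[j], acceptor_res_seq = opp$res_seq[j],
          acceptor_res_name = opp$res_name[j], acceptor_atom = opp$atom_name[j],
          distance = dist[j], angle = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(kind = character(0), donor_chain = character(0),
                      donor_res_seq = integer(0), donor_res_name = character(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_res_seq = integer(0),
                      acceptor_res_name = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$kind, res$donor_chain, res$donor_res_seq,
                     res$acceptor_res_seq), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("polar_bonds", class(res))
  res
}

# donors with antecedent coordinates resolved (NA when absent)
donor_table <- function(a) {
  is_bb_n <- a$atom_name == "N" & a$res_name != "PRO"
  is_sc <- mapply(function(rn, an) rn %in% names(side_chain_donors) &&
                    an %in% names(side_chain_donors[[rn]]),
                  a$res_name, a$atom_name)
  d <- a[is_bb_n | is_sc, , drop = FALSE]
  if (nrow(d) == 0) {
    d$ante_x <- d$ante_y <- d$ante_z <- numeric(0)
    return(d)
  }
  ante_name <- mapply(function(rn, an) {
    if (an == "N") "CA"
    else side_chain_donors[[rn]][[an]]
  }, d$res_name, d$atom_name)
  key_a <- paste(a$chain, a$res_seq, a$icode, a$atom_name, sep = "\r")
  key_want <- paste(d$chain, d$res_seq, d$icode, ante_name, sep = "\r")
  idx <- match(key_want, key_a)
  d$ante_x <- a$x[idx]; d$ante_y <- a$y[idx]; d$ante_z <- a$z[idx]
  d
}

acceptor_table <- function(a) {
  is_bb_o <- a$atom_name %in% c("O", "OXT")
  is_sc <- mapply(function(rn, an) rn %in% names(side_chain_acceptors) &&
                    an %in% side_chain_acceptors[[rn]],
                  a$res_name, a$atom_name)
  a[is_bb_o | is_sc, , drop = FALSE]
}
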