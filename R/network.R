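# Cross-interface contact typing, per-residue interaction counting,
# a network-style cooperativity score and hot-spot ranking.

#' Interaction-count table
#'
#' Container for per-receptor-residue interaction counts across a peptide
#' series, with one optional cooperativity score per peptide.
#'
#' @param counts Integer matrix, peptides x residues, with dimnames
#'   (peptide ids, residue labels of the form `"VAL-30"`).
#' @param coop_scores Numeric vector of per-peptide scores (NA allowed).
#' @return Object of class `interaction_table`.
#' @export
interaction_table <- function(counts, coop_scores = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("interaction counts must be >= 0")
  storage.mode(counts) <- "integer"
  if (is.null(coop_scores)) coop_scores <- rep(NA_real_, nrow(counts))
  if (length(coop_scores) != nrow(counts)) {
    stop("coop_scores length must match the number of peptides")
  }
  structure(list(counts = counts,
                 residue_labels = colnames(counts),
                 peptide_ids = rownames(counts),
                 coop_scores = as.numeric(coop_scores)),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("interaction_table:", nrow(x$counts), "peptides x",
      ncol(x$counts), "residues; grand total", sum(x$counts), "\n")
  invisible(x)
}

#' Type cross-interface atomic contacts
#'
#' A hydrophobic contact is a pair of apolar carbons (per the packaged
#' residue polarity table) on opposite sides of the interface within
#' `hydrophobic_cutoff`. Hydrogen bonds and salt bridges are delegated to
#' [detect_polar_bonds()] and merged, oriented so the receptor atom comes
#' first.
#'
#' @param model A `structure_model`.
#' @param spec A [complex_spec()].
#' @param hydrophobic_cutoff Apolar carbon-carbon cutoff (Angstrom, 4.5).
#' @param hb_dist,hb_angle,sb_dist Passed to [detect_polar_bonds()].
#' @return data.frame of class `contact_table`: receptor/ligand atom
#'   references, receptor atom coordinates, `distance`, `kind`.
#' @export
type_contacts <- function(model, spec, hydrophobic_cutoff = 4.5,
                          hb_dist = 3.5, hb_angle = 90, sb_dist = 4.0) {
  stopifnot(inherits(spec, "complex_spec"))
  a <- model$atoms
  a$row <- seq_len(nrow(a))
  rec <- a[a$chain %in% spec$receptor_chains, , drop = FALSE]
  lig <- a[a$chain %in% spec$ligand_chains, , drop = FALSE]

  rec_ap <- rec[rec$element == "C" &
                  is_apolar_carbon(rec$res_name, rec$atom_name), , drop = FALSE]
  lig_ap <- lig[lig$element == "C" &
                  is_apolar_carbon(lig$res_name, lig$atom_name), , drop = FALSE]
  out <- list()
  if (nrow(rec_ap) > 0 && nrow(lig_ap) > 0) {
    rx <- as.matrix(rec_ap[, c("x", "y", "z")])
    lx <- as.matrix(lig_ap[, c("x", "y", "z")])
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
    hit <- which(d2 <= hydrophobic_cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out[[1]] <- data.frame(
        rec_chain = rec_ap$chain[hit[, 1]],
        rec_res_seq = rec_ap$res_seq[hit[, 1]],
        rec_icode = rec_ap$icode[hit[, 1]],
        rec_res_name = rec_ap$res_name[hit[, 1]],
        rec_atom = rec_ap$atom_name[hit[, 1]],
        rec_x = rec_ap$x[hit[, 1]], rec_y = rec_ap$y[hit[, 1]],
        rec_z = rec_ap$z[hit[, 1]],
        lig_chain = lig_ap$chain[hit[, 2]],
        lig_res_seq = lig_ap$res_seq[hit[, 2]],
        lig_res_name = lig_ap$res_name[hit[, 2]],
        lig_atom = lig_ap$atom_name[hit[, 2]],
        distance = sqrt(pmax(d2[hit], 0)),
        kind = "hydrophobic", stringsAsFactors = FALSE)
    }
  }

  pb <- detect_polar_bonds(model, spec, hb_dist, hb_angle, sb_dist)
  if (nrow(pb) > 0) {
    don_is_rec <- pb$donor_chain %in% spec$receptor_chains
    rec_side <- data.frame(
      chain = ifelse(don_is_rec, pb$donor_chain, pb$acceptor_chain),
      res_seq = ifelse(don_is_rec, pb$donor_res_seq, pb$acceptor_res_seq),
      res_name = ifelse(don_is_rec, pb$donor_res_name, pb$acceptor_res_name),
      atom = ifelse(don_is_rec, pb$donor_atom, pb$acceptor_atom),
      stringsAsFactors = FALSE)
    lig_side <- data.frame(
      chain = ifelse(don_is_rec, pb$acceptor_chain, pb$donor_chain),
      res_seq = ifelse(don_is_rec, pb$acceptor_res_seq, pb$donor_res_seq),
      res_name = ifelse(don_is_rec, pb$acceptor_res_name, pb$donor_res_name),
      atom = ifelse(don_is_rec, pb$acceptor_atom, pb$donor_atom),
      stringsAsFactors = FALSE)
    key_a <- paste(a$chain, a$res_seq, a$atom_name, sep = "\r")
    idx <- match(paste(rec_side$chain, rec_side$res_seq, rec_side$atom,
                       sep = "\r"), key_a)
    out[[length(out) + 1]] <- data.frame(
      rec_chain = rec_side$chain, rec_res_seq = rec_side$res_seq,
      rec_icode = a$icode[idx], rec_res_name = rec_side$res_name,
      rec_atom = rec_side$atom,
      rec_x = a$x[idx], rec_y = a$y[idx], rec_z = a$z[idx],
      lig_chain = lig_side$chain, lig_res_seq = lig_side$res_seq,
      lig_res_name = lig_side$res_name, lig_atom = lig_side$atom,
      distance = pb$distance, kind = pb$kind, stringsAsFactors = FALSE)
  }

  res <- if (length(out) == 0) {
    data.frame(rec_chain = character(0), rec_res_seq = integer(0),
               rec_icode = character(0), rec_res_name = character(0),
               rec_atom = character(0), rec_x = numeric(0),
               rec_y = numeric(0), rec_z = numeric(0),
               lig_chain = character(0), lig_res_seq = integer(0),
               lig_res_name = character(0), lig_atom = character(0),
               distance = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$rec_res_seq, res$lig_res_seq, res$kind,
                   res$rec_atom, res$lig_atom), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("contact_table", class(res))
  res
}

#' Per-receptor-residue interaction counts
#'
#' @param contacts A `contact_table` from [type_contacts()] (one complex).
#' @param peptide_id Row label for the resulting one-row table.
#' @param residue_labels Optional fixed column order (labels `"RES-SEQ"`);
#'   defaults to the receptor residues observed in `contacts`, ordered by
#'   residue number.
#' @return An [interaction_table()] with a single row whose counts sum to
#'   `nrow(contacts)`.
#' @export
count_per_residue <- function(contacts, peptide_id = "peptide",
                              residue_labels = NULL) {
  labs <- res_label(contacts$rec_res_name, contacts$rec_res_seq)
  if (is.null(residue_labels)) {
    ord <- order(contacts$rec_res_seq)
    residue_labels <- unique(labs[ord])
  }
  counts <- table(factor(labs, levels = residue_labels))
  mat <- matrix(as.integer(counts), nrow = 1,
                dimnames = list(peptide_id, residue_labels))
  interaction_table(mat)
}

#' Network cooperativity score
#'
#' Each contact contributes `w(kind) * (1 + bonus * deg)`, where the weight
#' is 0.5 for hydrophobic contacts, 1.0 for hydrogen bonds and 1.5 for salt
#' bridges, and `deg` is the number of *other* contacts whose receptor atoms
#' lie within `neighbor_radius` of this contact's receptor atom. Spatially
#' clustered interaction networks therefore score higher than scattered
#' ones with the same contact count. The empty contact set scores 0.
#'
#' @param contacts A `contact_table`.
#' @param neighbor_radius Clustering radius (Angstrom, default 6).
#' @param bonus Per-neighbour bonus weight (default 0.1).
#' @return Single numeric score.
#' @export
cooperativity_score <- function(contacts, neighbor_radius = 6, bonus = 0.1) {
  n <- nrow(contacts)
  if (n == 0) return(0)
  w <- c(hydrophobic = 0.5, hydrogen_bond = 1.0, salt_bridge = 1.5)[contacts$kind]
  if (any(is.na(w))) stop("unknown contact kind")
  xyz <- as.matrix(contacts[, c("rec_x", "rec_y", "rec_z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  deg <- rowSums(d2 <= neighbor_radius^2 + 1e-12) - 1
  sum(as.numeric(w) * (1 + bonus * deg))
}

#' Rank receptor hot spots by total interaction count
#'
#' Residues are ordered by their column totals (ties break to the lower
#' residue number); the top-k fraction is the share of all counts carried by
#' the k highest-ranked residues, reported to the nearest integer percent.
#'
#' @param table An [interaction_table()].
#' @param k Number of top residues (default 5).
#' @return Object of class `hotspot_ranking`: `residues` (ordered labels),
#'   `totals` (aligned), `k`, `top_k_fraction` (integer percent, NA with
#'   `undefined = TRUE` when the grand total is zero).
#' @export
rank_hotspots <- function(table, k = 5) {
  stopifnot(inherits(table, "interaction_table"))
  totals <- colSums(table$counts)
  res_num <- suppressWarnings(as.integer(sub("^.*-", "", names(totals))))
  ord <- order(-totals, res_num, seq_along(totals))
  totals <- totals[ord]
  grand <- sum(totals)
  k <- min(k, length(totals))
  if (grand == 0) {
    frac <- NA_real_
    undefined <- TRUE
  } else {
    frac <- round_half_up(100 * sum(totals[seq_len(k)]) / grand)
    undefined <- FALSE
  }
  structure(list(residues = names(totals), totals = as.integer(totals),
                 k = k, top_k_fraction = frac, undefined = undefined),
            class = "hotspot_ranking")
}

#' @export
print.hotspot_ranking <- function(x, ...) {
  cat("hotspot_ranking: top", x$k, "=",
      paste(head(x$residues, x$k), collapse = ", "), "\n")
  if (x$undefined) cat("  top-k fraction undefined (all counts zero)\n")
  else cat("  top-k fraction:", x$top_k_fraction, "%\n")
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Aggregate cooperativity scores over a peptide subset
#'
#' @param table An [interaction_table()] carrying `coop_scores`.
#' @param peptide_filter Either a character vector of peptide ids, a
#'   logical/integer index, or a predicate function over peptide ids.
#' @return List with `mean`, `sd` (sample SD; NA with flag for n = 1) and
#'   `n`.
#' @export
aggregate_scores <- function(table, peptide_filter) {
  stopifnot(inherits(table, "interaction_table"))
  ids <- table$peptide_ids
  sel <- if (is.function(peptide_filter)) {
    vapply(ids, peptide_filter, logical(1))
  } else if (is.character(peptide_filter)) {
    ids %in% peptide_filter
  } else if (is.logical(peptide_filter)) {
    peptide_filter
  } else {
    seq_along(ids) %in% peptide_filter
  }
  scores <- table$coop_scores[sel]
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no peptides pass the filter")
  list(mean = mean(scores),
       sd = if (length(scores) > 1) sd(scores) else NA_real_,
       n = length(scores))
}
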