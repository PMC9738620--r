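# CAPRI-style docking model quality: Kabsch superposition, fraction of
# native contacts, ligand and interface backbone RMSD, quality classes and
# cohort summaries.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid fit of `mobile` onto `target` over corresponding
#' rows, via SVD of the covariance matrix with the determinant correction
#' that guarantees a proper rotation.
#'
#' @param mobile,target n x 3 coordinate matrices with corresponding rows
#'   (n >= 3, non-degenerate).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the fit is `mobile %*% rotation + translation`), and `rmsd`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("row counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 corresponding points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # degenerate (collinear) sets have rank < 2 covariance in either frame
  if (svd(A)$d[2] < 1e-8 * max(svd(A)$d[1], 1) ||
      svd(B)$d[2] < 1e-8 * max(svd(B)$d[1], 1)) {
    stop("degenerate (collinear) point set")
  }
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = ct - as.numeric(cm %*% R), rmsd = rmsd)
}

# Match atoms of model and reference by (chain, res_seq, icode, atom_name);
# returns corresponding coordinate matrices.
match_atoms <- function(model, reference, chains, atom_names) {
  msel <- tryCatch(select_atoms(model, chains, atom_names),
                   error = function(e) NULL)
  rsel <- select_atoms(reference, chains, atom_names)
  if (is.null(msel)) {
    return(list(model = NULL, reference = rsel, frac = 0))
  }
  kr <- paste(rsel$map$chain, rsel$map$res_seq, rsel$map$icode,
              rsel$map$atom_name, sep = "\r")
  km <- paste(msel$map$chain, msel$map$res_seq, msel$map$icode,
              msel$map$atom_name, sep = "\r")
  idx <- match(kr, km)
  ok <- !is.na(idx)
  list(model = msel$coords[idx[ok], , drop = FALSE],
       reference = rsel$coords[ok, , drop = FALSE],
       frac = mean(ok), map = rsel$map[ok, , drop = FALSE])
}

# Which backbone representation do model and reference share? Falls back to
# CA-only for coarse-grained models.
backbone_mode <- function(model, reference, chains) {
  nm <- unique(model$atoms$atom_name[model$atoms$chain %in% chains])
  if (all(c("N", "C", "O") %in% nm)) "backbone" else "CA"
}

#' Fraction of native contacts
#'
#' Native contacts are cross-interface residue pairs with any heavy-atom
#' distance within `contact_cutoff` in the reference; Fnat is the fraction
#' of them preserved (same residue-pair criterion) in the model. No
#' superposition is involved.
#'
#' @param model,reference `structure_model`s sharing residue identifiers.
#' @param spec A [complex_spec()].
#' @param contact_cutoff Heavy-atom cutoff (Angstrom, default 5).
#' @return Fraction in `[0, 1]`. When the reference has no native contacts,
#'   `NA` with attribute `undefined = TRUE`. When either structure is
#'   CA-only, the value carries attribute `low_confidence = TRUE`.
#' @export
fnat <- function(model, reference, spec, contact_cutoff = 5) {
  native <- contact_pairs(reference, spec, contact_cutoff)
  if (nrow(native) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  modeled <- contact_pairs(model, spec, contact_cutoff)
  key <- function(df) paste(df$rec_chain, df$rec_res_seq, df$rec_icode,
                            df$lig_chain, df$lig_res_seq, df$lig_icode,
                            sep = "\r")
  value <- mean(key(native) %in% key(modeled))
  ca_only <- all(model$atoms$atom_name == "CA")
  if (ca_only) attr(value, "low_confidence") <- TRUE
  value
}

#' Ligand backbone RMSD
#'
#' Superposes the model onto the reference using receptor backbone atoms
#' only, then reports the ligand backbone RMSD under that transform. For
#' CA-only models the backbone reduces to CA (recorded in the
#' `atoms_used` attribute).
#'
#' @param model,reference `structure_model`s sharing residue identifiers.
#' @param spec A [complex_spec()].
#' @return RMSD in Angstrom with attribute `atoms_used`.
#' @export
lrms <- function(model, reference, spec) {
  mode <- backbone_mode(model, reference,
                        c(spec$receptor_chains, spec$ligand_chains))
  bb <- if (mode == "backbone") "backbone" else "CA"
  rec <- match_atoms(model, reference, spec$receptor_chains, bb)
  if (rec$frac < 0.9) {
    stop("more than 10% of receptor ", bb, " atoms missing in model")
  }
  fit <- kabsch_superpose(rec$model, rec$reference)
  lig <- match_atoms(model, reference, spec$ligand_chains, bb)
  if (lig$frac < 0.9) {
    stop("more than 10% of ligand ", bb, " atoms missing in model")
  }
  moved <- lig$model %*% fit$rotation +
    matrix(fit$translation, nrow(lig$model), 3, byrow = TRUE)
  structure(sqrt(mean(rowSums((moved - lig$reference)^2))), atoms_used = bb)
}

#' Interface backbone RMSD
#'
#' Interface residues are those on either side with any heavy atom within
#' `interface_cutoff` of the partner in the *reference*; the model is
#' superposed on their backbone atoms and that same set's RMSD is reported.
#'
#' @param model,reference `structure_model`s sharing residue identifiers.
#' @param spec A [complex_spec()].
#' @param interface_cutoff Interface residue cutoff (Angstrom, default 10).
#' @return RMSD in Angstrom with attributes `atoms_used`, `n_residues`.
#' @export
irms <- function(model, reference, spec, interface_cutoff = 10) {
  pairs <- contact_pairs(reference, spec, interface_cutoff)
  if (nrow(pairs) == 0) stop("empty interface in reference at ",
                             interface_cutoff, " A")
  iface_keys <- unique(c(paste(pairs$rec_chain, pairs$rec_res_seq,
                               pairs$rec_icode, sep = "\r"),
                         paste(pairs$lig_chain, pairs$lig_res_seq,
                               pairs$lig_icode, sep = "\r")))
  mode <- backbone_mode(model, reference,
                        c(spec$receptor_chains, spec$ligand_chains))
  bb <- if (mode == "backbone") "backbone" else "CA"
  m <- match_atoms(model, reference,
                   c(spec$receptor_chains, spec$ligand_chains), bb)
  in_iface <- paste(m$map$chain, m$map$res_seq, m$map$icode,
                    sep = "\r") %in% iface_keys
  if (sum(in_iface) < 3) stop("fewer than 3 matched interface atoms")
  fit <- kabsch_superpose(m$model[in_iface, , drop = FALSE],
                          m$reference[in_iface, , drop = FALSE])
  structure(fit$rmsd, atoms_used = bb,
            n_residues = length(iface_keys))
}

capri_thresholds <- data.frame(
  quality = c("Acceptable", "Medium", "High"),
  lrms_max = c(5.0, 2.0, 1.0),
  irms_max = c(2.0, 1.0, 0.5),
  fnat_min = c(0.2, 0.5, 0.8),
  stringsAsFactors = FALSE
)

#' Classify docking model quality
#'
#' Applies the standard threshold ladder (Acceptable: LRMS < 5.0,
#' IRMS < 2.0, Fnat > 0.2; Medium: < 2.0, < 1.0, > 0.5; High: < 1.0,
#' < 0.5, > 0.8) and returns the highest class whose three conditions all
#' hold, else `"Incorrect"`. When `fnat` is NA (undefined or unavailable)
#' the class is computed from the two RMS conditions only and flagged.
#'
#' @param fnat Fraction of native contacts in `[0, 1]` or NA.
#' @param lrms,irms RMSD values in Angstrom (>= 0).
#' @return List with `quality`, per-class logical `checks` (3 conditions
#'   per class), and `fnat_missing`.
#' @export
classify_quality <- function(fnat, lrms, irms) {
  lrms <- as.numeric(lrms); irms <- as.numeric(irms)
  fnat <- as.numeric(fnat)
  if (any(c(lrms, irms) < 0) || (!is.na(fnat) && (fnat < 0 || fnat > 1))) {
    stop("metrics out of range")
  }
  th <- capri_thresholds
  checks <- lapply(seq_len(nrow(th)), function(i) {
    c(lrms = lrms < th$lrms_max[i],
      irms = irms < th$irms_max[i],
      fnat = if (is.na(fnat)) NA else fnat > th$fnat_min[i])
  })
  names(checks) <- th$quality
  pass <- vapply(checks, function(ck) all(ck[!is.na(ck)]), logical(1))
  quality <- if (any(pass)) th$quality[max(which(pass))] else "Incorrect"
  list(quality = quality, checks = checks, fnat_missing = is.na(fnat))
}

#' Full CAPRI-style assessment of one model
#'
#' @param model,reference `structure_model`s sharing residue identifiers.
#' @param spec A [complex_spec()].
#' @param contact_cutoff Fnat heavy-atom cutoff (Angstrom, default 5).
#' @param interface_cutoff IRMS interface definition cutoff (default 10).
#' @return Object of class `capri_result`: `fnat`, `lrms`, `irms`,
#'   `quality`, `atoms_used`, `flags`.
#' @export
capri_assess <- function(model, reference, spec, contact_cutoff = 5,
                         interface_cutoff = 10) {
  fn <- fnat(model, reference, spec, contact_cutoff)
  l <- lrms(model, reference, spec)
  i <- irms(model, reference, spec, interface_cutoff)
  cls <- classify_quality(as.numeric(fn), as.numeric(l), as.numeric(i))
  structure(list(fnat = as.numeric(fn), lrms = as.numeric(l),
                 irms = as.numeric(i), quality = cls$quality,
                 atoms_used = attr(l, "atoms_used"),
                 flags = list(
                   fnat_undefined = isTRUE(attr(fn, "undefined")),
                   fnat_low_confidence = isTRUE(attr(fn, "low_confidence")),
                   fnat_missing = cls$fnat_missing),
                 checks = cls$checks),
            class = "capri_result")
}

#' @export
print.capri_result <- function(x, ...) {
  cat(sprintf("capri_result: Fnat %.3f  LRMS %.2f A  IRMS %.2f A  -> %s (%s)\n",
              x$fnat, x$lrms, x$irms, x$quality, x$atoms_used))
  invisible(x)
}

#' Summarize a cohort of RMSD values against a threshold
#'
#' @param values Numeric vector (Angstrom), non-empty.
#' @param threshold Threshold (strict `<` comparison).
#' @param label Optional group label (e.g. "medoid").
#' @return Object of class `cohort_summary`: `label`, `values`,
#'   `threshold`, `n_below`, `fraction_below` (integer percent, half-up
#'   rounding).
#' @export
summarize_cohort <- function(values, threshold, label = "") {
  values <- as.numeric(values)
  if (length(values) == 0 || any(is.na(values))) {
    stop("values must be a non-empty numeric vector without NA")
  }
  n_below <- sum(values < threshold)
  structure(list(label = label, values = values, threshold = threshold,
                 n_below = n_below,
                 fraction_below = round_half_up(100 * n_below / length(values))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort %s: %d/%d below %.2f A (%d%%)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$n_below, length(x$values), x$threshold, x$fraction_below))
  invisible(x)
}
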