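# Deterministic synthetic-data generators: ideal-helix toy complexes with
# ground-truth contacts, rigid-body docking decoys with closed-form RMSD,
# and synthetic interaction tables. These stand in for the outputs of
# external docking engines so the whole pipeline is testable offline.

# Natural extension reference frame: place atom D given A, B, C with
# bond |CD|, angle B-C-D (degrees) and dihedral A-B-C-D (degrees).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Side-chain extension (Angstrom beyond CB along CA->CB) for the centroid
# pseudo-atom, a coarse proxy for side-chain bulk.
sc_extension <- c(
  A = NA, G = NA, S = 0.8, C = 0.9, T = 0.9, V = 0.9, P = 0.8,
  L = 1.5, I = 1.5, N = 1.4, D = 1.4, M = 2.0, E = 2.0, Q = 2.0,
  K = 2.4, F = 2.4, H = 2.2, R = 3.0, W = 2.8, Y = 2.8
)

#' Parameters for a toy receptor-peptide complex
#'
#' @param peptide_sequence One-letter peptide sequence (standard residues).
#' @param receptor_size Number of residues in the receptor slab.
#' @param gap Closest heavy-atom approach distance between peptide and slab
#'   (Angstrom, >= 0).
#' @param seed Integer seed (reserved for randomized variants; the default
#'   builder is fully deterministic).
#' @return Object of class `toy_complex_params`.
#' @export
toy_complex_params <- function(peptide_sequence, receptor_size = 36,
                               gap = 3, seed = 1L) {
  if (nchar(peptide_sequence) < 1) stop("peptide sequence must be non-empty")
  if (gap < 0) stop("gap must be >= 0")
  letters1 <- strsplit(toupper(peptide_sequence), "")[[1]]
  bad <- setdiff(letters1, names(aa1_to_aa3))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(peptide_sequence = toupper(peptide_sequence),
                 receptor_size = as.integer(receptor_size),
                 gap = gap, seed = as.integer(seed)),
            class = "toy_complex_params")
}

# Ideal alpha-helix backbone (phi = -57, psi = -47, omega = 180) with CB and
# a side-chain centroid pseudo-atom SC1 per residue.
build_helix_peptide <- function(sequence, chain = "C") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  phi <- -57; psi <- -47; omega <- 180
  # seed residue 1 backbone in the xy-plane
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  ang <- 111.2 * pi / 180
  C <- list(CA[[1]] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0))
  if (n > 1) {
    for (i in 2:n) {
      N[[i]] <- nerf_place(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                           1.329, 116.2, psi)
      CA[[i]] <- nerf_place(CA[[i - 1]], C[[i - 1]], N[[i]],
                            1.458, 121.7, omega)
      C[[i]] <- nerf_place(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi)
    }
  }
  rows <- list()
  add <- function(res_i, res_name, atom_name, el, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = NA_integer_, chain = chain, res_seq = res_i, icode = "",
      res_name = res_name, atom_name = atom_name, alt_loc = "",
      element = el, x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, vdw = NA_real_, het = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    res3 <- unname(aa1_to_aa3[letters1[i]])
    add(i, res3, "N", "N", N[[i]])
    add(i, res3, "CA", "C", CA[[i]])
    add(i, res3, "C", "C", C[[i]])
    # carbonyl O in the peptide plane, anti to the next N direction
    add(i, res3, "O", "O",
        nerf_place(N[[i]], CA[[i]], C[[i]], 1.231, 120.5, psi - 180))
    if (letters1[i] != "G") {
      CB <- nerf_place(C[[i]], N[[i]], CA[[i]], 1.530, 110.4, 122.6)
      add(i, res3, "CB", "C", CB)
      ext <- sc_extension[[letters1[i]]]
      if (!is.na(ext)) {
        u <- CB - CA[[i]]
        u <- u / sqrt(sum(u^2))
        add(i, res3, "SC1", "C", CB + ext * u)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$vdw <- assign_radii(atoms$element)
  atoms
}

# Rigid receptor slab: a grid of alternating GLY/ALA residues in the z ~ 0
# plane with ALA CB (and SC1) pointing up toward the peptide.
build_slab_receptor <- function(n_residues, chain = "A", spacing = 4.0) {
  nx <- ceiling(sqrt(n_residues))
  rows <- list()
  serial <- 0L
  for (k in seq_len(n_residues)) {
    i <- (k - 1) %% nx
    j <- (k - 1) %/% nx
    cx <- i * spacing
    cy <- j * spacing
    res3 <- if ((i + j) %% 2 == 0) "ALA" else "GLY"
    at <- rbind(
      c("N", "N", cx - 1.2, cy + 0.7, -0.4),
      c("CA", "C", cx, cy, 0),
      c("C", "C", cx + 1.3, cy + 0.6, -0.4),
      c("O", "O", cx + 1.4, cy + 1.8, -0.7))
    if (res3 == "ALA") {
      at <- rbind(at, c("CB", "C", cx, cy, 1.53),
                  c("SC1", "C", cx, cy, 2.3))
    }
    for (r in seq_len(nrow(at))) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, chain = chain, res_seq = k, icode = "",
        res_name = res3, atom_name = at[r, 1], alt_loc = "",
        element = at[r, 2], x = as.numeric(at[r, 3]),
        y = as.numeric(at[r, 4]), z = as.numeric(at[r, 5]),
        occupancy = 1, vdw = NA_real_, het = FALSE, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$vdw <- assign_radii(atoms$element)
  atoms
}

# All cross-set residue pairs with any heavy-atom distance <= cutoff.
contact_pairs <- function(model, spec, cutoff = 5) {
  rec <- select_atoms(model, spec$receptor_chains, "heavy")
  lig <- select_atoms(model, spec$ligand_chains, "heavy")
  d2 <- outer(rowSums(rec$coords^2), rowSums(lig$coords^2), "+") -
    2 * rec$coords %*% t(lig$coords)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(rec_chain = character(0), rec_res_seq = integer(0),
                      rec_icode = character(0), lig_chain = character(0),
                      lig_res_seq = integer(0), lig_icode = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    rec_chain = rec$map$chain[hit[, 1]],
    rec_res_seq = rec$map$res_seq[hit[, 1]],
    rec_icode = rec$map$icode[hit[, 1]],
    lig_chain = lig$map$chain[hit[, 2]],
    lig_res_seq = lig$map$res_seq[hit[, 2]],
    lig_icode = lig$map$icode[hit[, 2]],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$rec_chain, out$rec_res_seq, out$lig_chain, out$lig_res_seq), ,
      drop = FALSE]
}

#' Build a toy receptor-peptide complex with known contacts
#'
#' The peptide is built as an ideal alpha-helix (phi = -57, psi = -47) with
#' idealized CB and side-chain centroid pseudo-atoms (`SC1`); the receptor
#' is a rigid planar slab of alternating glycine/alanine residues. The helix
#' is positioned above the slab so the closest heavy-atom approach equals
#' `params$gap` exactly (solved numerically to machine precision), and the
#' ground-truth list of cross-interface residue pairs within 5 Angstrom is
#' returned alongside the structure.
#'
#' @param params A [toy_complex_params()] object.
#' @param contact_cutoff Heavy-atom distance defining a ground-truth contact
#'   (Angstrom, default 5).
#' @return List with `model` (a `structure_model`, receptor chain "A",
#'   peptide chain "C"), `contacts` (data.frame of residue pairs), and
#'   `spec` (the matching [complex_spec()]).
#' @export
#' @examples
#' toy <- make_toy_complex(toy_complex_params("LSIEET", receptor_size = 16))
#' nrow(toy$contacts)
make_toy_complex <- function(params, contact_cutoff = 5) {
  stopifnot(inherits(params, "toy_complex_params"))
  pep <- build_helix_peptide(params$peptide_sequence, chain = "C")
  rec <- build_slab_receptor(params$receptor_size, chain = "A")

  # spin the helix about its long axis so the apolar side-chain face points
  # down toward the slab (deterministic grid search); this gives the toy
  # interface a hydrophobic character like a real amphipathic helix
  ap <- pep$atom_name %in% c("CB", "SC1") &
    is_apolar_carbon(pep$res_name, pep$atom_name)
  if (any(ap)) {
    xyz0 <- as.matrix(pep[, c("x", "y", "z")])
    ctr <- colMeans(xyz0)
    best <- NULL
    for (th in seq(0, 358, by = 2) * pi / 180) {
      R <- matrix(c(1, 0, 0,
                    0, cos(th), -sin(th),
                    0, sin(th), cos(th)), 3, 3, byrow = TRUE)
      z_ap <- (sweep(xyz0[ap, , drop = FALSE], 2, ctr) %*% t(R))[, 3]
      if (is.null(best) || mean(z_ap) < best$score) {
        best <- list(score = mean(z_ap), R = R)
      }
    }
    xyz0 <- sweep(sweep(xyz0, 2, ctr) %*% t(best$R), 2, ctr, "+")
    pep$x <- xyz0[, 1]; pep$y <- xyz0[, 2]; pep$z <- xyz0[, 3]
  }

  # centre the helix over the slab, axis parallel to the plane
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  shift_xy <- c(mean(range(rec_xyz[, 1])) - mean(range(pep_xyz[, 1])),
                mean(range(rec_xyz[, 2])) - mean(range(pep_xyz[, 2])))
  pep_xyz[, 1] <- pep_xyz[, 1] + shift_xy[1]
  pep_xyz[, 2] <- pep_xyz[, 2] + shift_xy[2]

  min_dist <- function(dz) {
    p <- pep_xyz
    p[, 3] <- p[, 3] + dz
    d2 <- outer(rowSums(p^2), rowSums(rec_xyz^2), "+") -
      2 * p %*% t(rec_xyz)
    sqrt(max(min(d2), 0))
  }
  # bracket the offset where the closest approach equals the gap: scan from
  # full overlap (centres aligned) upward until the sign changes
  f <- function(z) min_dist(z) - params$gap
  grid <- seq(mean(rec_xyz[, 3]) - mean(pep_xyz[, 3]),
              params$gap + diff(range(c(pep_xyz[, 3], rec_xyz[, 3]))) + 10,
              length.out = 200)
  fv <- vapply(grid, f, 0)
  bracket <- which(fv[-length(fv)] <= 0 & fv[-1] > 0)
  if (length(bracket) == 0) {
    stop("cannot realise gap ", params$gap,
         " A by vertical placement of the helix")
  }
  i <- bracket[length(bracket)]
  dz <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  pep_xyz[, 3] <- pep_xyz[, 3] + dz
  pep$x <- pep_xyz[, 1]; pep$y <- pep_xyz[, 2]; pep$z <- pep_xyz[, 3]

  atoms <- rbind(rec, pep)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, source_id = "toy-complex")
  spec <- complex_spec("A", "C")
  list(model = model,
       contacts = contact_pairs(model, spec, contact_cutoff),
       spec = spec)
}

#' Rigid-body decoy specification
#'
#' @param translation 3-vector (Angstrom).
#' @param rotation_axis 3-vector; normalized internally. Must be non-zero
#'   when `rotation_angle != 0`.
#' @param rotation_angle Rotation angle in degrees about the ligand centroid.
#' @param seed Integer seed recorded for provenance.
#' @return Object of class `decoy_spec`.
#' @export
decoy_spec <- function(translation = c(0, 0, 0), rotation_axis = c(0, 0, 1),
                       rotation_angle = 0, seed = 1L) {
  translation <- as.numeric(translation)
  rotation_axis <- as.numeric(rotation_axis)
  nrm <- sqrt(sum(rotation_axis^2))
  if (rotation_angle != 0 && nrm == 0) {
    stop("rotation axis must be a non-zero vector")
  }
  if (nrm > 0) rotation_axis <- rotation_axis / nrm
  structure(list(translation = translation, rotation_axis = rotation_axis,
                 rotation_angle = rotation_angle, seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Random rigid-body decoy specification
#'
#' Draws a uniform random rotation axis, an angle and a translation from a
#' seeded stream, for property tests and decoy cohorts.
#'
#' @param seed Integer seed.
#' @param max_translation,max_angle Upper bounds for |t| (Angstrom) and the
#'   rotation angle (degrees).
#' @return A [decoy_spec()].
#' @export
random_decoy_spec <- function(seed, max_translation = 10, max_angle = 180) {
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old))
  ax <- stats::rnorm(3)
  t <- stats::rnorm(3)
  t <- t / sqrt(sum(t^2)) * runif(1, 0, max_translation)
  decoy_spec(translation = t, rotation_axis = ax,
             rotation_angle = runif(1, 0, max_angle), seed = seed)
}

.Random.seed_store <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

rotation_matrix_axis_angle <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * (u %*% t(u))
}

#' Generate a rigid-body docking decoy
#'
#' Applies a rigid rotation (about the ligand centroid) followed by a
#' translation to the ligand chains, leaving the receptor untouched. A pure
#' translation by `t` therefore yields a ligand RMSD of exactly `|t|`.
#'
#' @param reference A `structure_model` of the reference complex.
#' @param spec A [decoy_spec()].
#' @param complex_spec A [complex_spec()] naming receptor and ligand chains.
#' @return A transformed `structure_model`.
#' @export
make_decoy <- function(reference, spec, complex_spec) {
  stopifnot(inherits(spec, "decoy_spec"), inherits(complex_spec, "complex_spec"))
  a <- reference$atoms
  lig <- which(a$chain %in% complex_spec$ligand_chains)
  if (length(lig) == 0) stop("ligand chains not present in reference")
  xyz <- as.matrix(a[lig, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  R <- rotation_matrix_axis_angle(spec$rotation_axis, spec$rotation_angle)
  xyz <- sweep(xyz, 2, centroid) %*% t(R)
  xyz <- sweep(xyz, 2, centroid + spec$translation, "+")
  a$x[lig] <- xyz[, 1]; a$y[lig] <- xyz[, 2]; a$z[lig] <- xyz[, 3]
  structure_model(a, source_id = paste0(reference$source_id, "-decoy"))
}

#' Synthesize an interaction-count table
#'
#' Draws an integer peptides x residues count matrix from a named count law
#' (`"poisson"` with `lambda`, `"nbinom"` with `mu` and `size`, `"uniform"`
#' with `max`, or `"zero"`), for exercising hot-spot ranking and score
#' aggregation without structural input.
#'
#' @param n_peptides,n_residues Table dimensions (>= 1).
#' @param count_law List with element `name` and the law's parameters.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An [interaction_table()] with synthetic residue labels.
#' @export
synth_interaction_table <- function(n_peptides, n_residues,
                                    count_law = list(name = "poisson", lambda = 3),
                                    seed = 1L) {
  if (n_peptides < 1 || n_residues < 1) stop("table dimensions must be >= 1")
  old <- .Random.seed_store(seed)
  on.exit(.Random.seed_restore(old))
  n <- n_peptides * n_residues
  counts <- switch(count_law$name,
    poisson = rpois(n, count_law$lambda),
    nbinom = rnbinom(n, mu = count_law$mu, size = count_law$size),
    uniform = sample.int(count_law$max + 1L, n, replace = TRUE) - 1L,
    zero = rep(0L, n),
    stop("unsupported count law: ", count_law$name)
  )
  res3 <- sample(std_residues, n_residues, replace = TRUE)
  labels <- res_label(res3, seq_len(n_residues))
  mat <- matrix(as.integer(counts), nrow = n_peptides, ncol = n_residues,
                dimnames = list(paste0("Peptide-", seq_len(n_peptides)),
                                labels))
  interaction_table(mat, coop_scores = rep(NA_real_, n_peptides))
}
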