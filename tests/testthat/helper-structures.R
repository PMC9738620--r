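# Builders for tiny hand-made structures and independent oracles used
# across the suite. Everything is constructed in code; no binary fixtures.

atom_row <- function(chain, res_seq, res_name, atom_name, x, y, z,
                     element = NULL, occupancy = 1, het = FALSE) {
  if (is.null(element)) element <- substr(atom_name, 1, 1)
  data.frame(serial = NA_integer_, chain = chain, res_seq = res_seq,
             icode = "", res_name = res_name, atom_name = atom_name,
             alt_loc = "", element = element, x = x, y = y, z = z,
             occupancy = occupancy,
             vdw = unname(pepint::vdw_radii()[element]), het = het,
             stringsAsFactors = FALSE)
}

make_model <- function(..., source_id = "test") {
  atoms <- do.call(rbind, list(...))
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, source_id = source_id)
}

# a leucine with its 8 heavy atoms in a chemically sensible arrangement
leu_residue <- function(chain = "L", res_seq = 1, origin = c(0, 0, 0)) {
  o <- origin
  rbind(
    atom_row(chain, res_seq, "LEU", "N",   o[1] + 0.0, o[2] + 0.0, o[3] + 0.0),
    atom_row(chain, res_seq, "LEU", "CA",  o[1] + 1.46, o[2] + 0.0, o[3] + 0.0),
    atom_row(chain, res_seq, "LEU", "C",   o[1] + 2.0, o[2] + 1.4, o[3] + 0.0),
    atom_row(chain, res_seq, "LEU", "O",   o[1] + 1.3, o[2] + 2.4, o[3] + 0.0),
    atom_row(chain, res_seq, "LEU", "CB",  o[1] + 2.0, o[2] - 0.8, o[3] + 1.2),
    atom_row(chain, res_seq, "LEU", "CG",  o[1] + 2.1, o[2] - 0.3, o[3] + 2.6),
    atom_row(chain, res_seq, "LEU", "CD1", o[1] + 3.0, o[2] - 1.2, o[3] + 3.4),
    atom_row(chain, res_seq, "LEU", "CD2", o[1] + 0.8, o[2] - 0.3, o[3] + 3.4))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

rigid_move <- function(model, seed = 1, translation = NULL) {
  R <- random_rotation(seed)
  if (is.null(translation)) {
    set.seed(seed + 1000)
    translation <- rnorm(3, sd = 5)
  }
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + translation[1]
  a$y <- xyz[, 2] + translation[2]
  a$z <- xyz[, 3] + translation[3]
  structure_model(a, model$source_id)
}

# a flat 3x3 patch of single-atom ALA "residues" acting as a mini receptor
build_toy_slab_for_test <- function(chain = "A", spacing = 4) {
  rows <- list()
  k <- 0
  for (i in 0:2) for (j in 0:2) {
    k <- k + 1
    rows[[k]] <- atom_row(chain, k, "ALA", "CB", i * spacing, j * spacing, 0,
                          element = "C")
  }
  do.call(rbind, rows)
}

# independent O(n^2) residue-pair contact scan (oracle for contact lists)
brute_contacts <- function(model, spec, cutoff = 5) {
  a <- model$atoms
  a <- a[!a$element %in% c("H", "D"), ]
  rec <- a[a$chain %in% spec$receptor_chains, ]
  lig <- a[a$chain %in% spec$ligand_chains, ]
  seen <- character(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        seen <- c(seen, paste(rec$chain[i], rec$res_seq[i], lig$chain[j],
                              lig$res_seq[j], sep = "|"))
      }
    }
  }
  sort(unique(seen))
}

contact_key <- function(df) {
  sort(paste(df$rec_chain, df$rec_res_seq, df$lig_chain, df$lig_res_seq,
             sep = "|"))
}

# brute-force rigid-fit RMSD by quaternion grid with local refinement
# (independent of the SVD path)
quat_grid_rmsd <- function(mobile, target, n_coarse = 6000, seed = 42) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rmsd_of <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  set.seed(seed)
  best <- list(val = Inf, q = c(1, 0, 0, 0))
  for (i in seq_len(n_coarse)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    v <- rmsd_of(quat_to_rot(q))
    if (v < best$val) best <- list(val = v, q = q)
  }
  # local refinement around the best quaternion
  step <- 0.05
  for (round in 1:60) {
    improved <- FALSE
    for (k in 1:4) for (s in c(-1, 1)) {
      q <- best$q; q[k] <- q[k] + s * step; q <- q / sqrt(sum(q^2))
      v <- rmsd_of(quat_to_rot(q))
      if (v < best$val) { best <- list(val = v, q = q); improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (step < 1e-7) break
  }
  best$val
}
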