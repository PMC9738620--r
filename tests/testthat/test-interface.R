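# interface_report, solvation_gain and detect_polar_bonds. SASA quadrature
# is kept at 240 points here to stay fast; conservation identities are
# exact regardless of quadrature density.

test_that("a far-separated complex has an empty interface", {
  toy <- make_toy_complex(toy_complex_params("LSIEET", receptor_size = 9,
                                             gap = 100))
  rep <- interface_report(toy$model, toy$spec, n_points = 240)
  expect_equal(rep$per_chain$n_interface_residues, c(0, 0))
  expect_equal(rep$per_chain$interface_area, c(0, 0), tolerance = 1e-9)
  expect_equal(sum(rep$per_residue$is_interface), 0)
})

test_that("single-touch construction flags exactly one ligand residue and conserves area", {
  # ligand: two GLY residues; residue 1 sits 3.5 A above a slab atom,
  # residue 2 is 60 A away
  lig <- rbind(atom_row("C", 1, "GLY", "CA", 2, 2, 3.5),
               atom_row("C", 2, "GLY", "CA", 2, 2, 63.5))
  rec <- build_toy_slab_for_test()
  m <- make_model(rec, lig)
  spec <- complex_spec("A", "C")
  rep <- interface_report(m, spec, n_points = 240)
  lig_res <- rep$per_residue[rep$per_residue$side == "ligand", ]
  expect_identical(lig_res$is_interface, c(TRUE, FALSE))
  # conservation: chain interface_area equals the per-residue BSA sum
  for (side in c("receptor", "ligand")) {
    rs <- rep$per_residue[rep$per_residue$side == side, ]
    ia <- rep$per_chain$interface_area[rep$per_chain$side == side]
    expect_equal(sum(rs$bsa), ia, tolerance = 1e-6 * max(ia, 1))
  }
  # per-residue BSA identity and count ordering invariants
  expect_true(all(rep$per_residue$bsa >=
                    -1e-9 - 0 * rep$per_residue$bsa))
  pc <- rep$per_chain
  expect_true(all(pc$n_interface_residues <= pc$n_surface_residues))
  expect_true(all(pc$n_surface_residues <= pc$n_total_residues))
  expect_true(all(pc$n_interface_atoms <= pc$n_surface_atoms))
  expect_error(interface_report(m, complex_spec("A", "C"), probe = 1.4,
                                n_points = 16), "quadrature")
})

test_that("widening the gap never increases any residue's BSA", {
  gaps <- c(3, 4.5, 7)
  reps <- lapply(gaps, function(g) {
    toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                               gap = g))
    interface_report(toy$model, toy$spec, n_points = 240)$per_residue
  })
  for (i in 1:(length(gaps) - 1)) {
    a <- reps[[i]]; b <- reps[[i + 1]]
    key <- paste(a$chain, a$res_seq)
    m <- match(key, paste(b$chain, b$res_seq))
    expect_true(all(b$bsa[m] <= a$bsa + 1e-6))
  }
})

test_that("interface residue sets are invariant under global rigid motion", {
  # The quadrature sphere is fixed in space, so per-residue BSA moves by up
  # to ~ one point-area under rotation (measured ~2 A^2/residue at 240 points);
  # residues buried beyond that noise band must be called identically, and
  # any disagreement must be confined to grazing residues inside the band.
  toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                             gap = 3))
  rep1 <- interface_report(toy$model, toy$spec, n_points = 240)$per_residue
  rep2 <- interface_report(rigid_move(toy$model, seed = 5), toy$spec,
                           n_points = 240)$per_residue
  key <- function(df) paste(df$chain, df$res_seq)
  m <- match(key(rep1), key(rep2))
  noise <- 2.5
  expect_identical(rep1$bsa > noise, rep2$bsa[m] > noise)
  flipped <- rep1$is_interface != rep2$is_interface[m]
  expect_true(all(rep1$bsa[flipped] < noise & rep2$bsa[m][flipped] < noise))
  # and the BSA values themselves agree within the quadrature noise band
  expect_lt(max(abs(rep1$bsa - rep2$bsa[m])), noise)
})

test_that("solvation gain follows the atomic-solvation-parameter model", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                             gap = 100))
  rep_far <- interface_report(toy$model, toy$spec, n_points = 240)
  g <- solvation_gain(rep_far)
  expect_equal(unname(g$per_chain), c(0, 0), tolerance = 1e-9)

  # all-carbon touching pair: gain strictly negative (apolar burial)
  a1 <- atom_row("A", 1, "UNK", "X", 0, 0, 0, element = "C")
  a2 <- atom_row("C", 1, "UNK", "X", 3.5, 0, 0, element = "C")
  m <- make_model(a1, a2)
  rep <- interface_report(m, complex_spec("A", "C"), n_points = 960)
  expect_lt(sum(rep$per_chain$solvation_gain), 0)

  # manual sigma * dASA summation oracle on a small mixed complex
  lig <- rbind(atom_row("C", 1, "GLY", "CA", 2, 2, 3.2),
               atom_row("C", 1, "GLY", "O", 3.4, 2, 3.4))
  m2 <- make_model(build_toy_slab_for_test(), lig)
  rep2 <- interface_report(m2, complex_spec("A", "C"), n_points = 240)
  sig <- solvation_params()
  manual <- sum(sig[rep2$per_atom$asp_class] * rep2$per_atom$d_asa)
  expect_equal(sum(rep2$per_chain$solvation_gain), manual, tolerance = 1e-9)
  # recomputation under a different table scales accordingly
  g2 <- solvation_gain(rep2, asp_table = sig * 2)
  expect_equal(sum(g2$per_chain), 2 * manual, tolerance = 1e-9)
})

test_that("hydrogen bonds and salt bridges obey the geometric criteria", {
  # ideal backbone N-H...O=C pair across the interface at 2.9 A, angle 150
  don <- rbind(atom_row("A", 1, "GLY", "CA", -1.26, 0.84, 0),
               atom_row("A", 1, "GLY", "N", 0, 0, 0))
  acc <- rbind(atom_row("C", 1, "GLY", "O", 2.9, 0, 0),
               atom_row("C", 1, "GLY", "C", 3.9, 0.73, 0))
  m <- make_model(don, acc)
  spec <- complex_spec("A", "C")
  pb <- detect_polar_bonds(m, spec)
  expect_equal(nrow(pb), 1)
  expect_equal(pb$kind, "hydrogen_bond")
  expect_equal(pb$distance, 2.9, tolerance = 1e-6)
  expect_gt(pb$angle, 90)

  # same pair at 5.0 A: nothing
  acc5 <- acc; acc5$x <- acc5$x + 2.1
  expect_equal(nrow(detect_polar_bonds(make_model(don, acc5), spec)), 0)

  # acute antecedent angle rejects the bond
  don_bad <- don
  don_bad[1, c("x", "y")] <- c(1.0, 0.5)  # CA pulled toward the acceptor
  expect_equal(nrow(detect_polar_bonds(make_model(don_bad, acc), spec)), 0)

  # Asp...Arg pair: salt bridge (and donor-acceptor hydrogen bond) detected
  arg <- rbind(atom_row("A", 16, "ARG", "CZ", 0, 0, 1.2),
               atom_row("A", 16, "ARG", "NH1", 0, 0, 0))
  asp <- atom_row("C", 22, "ASP", "OD1", 3.2, 0, 0)
  pb2 <- detect_polar_bonds(make_model(arg, asp), spec)
  expect_true("salt_bridge" %in% pb2$kind)
  sb <- pb2[pb2$kind == "salt_bridge", ]
  expect_equal(sb$donor_res_name, "ARG")
  expect_equal(sb$acceptor_res_name, "ASP")
  expect_true(all(pb2$distance > 0))
})
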