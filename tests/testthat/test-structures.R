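test_that("read_pdb parses minimal records and resolves altlocs", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), pdb)
  m <- read_pdb(pdb)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$res_seq, 1L)
  expect_equal(unlist(m$atoms[, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))

  # altloc: highest occupancy wins; waters and hydrogens dropped
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  H   ALA A   1       0.000   0.000   1.000  1.00  0.00           H",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), pdb)
  m <- read_pdb(pdb)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 1.0)

  # element inference when columns 77-78 are blank
  writeLines(c(
    "ATOM      1  NZ  LYS A   1       0.000   0.000   0.000  1.00  0.00",
    "END"), pdb)
  expect_equal(read_pdb(pdb)$atoms$element, "N")

  writeLines("REMARK no atoms here", pdb)
  expect_error(read_pdb(pdb), "no ATOM")
  expect_error(read_pdb(tempfile()), "cannot read")
})

test_that("write_pdb/read_pdb round-trips coordinates within PDB precision", {
  helix <- make_toy_complex(toy_complex_params(
    strrep("A", 18), receptor_size = 4, gap = 20))$model
  p1 <- tempfile(fileext = ".pdb")
  write_pdb(helix, p1)
  m1 <- read_pdb(p1)
  expect_equal(nrow(m1$atoms), nrow(helix$atoms))
  expect_lt(max(abs(as.matrix(m1$atoms[, c("x", "y", "z")]) -
                      as.matrix(helix$atoms[, c("x", "y", "z")]))), 1e-3)
  # read o write o read is the identity exactly (quantisation already done)
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(m1, p2)
  m2 <- read_pdb(p2)
  expect_identical(m2$atoms[, c("x", "y", "z")], m1$atoms[, c("x", "y", "z")])

  # randomized 50-atom model
  set.seed(7)
  rnd <- do.call(rbind, lapply(1:50, function(i) {
    atom_row("A", i, "GLY", "CA", runif(1, -50, 50), runif(1, -50, 50),
             runif(1, -50, 50))
  }))
  rnd$serial <- seq_len(nrow(rnd))
  mr <- structure_model(rnd, "rnd")
  p3 <- tempfile(fileext = ".pdb")
  write_pdb(mr, p3)
  back <- read_pdb(p3)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(mr$atoms[, c("x", "y", "z")]))), 1e-3)

  # TER bookkeeping and overflow guard
  two <- make_model(atom_row("A", 1, "GLY", "CA", 0, 0, 0),
                    atom_row("B", 1, "GLY", "CA", 5, 0, 0))
  p4 <- tempfile(fileext = ".pdb")
  write_pdb(two, p4)
  expect_equal(sum(startsWith(readLines(p4), "TER")), 2)
  bad <- make_model(atom_row("A", 1, "GLY", "CA", 12345.0, 0, 0))
  expect_error(write_pdb(bad, tempfile()), "field width")
})

test_that("select_atoms honours selectors and conserves partitions", {
  toy <- make_toy_complex(toy_complex_params("LSI", receptor_size = 4,
                                             gap = 10))$model
  bb <- select_atoms(toy, "C", "backbone")
  expect_equal(nrow(bb$coords), 12)  # 4 backbone atoms x 3 residues
  expect_named(bb, c("coords", "map"))
  expect_error(select_atoms(toy, "Z", "heavy"), "Z")
  expect_error(select_atoms(toy, "C", "QQ"), "empty atom selection")

  leu <- make_model(leu_residue())
  expect_equal(nrow(select_atoms(leu, "L", "heavy")$coords), 8)

  # |backbone| + |side-chain heavy| == |heavy| per residue
  heavy <- select_atoms(toy, NULL, "heavy")
  bb_all <- select_atoms(toy, NULL, "backbone")
  sc <- heavy$map[!paste(heavy$map$atom_name) %in% c("N", "CA", "C", "O"), ]
  expect_equal(nrow(bb_all$map) + nrow(sc), nrow(heavy$map))
})

test_that("complex_spec validates chain sets", {
  expect_error(complex_spec(character(0), "C"), "non-empty")
  expect_error(complex_spec(c("A", "B"), c("B", "C")), "overlap")
  sp <- complex_spec("A", "C")
  expect_s3_class(sp, "complex_spec")
})
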