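test_that("kabsch superposition recovers exact and noisy fits", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- A %*% t(Rz)
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(A %*% fit$rotation +
                 matrix(fit$translation, 10, 3, byrow = TRUE), B,
               tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # noisy correspondence vs independent quaternion-grid minimizer
  set.seed(99)
  M <- matrix(rnorm(150), 50, 3)
  Rr <- random_rotation(5)
  Tt <- c(3, -2, 1)
  N <- M %*% t(Rr) + matrix(Tt, 50, 3, byrow = TRUE) +
    matrix(rnorm(150, sd = 0.1), 50, 3)
  fitn <- kabsch_superpose(M, N)
  expect_equal(fitn$rmsd, quat_grid_rmsd(M, N), tolerance = 1e-3)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("fnat counts preserved native residue contacts without superposition", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                             gap = 3))
  expect_equal(as.numeric(fnat(toy$model, toy$model, toy$spec)), 1.0)
  far <- make_decoy(toy$model, decoy_spec(translation = c(100, 0, 0)),
                    toy$spec)
  expect_equal(as.numeric(fnat(far, toy$model, toy$spec)), 0.0)

  # constructed half-preservation: two ligand residues at different heights;
  # shifting +2 in z breaks one contact (4 -> 6 A) and keeps one (2 -> 4 A)
  rec <- rbind(atom_row("A", 1, "ALA", "CB", 0, 0, 0, element = "C"),
               atom_row("A", 2, "ALA", "CB", 20, 0, 0, element = "C"))
  lig <- rbind(atom_row("C", 1, "GLY", "CA", 0, 0, 4),
               atom_row("C", 2, "GLY", "CA", 20, 0, 2))
  ref <- make_model(rec, lig)
  spec <- complex_spec("A", "C")
  shifted <- make_decoy(ref, decoy_spec(translation = c(0, 0, 2)), spec)
  expect_equal(as.numeric(fnat(shifted, ref, spec)), 0.5)

  # contact-free reference: undefined flag, not zero
  apart <- make_model(atom_row("A", 1, "ALA", "CB", 0, 0, 0, element = "C"),
                      atom_row("C", 1, "GLY", "CA", 0, 0, 50))
  fn <- fnat(apart, apart, spec)
  expect_true(is.na(fn))
  expect_true(attr(fn, "undefined"))
})

test_that("lrms and irms follow their definitions on rigid decoys", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                             gap = 3))
  spec <- toy$spec
  expect_equal(as.numeric(lrms(toy$model, toy$model, spec)), 0,
               tolerance = 1e-10)
  expect_equal(as.numeric(irms(toy$model, toy$model, spec)), 0,
               tolerance = 1e-10)

  shift <- make_decoy(toy$model, decoy_spec(translation = c(0, 4, 0)), spec)
  expect_equal(as.numeric(lrms(shift, toy$model, spec)), 4, tolerance = 1e-9)
  expect_gt(as.numeric(irms(shift, toy$model, spec)), 0)

  # irms definition oracle, recomputed from scratch for a seeded decoy
  d <- make_decoy(toy$model, random_decoy_spec(23), spec)
  got <- as.numeric(irms(d, toy$model, spec, interface_cutoff = 10))
  iface <- unique(do.call(rbind, lapply(
    strsplit(brute_contacts(toy$model, spec, 10), "\\|"),
    function(p) data.frame(chain = c(p[1], p[3]),
                           res_seq = as.integer(c(p[2], p[4]))))))
  key <- function(m) {
    bb <- select_atoms(m, NULL, "backbone")
    sel <- paste(bb$map$chain, bb$map$res_seq) %in%
      paste(iface$chain, iface$res_seq)
    bb$coords[sel, ]
  }
  fit <- kabsch_superpose(key(d), key(toy$model))
  expect_equal(got, fit$rmsd, tolerance = 1e-9)

  # global rigid motion of the model leaves all three metrics unchanged
  moved <- rigid_move(d, seed = 77)
  expect_equal(as.numeric(lrms(moved, toy$model, spec)),
               as.numeric(lrms(d, toy$model, spec)), tolerance = 1e-6)
  expect_equal(as.numeric(irms(moved, toy$model, spec)),
               as.numeric(irms(d, toy$model, spec)), tolerance = 1e-6)
  expect_equal(as.numeric(fnat(moved, toy$model, spec)),
               as.numeric(fnat(d, toy$model, spec)))
  # whole-complex rotation: irms exactly 0
  whole <- rigid_move(toy$model, seed = 31)
  expect_equal(as.numeric(irms(whole, toy$model, spec)), 0, tolerance = 1e-6)
})

test_that("quality classification applies the threshold ladder and is monotone", {
  expect_equal(classify_quality(0.9, 0.8, 0.4)$quality, "High")
  expect_equal(classify_quality(0.55, 1.5, 0.9)$quality, "Medium")
  expect_equal(classify_quality(0.0, 50, 30)$quality, "Incorrect")
  expect_equal(classify_quality(0.25, 4.0, 1.5)$quality, "Acceptable")
  expect_error(classify_quality(0.5, -1, 0.5), "out of range")
  # NA fnat: classified on RMS only, flagged
  na_cls <- classify_quality(NA, 0.8, 0.4)
  expect_true(na_cls$fnat_missing)
  expect_equal(na_cls$quality, "High")

  # monotonicity: improving one metric never lowers the class
  lvl <- c(Incorrect = 0, Acceptable = 1, Medium = 2, High = 3)
  set.seed(4)
  for (i in 1:200) {
    f <- runif(1); l <- runif(1, 0, 8); r <- runif(1, 0, 4)
    base <- lvl[[classify_quality(f, l, r)$quality]]
    expect_gte(lvl[[classify_quality(min(1, f + runif(1, 0, 0.3)), l, r)$quality]], base)
    expect_gte(lvl[[classify_quality(f, max(0, l - runif(1, 0, 2)), r)$quality]], base)
    expect_gte(lvl[[classify_quality(f, l, max(0, r - runif(1, 0, 1)))$quality]], base)
  }
})

test_that("capri_assess integrates the metrics for CA-only models too", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNE", receptor_size = 16,
                                             gap = 3))
  d <- make_decoy(toy$model, decoy_spec(translation = c(0.3, 0.2, 0)),
                  toy$spec)
  res <- capri_assess(d, toy$model, toy$spec)
  expect_s3_class(res, "capri_result")
  expect_equal(res$atoms_used, "backbone")
  expect_true(res$quality %in% c("High", "Medium", "Acceptable", "Incorrect"))

  # CA-only model: atom intersection drops to CA, fnat flagged low-confidence
  ca <- toy$model
  ca$atoms <- ca$atoms[ca$atoms$atom_name == "CA", ]
  res_ca <- capri_assess(ca, toy$model, toy$spec)
  expect_equal(res_ca$atoms_used, "CA")
  expect_true(res_ca$flags$fnat_low_confidence)
})

test_that("cohort summaries use strict comparison and half-up rounding", {
  t4 <- load_fixture("table4")
  expect_equal(summarize_cohort(t4$CA_Medoid, 1.0)$fraction_below, 13)
  expect_equal(summarize_cohort(t4$CA_Filtered, 1.0)$fraction_below, 33)
  expect_equal(summarize_cohort(t4$CA_Lowest, 1.0)$fraction_below, 67)
  expect_equal(summarize_cohort(c(0.1, 0.2), 1.0)$fraction_below, 100)
  # strict "<": a value equal to the threshold does not count
  expect_equal(summarize_cohort(c(1.0, 0.5), 1.0)$n_below, 1)
  expect_error(summarize_cohort(numeric(0), 1.0), "non-empty")
})
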