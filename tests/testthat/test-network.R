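test_that("hydrophobic contact typing follows the polarity table", {
  slab <- build_toy_slab_for_test()
  # Leu side-chain carbon 4.0 A above a slab CB
  leu <- leu_residue("C", 1, origin = c(2, 2, 0))
  leu$z <- leu$z + 4.0 - min(leu$z[leu$atom_name == "CD2"]) + 0  # CD2 at 4.0-ish
  m <- make_model(slab, leu)
  spec <- complex_spec("A", "C")
  ct <- type_contacts(m, spec)
  expect_gt(sum(ct$kind == "hydrophobic"), 0)

  # all-polar pair at 4.0 A: no hydrophobic contact
  ser_o <- atom_row("C", 1, "SER", "OG", 2, 2, 4, element = "O")
  polar <- make_model(atom_row("A", 1, "SER", "OG", 2, 2, 0, element = "O"),
                      ser_o)
  expect_equal(nrow(type_contacts(polar, spec)), 0)
})

test_that("typed contacts equal a brute-force typed scan on a random toy", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNEIR", receptor_size = 25,
                                             gap = 3))
  ct <- type_contacts(toy$model, toy$spec)
  hyd <- ct[ct$kind == "hydrophobic", ]
  # independent scan: apolar carbons on both sides within 4.5
  a <- toy$model$atoms
  apol <- function(side) {
    x <- a[a$chain == side & a$element == "C", ]
    x[mapply(function(rn, an) an %in% pepint:::apolar_carbons[[rn]],
             x$res_name, x$atom_name), ]
  }
  ra <- apol("A"); la <- apol("C")
  seen <- character(0)
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
    d <- sqrt(sum((c(ra$x[i], ra$y[i], ra$z[i]) -
                     c(la$x[j], la$y[j], la$z[j]))^2))
    if (d <= 4.5) {
      seen <- c(seen, paste(ra$res_seq[i], ra$atom_name[i],
                            la$res_seq[j], la$atom_name[j]))
    }
  }
  got <- paste(hyd$rec_res_seq, hyd$rec_atom, hyd$lig_res_seq, hyd$lig_atom)
  expect_setequal(got, seen)
})

test_that("per-residue counts conserve the contact total", {
  toy <- make_toy_complex(toy_complex_params("LSIEETNEIR", receptor_size = 25,
                                             gap = 3))
  ct <- type_contacts(toy$model, toy$spec)
  tab <- count_per_residue(ct, "toy")
  expect_equal(sum(tab$counts), nrow(ct))

  empty <- ct[0, ]
  tab0 <- count_per_residue(empty, "none", residue_labels = c("ALA-1", "GLY-2"))
  expect_equal(as.integer(tab0$counts), c(0L, 0L))

  three <- ct[rep(1, 3), ]
  tab3 <- count_per_residue(three, "x")
  expect_equal(as.integer(tab3$counts), 3L)
})

test_that("cooperativity score rewards clustering and is monotone in contacts", {
  expect_equal(cooperativity_score(data.frame()), 0)

  one_hb <- data.frame(rec_x = 0, rec_y = 0, rec_z = 0,
                       kind = "hydrogen_bond", stringsAsFactors = FALSE)
  expect_equal(cooperativity_score(one_hb, bonus = 0.1), 1.0)

  mk <- function(xs) data.frame(rec_x = xs, rec_y = 0, rec_z = 0,
                                kind = "hydrophobic", stringsAsFactors = FALSE)
  clustered <- mk(c(0, 1, 2, 3))        # all within 6 A of each other
  scattered <- mk(c(0, 20, 40, 60))     # all isolated
  expect_gt(cooperativity_score(clustered), cooperativity_score(scattered))
  # direct evaluation of the stated formula for the clustered set
  expect_equal(cooperativity_score(clustered, neighbor_radius = 6,
                                   bonus = 0.1),
               sum(0.5 * (1 + 0.1 * c(3, 3, 3, 3))))

  # removing any contact never increases the score
  toy <- make_toy_complex(toy_complex_params("LSIEETNEIR", receptor_size = 25,
                                             gap = 3))
  ct <- type_contacts(toy$model, toy$spec)
  full <- cooperativity_score(ct)
  for (drop in seq_len(min(nrow(ct), 8))) {
    expect_lte(cooperativity_score(ct[-drop, ]), full)
  }
})

test_that("hot-spot ranking reproduces the packaged interaction fixture", {
  tab <- load_fixture("table5")
  expect_equal(unname(colSums(tab$counts)),
               c(20L, 42L, 26L, 44L, 30L, 39L, 32L, 13L, 19L, 10L))
  rk <- rank_hotspots(tab, k = 5)
  expect_setequal(head(rk$residues, 5),
                  c("VAL-30", "ASP-26", "ASP-22", "LEU-33", "LYS-29"))
  expect_equal(rk$top_k_fraction, 68)

  # single nonzero column: 100% for any k >= 1
  single <- interaction_table(matrix(c(0L, 0L, 5L, 0L), 1,
                                     dimnames = list("p", paste0("ALA-", 1:4))))
  expect_equal(rank_hotspots(single, 1)$top_k_fraction, 100)
  # uniform counts over 10 residues, k = 5 -> 50%
  unif <- interaction_table(matrix(2L, 1, 10,
                                   dimnames = list("p", paste0("GLY-", 1:10))))
  expect_equal(rank_hotspots(unif, 5)$top_k_fraction, 50)
  # scale invariance
  rk10 <- rank_hotspots(interaction_table(tab$counts * 10L), 5)
  expect_equal(rk10$top_k_fraction, rk$top_k_fraction)
  expect_identical(rk10$residues, rk$residues)
  # deterministic tie-break toward the lower residue number
  tie <- interaction_table(matrix(c(3L, 3L), 1,
                                  dimnames = list("p", c("LYS-9", "ALA-2"))))
  expect_identical(rank_hotspots(tie, 1)$residues[1], "ALA-2")
})

test_that("score aggregation matches the published per-group mean", {
  tab <- load_fixture("table5")
  agg <- aggregate_scores(tab, paste0("Peptide-", 8:13))
  expect_equal(round(agg$mean + 1e-12, 2), 4.93)
  expect_equal(agg$n, 6)
  # mean bounded by the inputs
  expect_gte(agg$mean, min(tab$coop_scores))
  expect_lte(agg$mean, max(tab$coop_scores))

  one <- aggregate_scores(tab, "Peptide-11")
  expect_equal(one$mean, 2.5)
  expect_true(is.na(one$sd))
  expect_error(aggregate_scores(tab, "Peptide-99"), "no peptides")
})
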