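test_that("superposition of a structure onto itself is the identity", {
  p <- make_conformer_pair(8, seed = 4, rigid_motion = FALSE)
  sup <- iterative_superpose(p$a, p$a)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
})

test_that("a rigidly moved copy is recovered to zero RMSD and the transform inverts", {
  set.seed(7)
  p <- make_conformer_pair(10, seed = 7, rigid_motion = FALSE)
  R <- random_rotation_oracle(); tr <- c(5, -3, 12)
  moved <- rigid_move_structure(p$a, R, tr)
  sup <- iterative_superpose(moved, p$a)
  expect_lt(sup$rmsd, 1e-6)
  ## recovered rotation inverts the applied one
  expect_equal(sup$rotation, t(R), tolerance = 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
})

test_that("Kabsch fit dominates random rotations on random clouds", {
  set.seed(11)
  mobile <- matrix(rnorm(30), ncol = 3)
  reference <- matrix(rnorm(30), ncol = 3)
  best <- kabsch_rmsd_via_package(mobile, reference)
  rand <- replicate(1000, rmsd_given_rotation(mobile, reference,
                                              random_rotation_oracle()))
  expect_lte(best, min(rand) + 1e-12)
})

test_that("superposition RMSD matches an independent least-squares fit", {
  set.seed(3)
  a <- make_conformer_pair(12, seed = 3, rigid_motion = FALSE)$a
  b <- a
  b$atoms[c("x", "y", "z")] <- b$atoms[c("x", "y", "z")] +
    matrix(rnorm(nrow(b$atoms) * 3, sd = 0.4), ncol = 3)
  sup <- iterative_superpose(b, a, trim_sigma = Inf, max_cycles = 1)
  ## bio3d's closed-form fit on the same backbone pairing
  sel_a <- a$atoms$elety %in% c("N", "CA", "C")
  xyz_fixed <- as.numeric(t(as.matrix(a$atoms[sel_a, c("x", "y", "z")])))
  xyz_mob <- as.numeric(t(as.matrix(b$atoms[sel_a, c("x", "y", "z")])))
  r <- bio3d::rot.lsq(xyz_mob, xyz_fixed)
  rmsd_bio3d <- sqrt(mean(colSums(matrix(r - xyz_fixed, nrow = 3)^2)))
  expect_equal(sup$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("superposition RMSD is invariant to pre-applied rigid motions", {
  set.seed(9)
  p <- make_conformer_pair(10, seed = 9, rigid_motion = FALSE)
  b <- p$a
  b$atoms[c("x", "y", "z")] <- b$atoms[c("x", "y", "z")] +
    matrix(rnorm(nrow(b$atoms) * 3, sd = 0.5), ncol = 3)
  base <- iterative_superpose(b, p$a)$rmsd
  for (i in 1:3) {
    moved <- rigid_move_structure(b, random_rotation_oracle(),
                                  rnorm(3, sd = 10))
    expect_equal(iterative_superpose(moved, p$a)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("trimming drops outlier pairs and errors are signalled", {
  p <- make_conformer_pair(12, seed = 5, rigid_motion = FALSE)
  b <- p$a
  ## one backbone atom thrown far off: trimmed, near-zero final rmsd
  i <- which(b$atoms$resno == 6 & b$atoms$elety == "CA")
  b$atoms[i, c("x", "y", "z")] <- b$atoms[i, c("x", "y", "z")] + 40
  sup <- iterative_superpose(b, p$a)
  expect_lt(sup$rmsd, 0.5)
  expect_lt(length(sup$retained_pairs), sup$n_start)
  expect_error(iterative_superpose(
    as_at_structure(p$a$atoms[1:4, ]), as_at_structure(p$b$atoms[13:24, ])),
    "shared")
})

test_that("displacement scan recovers prescribed displacements through rigid motion", {
  p <- make_conformer_pair(10, displaced = list(`5` = c(3, 4, 0)), seed = 21)
  sup <- iterative_superpose(p$b, p$a)
  sc <- displacement_scan(p$b, p$a, sup)
  expect_s3_class(sc, "displacement_scan")
  expect_equal(sc$displacement[sc$resno == 5], 5, tolerance = 1e-6)
  expect_lt(max(sc$displacement[sc$resno != 5]), 1e-6)
  expect_identical(sc$rank[sc$resno == 5], 1L)
  ## ranking is a sorted permutation
  expect_identical(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$displacement) <= 1e-12))
})

test_that("identical conformers give an all-zero scan; two displacements rank in order", {
  p0 <- make_conformer_pair(6, seed = 1, rigid_motion = FALSE)
  sup0 <- iterative_superpose(p0$b, p0$a)
  expect_lt(max(displacement_scan(p0$b, p0$a, sup0)$displacement), 1e-9)

  p2 <- make_conformer_pair(9, displaced = list(`3` = c(2, 0, 0),
                                                `7` = c(0, 0, 7)), seed = 8)
  sc2 <- displacement_scan(p2$b, p2$a, iterative_superpose(p2$b, p2$a))
  expect_identical(sc2$resno[sc2$rank == 1], 7L)
  expect_identical(sc2$resno[sc2$rank == 2], 3L)
  expect_equal(sc2$displacement[sc2$rank == 1], 7, tolerance = 1e-6)
  expect_equal(sc2$displacement[sc2$rank == 2], 2, tolerance = 1e-6)
})

test_that("intra_pair_distance is a symmetric distal-carbon distance", {
  p <- make_conformer_pair(8, seed = 6, rigid_motion = FALSE)
  d <- intra_pair_distance(p$a, 2, 5)
  expect_gt(d, 0)
  expect_equal(d, intra_pair_distance(p$a, 5, 2))
  expect_equal(intra_pair_distance(p$a, 4, 4), 0)
  ## agrees with a direct coordinate computation
  c2 <- distal_side_chain_carbon(p$a, residue_keys(p$a)[[2]])$coords
  c5 <- distal_side_chain_carbon(p$a, residue_keys(p$a)[[5]])$coords
  expect_equal(d, sqrt(sum((c2 - c5)^2)), tolerance = 1e-12)
  expect_error(intra_pair_distance(p$a, 2, 99), "not found")
})

test_that("deviation maps report per-atom and per-residue RMS deviations", {
  p <- make_conformer_pair(7, seed = 10, rigid_motion = FALSE)
  ident <- list(rotation = diag(3), translation = c(0, 0, 0))
  dm0 <- deviation_map(p$a, p$a, ident)
  expect_lt(max(dm0$atoms$deviation), 1e-12)
  expect_lt(max(abs(dm0$residues$rmsd)), 1e-12)

  b <- p$a
  sel <- b$atoms$resno == 4
  b$atoms[sel, c("x", "y", "z")] <- b$atoms[sel, c("x", "y", "z")] +
    matrix(rep(c(2, 0, 0), each = sum(sel)), ncol = 3)
  dm <- deviation_map(b, p$a, ident)
  expect_equal(dm$residues$rmsd[dm$residues$resno == 4], 2, tolerance = 1e-9)
  expect_lt(max(dm$residues$rmsd[dm$residues$resno != 4]), 1e-12)
  ## per-residue value is the RMS of its atoms' deviations
  for (rn in unique(dm$residues$resno)) {
    at <- dm$atoms$deviation[grepl(paste0("^", rn, "\\|"), dm$atoms$key)]
    expect_equal(dm$residues$rmsd[dm$residues$resno == rn],
                 sqrt(mean(at^2)), tolerance = 1e-9)
  }
  ## color channel clipped, numeric output not
  b2 <- p$a
  b2$atoms[1, c("x", "y", "z")] <- b2$atoms[1, c("x", "y", "z")] + 20
  dm2 <- deviation_map(b2, p$a, ident, scale_max = 5)
  expect_gt(max(dm2$atoms$deviation), 5)
  expect_lte(max(dm2$atoms$color), 5)
  ## difference of a map with itself is zero
  diff0 <- deviation_map_diff(dm, dm)
  expect_lt(max(abs(diff0$atoms$deviation)), 1e-12)
  expect_lt(max(abs(diff0$residues$rmsd)), 1e-12)
  ## mismatched rosters error
  expect_error(deviation_map(as_at_structure(p$a$atoms[-1, ]), p$a, ident),
               "mismatch")
})
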