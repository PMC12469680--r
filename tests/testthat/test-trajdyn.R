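test_that("trajectory loading from multi-model PDB preserves frames and metadata", {
  tr <- make_trajectory(n_atoms = 5, n_frames = 12, mode_sds = 1,
                        noise_std = 0.05, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  ## write each frame as a MODEL block
  con <- file(f, "w")
  for (i in seq_len(12)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    for (j in 1:5)
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        j, j, tr$coords[i, j, 1], tr$coords[i, j, 2], tr$coords[i, j, 3]), con)
    writeLines("ENDMDL", con)
  }
  close(con)
  tr2 <- load_trajectory(f, spacing_ps = 20)
  expect_identical(dim(tr2$coords), c(12L, 5L, 3L))
  expect_identical(tr2$atoms$elety, rep("CA", 5))
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-3)

  ## mismatching rosters error with the offending frame named
  lines <- readLines(f)
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-3], bad)  # drop one atom from frame 1
  expect_error(load_trajectory(bad), "frame")
})

test_that("coordinate-matrix trajectories round-trip", {
  tr <- make_trajectory(n_atoms = 4, n_frames = 15, mode_sds = 1,
                        noise_std = 0.1, seed = 5)
  m <- do.call(cbind, lapply(1:4, function(j) tr$coords[, j, ]))
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  tr2 <- load_trajectory(f, spacing_ps = 10)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("frame-count arithmetic matches the production scale", {
  expect_identical(expected_frames(1000, 20), 50000L)
  n <- expected_frames(1000, 20)
  keep <- as.integer(ceiling(0.15 * n))
  expect_identical(keep, 7500L)
  expect_identical(n - keep + 1L, 42501L)  # first retained frame, 1-based
})

test_that("alignment removes rigid motion and windowing keeps trailing frames", {
  tr <- make_trajectory(n_atoms = 12, n_frames = 40, mode_sds = numeric(0),
                        noise_std = 0.2, seed = 4)
  ## rigid-body-only trajectory: every frame a rigid move of frame 1
  base <- tr$coords[1, , ]
  set.seed(42)
  for (i in 2:40) {
    R <- random_rotation_oracle()
    tr$coords[i, , ] <- sweep(base %*% R, 2, rnorm(3, sd = 8), `+`)
  }
  at <- align_and_window(tr, final_fraction = 1)
  dev <- vapply(seq_len(40), function(i)
    max(abs(at$coords[i, , ] - at$coords[1, , ])), numeric(1))
  expect_lt(max(dev), 1e-6)

  at2 <- align_and_window(tr, final_fraction = 0.15)
  expect_identical(dim(at2$coords)[[1]], 6L)   # ceil(0.15 * 40)
  expect_identical(at2$window_start, 35L)
  expect_identical(dim(align_and_window(tr, final_fraction = 1)$coords)[[1]], 40L)
})

test_that("PCA matches the brute-force covariance oracle and fixes signs", {
  ## single mode, no noise: rank-1 covariance
  tr1 <- make_trajectory(n_atoms = 15, n_frames = 60, mode_sds = 3,
                         noise_std = 0, seed = 6)
  at1 <- align_and_window(tr1, final_fraction = 1, align = FALSE)
  p1 <- ca_pca(at1, 5)
  expect_equal(p1$variance_ratios[[1]], 1, tolerance = 1e-9)

  ## two modes 4:1 variance, no noise: analytic 0.8 / 0.2
  tr2 <- make_trajectory(n_atoms = 20, n_frames = 100, mode_sds = c(2, 1),
                         noise_std = 0, seed = 7)
  at2 <- align_and_window(tr2, final_fraction = 1, align = FALSE)
  p2 <- ca_pca(at2, 5)
  expect_equal(p2$variance_ratios[1:2], c(0.8, 0.2), tolerance = 1e-9)

  ## mode + isotropic noise: implementation vs brute-force eigen oracle
  tr3 <- make_trajectory(n_atoms = 60, n_frames = 2000, mode_sds = 3,
                         noise_std = 0.1, seed = 13)
  at3 <- align_and_window(tr3, final_fraction = 1)
  p3 <- ca_pca(at3, 20)
  oracle <- oracle_pca_ratios(at3)
  expect_equal(p3$variance_ratios, oracle[1:20], tolerance = 1e-9)
  ## orthonormal components, non-increasing ratios, sign convention
  G <- crossprod(p3$components)
  expect_equal(G, diag(ncol(p3$components)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p3$variance_ratios) <= 1e-12))
  for (j in seq_len(ncol(p3$components))) {
    i <- which.max(abs(p3$components[, j]))
    expect_gt(p3$components[i, j], 0)
  }
  ## degenerate trajectory errors
  tr0 <- tr1; tr0$coords <- tr0$coords[rep(1, 20), , , drop = FALSE]
  at0 <- align_and_window(tr0, final_fraction = 1)
  expect_error(ca_pca(at0, 3), "no variance")
})

test_that("PCA after alignment is invariant to a uniform rigid motion of all frames", {
  tr <- make_trajectory(n_atoms = 10, n_frames = 80, mode_sds = c(2, 1),
                        noise_std = 0.05, seed = 9)
  set.seed(77)
  R <- random_rotation_oracle(); tv <- rnorm(3, sd = 15)
  tr2 <- tr
  for (i in seq_len(80))
    tr2$coords[i, , ] <- sweep(tr$coords[i, , ] %*% R, 2, tv, `+`)
  p1 <- ca_pca(align_and_window(tr, final_fraction = 1), 5)
  p2 <- ca_pca(align_and_window(tr2, final_fraction = 1), 5)
  expect_equal(p1$variance_ratios, p2$variance_ratios, tolerance = 1e-9)
})

test_that("PC-plane displacement measures head-to-tail drift", {
  fake <- structure(list(projections = cbind(rep(0, 100), rep(0, 100))),
                    class = "ca_pca")
  expect_equal(pc_plane_displacement(fake), 0)

  n <- 200
  s <- seq(0, 1, length.out = n)
  drift <- structure(list(projections = cbind(3 * s, 4 * s)),
                     class = "ca_pca")
  got <- pc_plane_displacement(drift, 0.05, 0.05)
  ## closed-form window means on the discrete ramp
  nh <- floor(0.05 * n)
  head_mean <- mean(s[1:nh]); tail_mean <- mean(s[(n - nh + 1):n])
  expect_equal(got, 5 * (tail_mean - head_mean), tolerance = 1e-12)
  expect_equal(got, 4.75, tolerance = 0.05)

  ## permuting frames within each window changes nothing
  P <- drift$projections
  perm <- c(sample(1:nh), (nh + 1):(n - nh), sample((n - nh + 1):n))
  drift2 <- structure(list(projections = P[perm, ]), class = "ca_pca")
  expect_equal(pc_plane_displacement(drift2, 0.05, 0.05), got, tolerance = 1e-12)
})

test_that("DCCM fixes: in-phase, anti-phase and null correlation structure", {
  ## identical fluctuation on every residue -> all entries 1
  n <- 40
  a <- rnorm(n)
  coords <- array(0, dim = c(n, 6, 3))
  for (j in 1:6) coords[, j, 1] <- 10 * j + a
  at <- structure(list(coords = coords,
                       atoms = data.frame(resno = 1:6, elety = "CA")),
                  class = "aligned_trajectory")
  cm <- residue_correlation(at)
  expect_true(all(abs(cm - 1) < 1e-9))

  ## two groups exactly anti-phase along one axis -> cross entries -1
  coords2 <- coords
  for (j in 4:6) coords2[, j, 1] <- 10 * j - a
  at2 <- structure(list(coords = coords2,
                        atoms = data.frame(resno = 1:6, elety = "CA")),
                   class = "aligned_trajectory")
  cm2 <- residue_correlation(at2)
  expect_true(all(abs(cm2[1:3, 4:6] + 1) < 1e-9))
  expect_true(all(abs(diag(cm2) - 1) < 1e-9))

  ## independent isotropic noise: off-diagonal 95th percentile < 0.1
  offdiag <- unlist(lapply(1:50, function(s) {
    tr <- make_trajectory(n_atoms = 20, n_frames = 1000,
                          mode_sds = numeric(0), noise_std = 0.3,
                          seed = 1000 + s)
    at <- align_and_window(tr, final_fraction = 1, align = FALSE)
    cm <- residue_correlation(at)
    abs(cm[upper.tri(cm)])
  }))
  expect_lt(unname(quantile(offdiag, 0.95)), 0.1)
})

test_that("DCCM agrees with an independent implementation and is rotation-invariant", {
  tr <- make_trajectory(n_atoms = 15, n_frames = 300, mode_sds = c(1.5, 0.8),
                        noise_std = 0.2, seed = 21)
  at <- align_and_window(tr, final_fraction = 1)
  cm <- residue_correlation(at)
  ## bio3d's DCCM on the same aligned coordinates
  X <- do.call(cbind, lapply(seq_len(15), function(j) at$coords[, j, ]))
  ref <- bio3d::dccm.xyz(X)
  expect_equal(unclass(cm), unclass(ref), tolerance = 1e-6, ignore_attr = TRUE)

  ## global rotation applied identically to all frames leaves the map unchanged
  set.seed(31)
  R <- random_rotation_oracle()
  at2 <- at
  for (i in seq_len(dim(at$coords)[[1]]))
    at2$coords[i, , ] <- at$coords[i, , ] %*% R
  cm2 <- residue_correlation(at2)
  expect_equal(unclass(cm), unclass(cm2), tolerance = 1e-9, ignore_attr = TRUE)

  ## zero-variance residue flagged as NA
  at3 <- at
  at3$coords[, 4, ] <- 0
  expect_warning(cm3 <- residue_correlation(at3), "zero-variance")
  expect_true(all(is.na(cm3[4, ])))
})

test_that("delta correlation is zero on itself, thresholded, and antisymmetric", {
  tr <- make_trajectory(n_atoms = 12, n_frames = 200, mode_sds = 1,
                        noise_std = 0.2, seed = 8)
  cm <- residue_correlation(align_and_window(tr, final_fraction = 1))
  d0 <- delta_correlation(cm, cm)
  expect_true(all(d0$delta == 0))
  expect_identical(nrow(d0$top_positive), 0L)
  expect_identical(nrow(d0$top_negative), 0L)

  tr2 <- make_trajectory(n_atoms = 12, n_frames = 200, mode_sds = 1,
                         noise_std = 0.2, seed = 88)
  cm2 <- residue_correlation(align_and_window(tr2, final_fraction = 1))
  fwd <- delta_correlation(cm2, cm, threshold = 0)
  rev <- delta_correlation(cm, cm2, threshold = 0)
  expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
  ## ranking swaps sides under target/reference exchange
  expect_equal(fwd$top_positive$delta_rho, -rev$top_negative$delta_rho,
               tolerance = 1e-12)
  ## threshold 0 keeps the raw matrix
  expect_equal(fwd$thresholded, fwd$delta)
  thr <- delta_correlation(cm2, cm, threshold = 0.5)
  expect_true(all(thr$thresholded[abs(thr$delta) < 0.5] == 0))

  ## mismatched indexing errors with the offending residues
  cm3 <- cm2[1:10, 1:10]
  class(cm3) <- class(cm2)
  expect_error(delta_correlation(cm3, cm), "mismatch|11")
})

test_that("injected block coupling is detected and ranked first", {
  sd_shared <- sqrt(3 * 0.3^2 * 0.7 / 0.3)   # analytic vector-DCCM rho = 0.7
  blocks <- list(a = 2:4, b = 15:17, sd = sd_shared)
  mut <- make_trajectory(n_atoms = 20, n_frames = 1500, mode_sds = numeric(0),
                         noise_std = 0.3, coupled_blocks = blocks, seed = 14)
  wt <- make_trajectory(n_atoms = 20, n_frames = 1500, mode_sds = numeric(0),
                        noise_std = 0.3, seed = 14)  # same seed: shared noise
  expect_equal(attr(mut, "truth")$block_correlation, 0.7, tolerance = 1e-9)
  cm_mut <- residue_correlation(align_and_window(mut, final_fraction = 1,
                                                 align = FALSE))
  cm_wt <- residue_correlation(align_and_window(wt, final_fraction = 1,
                                                align = FALSE))
  dc <- delta_correlation(cm_mut, cm_wt, threshold = 0.5, top_k = 15)
  ## the injected coupling clears the 0.5 threshold
  expect_gt(nrow(dc$top_positive), 0)
  in_blocks <- function(r) as.integer(r) %in% c(blocks$a, blocks$b)
  expect_true(all(in_blocks(dc$top_positive$res_i)))
  expect_true(all(in_blocks(dc$top_positive$res_j)))
  ## cross-block pairs are detected near the analytic value
  cross <- mean(dc$delta[as.character(blocks$a), as.character(blocks$b)])
  expect_equal(cross, 0.7, tolerance = 0.1)
})
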