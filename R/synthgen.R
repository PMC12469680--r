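## Seeded synthetic-data generators with known ground truth for every
## analysis stage. Identical seed and parameters give bit-identical output
## (Mersenne-Twister via a local RNG scope); each generator echoes its
## generating parameters back as the `truth` attribute, so every fixture
## carries its own answer key.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic conformer pair with prescribed distal-carbon displacements
#'
#' Builds two minimal polypeptide models on an idealized extended backbone:
#' each residue gets N, CA, C backbone atoms plus an explicitly placed distal
#' side-chain carbon (CE1 of histidine by default). The mobile copy displaces
#' the distal atoms of chosen residues by prescribed vectors and then
#' optionally applies a global rigid motion, so the scan's answer after
#' superposition is the displacement map itself.
#'
#' @param n_residues Number of residues (>= 3).
#' @param displaced Named list: residue number -> 3-vector displacement
#'   (Angstrom) applied to that residue's distal atom in the second copy.
#' @param seed RNG seed (used for the rigid motion).
#' @param rigid_motion Apply a random rotation + translation to the whole
#'   second copy? Default `TRUE`.
#' @param resid Residue type used for all residues (default `"HIS"`, distal
#'   carbon CE1).
#' @return List of two `at_structure`s (`a`, `b`) with attribute `truth`
#'   (the displacement map).
#' @export
make_conformer_pair <- function(n_residues, displaced = list(), seed = 1,
                                rigid_motion = TRUE, resid = "HIS") {
  if (n_residues < 3) stop("need at least 3 residues", call. = FALSE)
  keys <- as.integer(names(displaced))
  if (length(displaced) && (any(is.na(keys)) || any(keys < 1 | keys > n_residues)))
    stop("displacement map keys outside residue range", call. = FALSE)
  distal <- distal_atom_table()[[resid]][[1]]

  one <- function(i) {
    base <- c(3.8 * i, 0, 0)            # extended-chain CA spacing ~3.8 A
    data.frame(
      chain = "A", resno = i, insert = "",
      resid = resid,
      elety = c("N", "CA", "C", distal),
      x = base[1] + c(-1.2, 0, 1.2, 0.3),
      y = base[2] + c(0.3, 0, 0.4, 1.8),
      z = base[3] + c(0, 0, 0, 1.1),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_residues), one))
  a <- as_at_structure(atoms, id = "synthetic-ref")

  atoms_b <- atoms
  for (r in names(displaced)) {
    sel <- atoms_b$resno == as.integer(r) & atoms_b$elety == distal
    v <- as.numeric(displaced[[r]])
    atoms_b[sel, c("x", "y", "z")] <-
      atoms_b[sel, c("x", "y", "z")] +
      matrix(v, nrow = sum(sel), ncol = 3, byrow = TRUE)
  }
  if (rigid_motion) {
    with_seed(seed, {
      R <- random_rotation()
      t <- stats::runif(3, -20, 20)
      xyz <- as.matrix(atoms_b[c("x", "y", "z")]) %*% R
      atoms_b[c("x", "y", "z")] <- sweep(xyz, 2, t, `+`)
    })
  }
  b <- as_at_structure(atoms_b, id = "synthetic-mobile")
  structure(list(a = a, b = b), truth = displaced)
}

## uniform random rotation via QR of a Gaussian matrix, det +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Synthetic inhibition kinetics dataset
#'
#' Exponential progress curve A(t) = A0 exp(-k_obs t) with k_obs =
#' k2_true * inhibitor_conc / SI_true, sampled at `n_points` spanning about
#' three half-lives, with multiplicative Gaussian noise; plus a stoichiometry
#' titration declining linearly to zero at ratio = SI_true with additive
#' Gaussian noise.
#'
#' @param k2_true True second-order rate constant, 1/M/s.
#' @param inhibitor_conc Inhibitor concentration, M.
#' @param SI_true True stoichiometry of inhibition (>= 1).
#' @param noise_frac Multiplicative noise fraction for the curve (>= 0); the
#'   titration gets additive noise of `2 * noise_frac * A0` units.
#' @param n_points Points per dataset.
#' @param A0 Uninhibited activity (default 100).
#' @param seed RNG seed.
#' @return List with `curve` (a `progress_curve`), `titration` (data.frame
#'   ratio/activity) and attribute `truth`.
#' @export
make_kinetics_dataset <- function(k2_true = 4e3, inhibitor_conc = 5e-7,
                                  SI_true = 1, noise_frac = 0.02,
                                  n_points = 12, A0 = 100, seed = 1) {
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  stopifnot(k2_true > 0, inhibitor_conc > 0, SI_true >= 1)
  k_obs <- k2_true * inhibitor_conc / SI_true
  with_seed(seed, {
    times <- seq(0, 3 * log(2) / k_obs, length.out = n_points)
    act <- A0 * exp(-k_obs * times) *
      (1 + noise_frac * stats::rnorm(n_points))
    act <- pmax(act, 0)
    curve <- progress_curve(times, act, inhibitor_conc = inhibitor_conc,
                            protease_conc = inhibitor_conc / 20)
    ratios <- seq(0, 1.5 * SI_true, length.out = max(n_points, 7))
    tact <- pmax(A0 * (1 - ratios / SI_true), 0) +
      2 * noise_frac * A0 * stats::rnorm(length(ratios))
    structure(list(curve = curve,
                   titration = data.frame(ratio = ratios,
                                          activity = pmax(tact, 0))),
              truth = list(k2 = k2_true, k_obs = k_obs, SI = SI_true,
                           inhibitor_conc = inhibitor_conc, A0 = A0,
                           noise_frac = noise_frac, seed = seed))
  })
}

#' Synthetic van't Hoff melt curve
#'
#' Two-state melting fluorescence on the standard 20-85 C scan grid (2 C
#' steps through the transition region, 5 C steps in the far baselines) with
#' multiplicative Gaussian noise.
#'
#' @param Tm_true Melting temperature, Celsius, within 20-85.
#' @param dH_true Van't Hoff enthalpy, kcal/mol.
#' @param baselines List with `native` and `unfolded`, each
#'   `c(intercept, slope)` in units and units/K (defaults: drifting
#'   baselines with a 60% amplitude drop on unfolding).
#' @param noise_frac Multiplicative noise fraction.
#' @param seed RNG seed.
#' @return A `melt_curve` with attribute `truth`.
#' @export
make_melt_curve <- function(Tm_true = 63, dH_true = 150,
                            baselines = list(native = c(1000, -1.0),
                                             unfolded = c(500, -0.4)),
                            noise_frac = 0, seed = 1) {
  if (Tm_true < 20 || Tm_true > 85)
    stop("Tm outside the 20-85 C scan range", call. = FALSE)
  temps <- sort(unique(c(seq(20, 85, by = 5),
                         seq(max(20, Tm_true - 12), min(85, Tm_true + 12), by = 2))))
  T_K <- temps + 273.15
  f <- vant_hoff_model(T_K, Tm_true + 273.15, dH_true,
                       baselines$native[[1]], baselines$native[[2]],
                       baselines$unfolded[[1]], baselines$unfolded[[2]])
  if (noise_frac > 0)
    f <- with_seed(seed, f * (1 + noise_frac * stats::rnorm(length(f))))
  structure(melt_curve(temps, f),
            truth = list(Tm = Tm_true, dH = dH_true, baselines = baselines,
                         noise_frac = noise_frac, seed = seed))
}

#' Synthetic fluorescence concentration series with activation gain step
#'
#' Emulates the baseline-fluorescence titration followed by addition of
#' saturating heparin pentasaccharide: fluorescence rises linearly with
#' protein concentration (slope = baseline fluorescence), then the final
#' concentration is re-read after the pentasaccharide step with the
#' fluorescence scaled by (1 + gain). The wild-type preset is a 0.40 gain
#' read with 1% multiplicative noise.
#'
#' @param slope Baseline fluorescence, units per M.
#' @param gain True fractional gain on saturation (WT preset 0.40).
#' @param conc Concentration grid, M.
#' @param noise_frac Multiplicative noise fraction (default 0.01).
#' @param n_sat Replicate reads of the saturated endpoint (default 5).
#' @param seed RNG seed.
#' @return List with `series` (data.frame conc_M/fluorescence),
#'   `saturated` (replicate endpoint reads, units) and attribute `truth`.
#' @export
make_fluorescence_series <- function(slope = 2e8, gain = 0.40,
                                     conc = seq(1e-7, 1e-6, length.out = 8),
                                     noise_frac = 0.01, n_sat = 5, seed = 1) {
  with_seed(seed, {
    f <- slope * conc * (1 + noise_frac * stats::rnorm(length(conc)))
    f_sat <- slope * conc[[length(conc)]] * (1 + gain) *
      (1 + noise_frac * stats::rnorm(n_sat))
    structure(list(series = data.frame(conc_M = conc, fluorescence = f),
                   saturated = f_sat),
              truth = list(slope = slope, gain = gain,
                           noise_frac = noise_frac, seed = seed))
  })
}

#' Synthetic trajectory built from collective modes plus isotropic noise
#'
#' Frame t = base + sum_i a_i(t) v_i + noise, with mode amplitudes a_i
#' zero-mean Gaussian of the stated standard deviations and the mode vectors
#' orthonormalized internally. An optional coupled-blocks mode adds a shared
#' Gaussian amplitude along one axis to two residue blocks, injecting a known
#' residue-residue correlation (see `truth$block_correlation` for the
#' analytic value given the block mode std and noise std).
#'
#' @param n_atoms Number of C-alpha atoms.
#' @param n_frames Number of frames (> 10).
#' @param mode_sds Standard deviations of the collective-mode amplitudes
#'   (one mode per entry); may be empty when noise_std > 0.
#' @param noise_std Isotropic per-coordinate noise standard deviation.
#' @param coupled_blocks Optional list `list(a = idx, b = idx, sd = s)`:
#'   atoms in blocks a and b share an extra x-axis mode of amplitude std `s`.
#' @param spacing_ps Frame spacing, ps.
#' @param seed RNG seed.
#' @return A `trajectory` with attribute `truth` (modes, sds, analytic
#'   variance ratios for the noise-free case, and analytic block
#'   correlation).
#' @export
make_trajectory <- function(n_atoms = 30, n_frames = 500,
                            mode_sds = c(2, 1), noise_std = 0.1,
                            coupled_blocks = NULL, spacing_ps = 20, seed = 1) {
  if (n_frames <= 10) stop("need more than 10 frames", call. = FALSE)
  if (length(mode_sds) == 0 && noise_std <= 0 && is.null(coupled_blocks))
    stop("degenerate: zero modes and zero noise", call. = FALSE)
  n3 <- 3 * n_atoms
  with_seed(seed, {
    base <- matrix(stats::rnorm(n3, sd = 10), ncol = 3)
    V <- NULL
    if (length(mode_sds)) {
      M <- matrix(stats::rnorm(n3 * length(mode_sds)), nrow = n3)
      V <- qr.Q(qr(M))[, seq_along(mode_sds), drop = FALSE]  # orthonormal modes
    }
    ## amplitudes: Gaussian draws, then centered and orthogonalized so the
    ## sample covariance is exactly diag(mode_sds^2) -- the noise-free
    ## variance ratios are analytic, not merely asymptotic
    amp <- NULL
    if (length(mode_sds)) {
      A <- matrix(stats::rnorm(n_frames * length(mode_sds)), nrow = n_frames)
      A <- sweep(A, 2, colMeans(A))
      Q <- qr.Q(qr(A))
      amp <- Q %*% diag(mode_sds * sqrt(n_frames - 1), length(mode_sds))
      amp <- sweep(amp, 2, colMeans(amp))
    }

    X <- matrix(rep(as.vector(t(base)), each = n_frames), nrow = n_frames)
    if (!is.null(V)) X <- X + amp %*% t(V)
    if (noise_std > 0) X <- X + matrix(stats::rnorm(n_frames * n3, sd = noise_std),
                                       nrow = n_frames)
    block_cor <- NULL
    if (!is.null(coupled_blocks)) {
      shared <- stats::rnorm(n_frames, sd = coupled_blocks$sd)
      cols_x <- function(idx) 3 * (idx - 1) + 1      # x-coordinate columns
      for (i in c(coupled_blocks$a, coupled_blocks$b))
        X[, cols_x(i)] <- X[, cols_x(i)] + shared
      ## analytic displacement-vector correlation between an atom in block a
      ## and one in block b: cov(dr_i, dr_j) = s^2 (x axis only); per-atom
      ## variance |dr|^2 = s^2 + 3 noise^2. Exact only when mode_sds is empty
      ## (dense random modes add variance shared by all atoms).
      s2 <- coupled_blocks$sd^2
      block_cor <- s2 / (s2 + 3 * noise_std^2)
    }
    coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
    for (k in 1:3) coords[, , k] <- X[, seq(k, by = 3, length.out = n_atoms)]
    tr <- trajectory(coords, spacing_ps = spacing_ps, id = "synthetic")
    var_ratio <- if (length(mode_sds) && noise_std == 0)
      mode_sds^2 / sum(mode_sds^2) else NULL
    structure(tr, truth = list(mode_sds = mode_sds, noise_std = noise_std,
                               variance_ratios = var_ratio,
                               block_correlation = block_cor,
                               coupled_blocks = coupled_blocks, seed = seed))
  })
}

#' Synthetic mutant rate table from an energy model
#'
#' Rates follow k2(S) = k2_wt * exp[sum of single-mutation energies in S /
#' (R T)] * exp[-sum of pairwise interaction energies within S / (R T)], so
#' [coupling_index()] recovers each pairwise energy exactly:
#' CI(a,b) = exp(e_ab / (R T)).
#'
#' @param single_energies Named numeric: mutation -> kcal/mol effect on
#'   ln k2 (positive = activating).
#' @param pair_energies Named numeric: `"a:b"` -> interaction energy,
#'   kcal/mol.
#' @param k2_wt Wild-type rate, 1/M/s.
#' @param T Temperature, K.
#' @param subsets Which mutation subsets to tabulate; default all subsets of
#'   the named mutations.
#' @return A `mutant_rate_table` with attribute `truth`.
#' @export
make_rate_table <- function(single_energies, pair_energies = numeric(0),
                            k2_wt = 4e3, T = 298.15, subsets = NULL) {
  stopifnot(all(is.finite(single_energies)), all(is.finite(pair_energies)))
  muts <- names(single_energies)
  if (is.null(subsets)) {
    subsets <- list(character(0))
    for (m in muts) subsets <- c(subsets, lapply(subsets, c, m))
  }
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")
  k2 <- vapply(subsets, function(S) {
    e1 <- sum(single_energies[S])
    e2 <- 0
    if (length(S) > 1 && length(pair_energies)) {
      for (p in utils::combn(sort(S), 2, simplify = FALSE)) {
        k <- pair_key(p[[1]], p[[2]])
        if (k %in% names(pair_energies)) e2 <- e2 + pair_energies[[k]]
      }
    }
    k2_wt * exp(e1 / (R_GAS * T)) * exp(-e2 / (R_GAS * T))
  }, numeric(1))
  structure(mutant_rate_table(subsets, k2),
            truth = list(single_energies = single_energies,
                         pair_energies = pair_energies, k2_wt = k2_wt, T = T))
}
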