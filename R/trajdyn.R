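## Trajectory analysis: loading, per-frame rigid alignment, windowing,
## C-alpha principal component analysis, PC-plane displacement, dynamic
## cross-correlation maps (DCCM) and differential correlation ranking.
##
## A `trajectory` holds a frames x atoms x 3 array plus atom metadata; an
## `aligned_trajectory` is its C-alpha subset after per-frame Kabsch
## superposition onto a reference frame.

#' Build a trajectory object
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom), or a
#'   `frames x 3N` matrix (flattened x,y,z per atom).
#' @param atoms data.frame of atom metadata with at least `resno` and `elety`
#'   (plus optional `chain`, `resid`); one row per atom. If omitted, atoms
#'   are labelled CA with sequential residue numbers.
#' @param spacing_ps Frame spacing in picoseconds (> 0).
#' @param id Source identifier.
#' @return A `trajectory`.
#' @export
trajectory <- function(coords, atoms = NULL, spacing_ps = 20, id = "traj") {
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) %% 3 == 0)
    n_at <- ncol(coords) / 3
    arr <- array(NA_real_, dim = c(nrow(coords), n_at, 3))
    for (k in 1:3) arr[, , k] <- coords[, seq(k, by = 3, length.out = n_at)]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[[3]] == 3)
  if (spacing_ps <= 0) stop("frame spacing must be positive", call. = FALSE)
  n_at <- dim(coords)[[2]]
  if (is.null(atoms))
    atoms <- data.frame(chain = "A", resno = seq_len(n_at),
                        resid = "ALA", elety = "CA", stringsAsFactors = FALSE)
  if (nrow(atoms) != n_at) stop("atom metadata does not match coordinate atoms",
                                call. = FALSE)
  structure(list(coords = coords, atoms = atoms, spacing_ps = spacing_ps,
                 id = id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory '%s': %d frames x %d atoms, %.3g ps spacing (%.4g ns)\n",
              x$id, d[[1]], d[[2]], x$spacing_ps, d[[1]] * x$spacing_ps / 1000))
  invisible(x)
}

#' Expected frame count for a stated duration
#'
#' @param duration_ns Trajectory length, ns.
#' @param spacing_ps Save interval, ps.
#' @return Integer frame count (duration / spacing); 1000 ns at 20 ps gives
#'   50,000.
#' @export
expected_frames <- function(duration_ns, spacing_ps) {
  as.integer(round(duration_ns * 1000 / spacing_ps))
}

#' Load a trajectory from a multi-model PDB or a coordinate-matrix file
#'
#' Multi-model PDB frames are ordered by MODEL number; every model must share
#' one atom roster. The plain-text alternative is a whitespace-delimited
#' matrix, one frame per row, columns x1 y1 z1 x2 y2 z2 ...
#'
#' @param path File path; format from extension (`.pdb` vs anything else) or
#'   `format`.
#' @param spacing_ps Frame spacing, ps.
#' @param format `"auto"`, `"pdb"` or `"matrix"`.
#' @return A `trajectory`.
#' @export
load_trajectory <- function(path, spacing_ps = 20,
                            format = c("auto", "pdb", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) "pdb" else "matrix"
  if (format == "pdb") {
    frames <- split_pdb_models(path)
    rosters <- lapply(frames, function(f)
      paste(f$chain, f$resno, f$resid, f$elety, sep = "|"))
    for (i in seq_along(rosters))
      if (!identical(rosters[[i]], rosters[[1]]))
        stop("atom roster of frame ", i, " differs from frame 1", call. = FALSE)
    coords <- array(NA_real_, dim = c(length(frames), nrow(frames[[1]]), 3))
    for (i in seq_along(frames))
      coords[i, , ] <- as.matrix(frames[[i]][c("x", "y", "z")])
    atoms <- frames[[1]][c("chain", "resno", "resid", "elety")]
    trajectory(coords, atoms, spacing_ps, id = basename(path))
  } else {
    m <- as.matrix(utils::read.table(path))
    coords <- array(NA_real_, dim = c(nrow(m), ncol(m) / 3, 3))
    for (k in 1:3) coords[, , k] <- m[, seq(k, ncol(m), by = 3)]
    trajectory(coords, NULL, spacing_ps, id = basename(path))
  }
}

## Minimal multi-model PDB reader: MODEL/ENDMDL blocks of ATOM records. A file
## without MODEL records is a single frame.
split_pdb_models <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    blocks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(model_starts)) ends <- c(ends, length(lines))
    blocks <- Map(function(s, e) lines[s:e], model_starts, ends)
  }
  lapply(blocks, function(bl) {
    at <- bl[grepl("^ATOM  |^HETATM", bl)]
    if (length(at) == 0) stop("PDB frame without ATOM records", call. = FALSE)
    data.frame(
      elety = trimws(substr(at, 13, 16)),
      resid = trimws(substr(at, 18, 20)),
      chain = trimws(substr(at, 22, 22)),
      resno = as.integer(substr(at, 23, 26)),
      x = as.numeric(substr(at, 31, 38)),
      y = as.numeric(substr(at, 39, 46)),
      z = as.numeric(substr(at, 47, 54)),
      stringsAsFactors = FALSE)
  })
}

#' Align frames to a reference and keep the trailing window
#'
#' Restricts the trajectory to C-alpha atoms, rigidly superposes every frame
#' onto the chosen reference frame of the full (pre-window) trajectory with
#' the Kabsch algorithm, then keeps the last `ceil(final_fraction * n)`
#' frames. `final_fraction = 1` keeps all frames; the production analysis
#' window is the final 15%.
#'
#' @param traj A `trajectory`.
#' @param reference Reference frame index (default 1, the initial structure).
#' @param final_fraction Fraction of trailing frames to keep, in (0, 1].
#' @param align Perform the per-frame superposition? `FALSE` trusts the
#'   input frames as already expressed in a common frame (synthetic
#'   trajectories generated without global motion), where re-fitting would
#'   only fold collective displacements into the rigid-body correction.
#' @return An `aligned_trajectory`: `coords` (window frames x n_Ca x 3),
#'   `atoms` (C-alpha metadata), `window_start` (index of the first retained
#'   frame in the original trajectory), `reference`.
#' @export
align_and_window <- function(traj, reference = 1, final_fraction = 0.15,
                             align = TRUE) {
  stopifnot(final_fraction > 0, final_fraction <= 1)
  ca <- which(traj$atoms$elety == "CA")
  if (length(ca) < 3) stop("fewer than 3 C-alpha atoms", call. = FALSE)
  coords <- traj$coords[, ca, , drop = FALSE]
  n <- dim(coords)[[1]]
  ref <- coords[reference, , ]
  aligned <- coords
  if (align) {
    for (i in seq_len(n)) {
      sup <- kabsch(coords[i, , ], ref)
      aligned[i, , ] <- apply_transform(coords[i, , ], sup)
    }
  }
  keep_n <- as.integer(ceiling(final_fraction * n))
  start <- n - keep_n + 1L
  structure(list(coords = aligned[start:n, , , drop = FALSE],
                 atoms = traj$atoms[ca, , drop = FALSE],
                 window_start = start, reference = reference,
                 final_fraction = final_fraction,
                 spacing_ps = traj$spacing_ps, id = traj$id),
            class = "aligned_trajectory")
}

#' @export
print.aligned_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "aligned_trajectory '%s': %d frames (from frame %d) x %d C-alpha atoms\n",
    x$id, d[[1]], x$window_start, d[[2]]))
  invisible(x)
}

#' C-alpha principal component analysis of an aligned trajectory
#'
#' Flattens each frame's C-alpha coordinates to a 3N-vector, mean-centers
#' over the analysis window, and decomposes the covariance by singular value
#' decomposition. Components follow a fixed sign convention (the
#' largest-magnitude element of each component is positive) so projections
#' are reproducible across runs.
#'
#' @param atraj An `aligned_trajectory`.
#' @param n_components Number of leading components to keep (default 20).
#' @return A `ca_pca`: `components` (3N x k, orthonormal columns),
#'   `variance_ratios` (per kept PC, fractions of total variance),
#'   `projections` (frames x k), `mean` (3N), `sdev` (all singular-value
#'   scale). Methods: `print`, `summary`, `predict` (project new frames).
#' @export
ca_pca <- function(atraj, n_components = 20) {
  d <- dim(atraj$coords)
  ## canonical flatten: for atom j, columns (3j-2):(3j) are x,y,z
  X <- do.call(cbind, lapply(seq_len(d[[2]]), function(j) atraj$coords[, j, ]))
  n <- nrow(X)
  if (n <= n_components) n_components <- n - 1L
  if (n_components < 1) stop("need more frames than components", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-12) stop("no variance: all frames identical", call. = FALSE)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)                      # covariance eigenvalues
  total <- sum(ev)
  k <- min(n_components, sum(ev > 1e-14 * ev[[1]]))
  comps <- sv$v[, seq_len(k), drop = FALSE]
  proj <- Xc %*% comps
  ## sign convention: largest-|.| element of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) { comps[, j] <- -comps[, j]; proj[, j] <- -proj[, j] }
  }
  structure(list(components = comps, variance_ratios = ev[seq_len(k)] / total,
                 projections = proj, mean = mu,
                 eigenvalues = ev[seq_len(k)], total_variance = total,
                 n_frames = n),
            class = "ca_pca")
}

#' @export
print.ca_pca <- function(x, ...) {
  cat(sprintf("ca_pca: %d frames, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_frames, ncol(x$components), 100 * x$variance_ratios[[1]],
              if (length(x$variance_ratios) > 1) 100 * x$variance_ratios[[2]] else 0))
  invisible(x)
}

#' @export
summary.ca_pca <- function(object, ...) {
  print(object)
  v <- utils::head(object$variance_ratios, 10)
  cat("  variance ratios:", paste(sprintf("%.3f", v), collapse = " "), "\n")
  invisible(object)
}

#' @export
predict.ca_pca <- function(object, newdata, ...) {
  sweep(newdata, 2, object$mean) %*% object$components
}

#' Net displacement in the PC1-PC2 plane
#'
#' Euclidean distance between the mean (PC1, PC2) projection of the first
#' `head_fraction` of frames and that of the last `tail_fraction`: a scalar
#' summary of how far the system drifted in the essential subspace.
#'
#' @param pca A `ca_pca` with at least 2 components.
#' @param head_fraction,tail_fraction Window fractions in (0, 0.5], default
#'   0.05 each.
#' @return Dimensionless displacement (projection units).
#' @export
pc_plane_displacement <- function(pca, head_fraction = 0.05,
                                  tail_fraction = 0.05) {
  stopifnot(head_fraction > 0, head_fraction <= 0.5,
            tail_fraction > 0, tail_fraction <= 0.5)
  P <- pca$projections[, 1:2, drop = FALSE]
  n <- nrow(P)
  nh <- max(1L, floor(head_fraction * n)); nt <- max(1L, floor(tail_fraction * n))
  if (nh + nt > n) stop("windows overlap: too few frames", call. = FALSE)
  head_mean <- colMeans(P[seq_len(nh), , drop = FALSE])
  tail_mean <- colMeans(P[seq.int(n - nt + 1L, n), , drop = FALSE])
  sqrt(sum((tail_mean - head_mean)^2))
}

#' Residue-residue dynamic cross-correlation map (DCCM)
#'
#' Pearson correlation of C-alpha positional fluctuations. The default is the
#' displacement-vector correlation
#' rho_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) with dr the deviation
#' from the time-mean position; `mode = "per-coordinate"` instead averages
#' the three coordinate-wise Pearson coefficients. Residues with zero
#' fluctuation get NA rows/columns with a warning.
#'
#' @param atraj An `aligned_trajectory` with >= 10 frames.
#' @param mode `"vector"` (default) or `"per-coordinate"`.
#' @return A `dccm_matrix`: residues x residues symmetric matrix with unit
#'   diagonal, residue numbers as dimnames, `mode` attribute.
#' @export
residue_correlation <- function(atraj, mode = c("vector", "per-coordinate")) {
  mode <- match.arg(mode)
  d <- dim(atraj$coords)
  if (d[[1]] < 10) stop("need at least 10 frames", call. = FALSE)
  n_res <- d[[2]]
  mean_pos <- apply(atraj$coords, c(2, 3), mean)
  dr <- atraj$coords
  for (k in 1:3) dr[, , k] <- sweep(atraj$coords[, , k], 2, mean_pos[, k])

  if (mode == "vector") {
    ## inner products <dr_i . dr_j> via the three coordinate cross-products
    C <- matrix(0, n_res, n_res)
    for (k in 1:3) C <- C + crossprod(dr[, , k]) / d[[1]]
    v <- diag(C)
    zero <- v <= 1e-300
    denom <- sqrt(outer(v, v))
    rho <- C / denom
  } else {
    rho <- matrix(0, n_res, n_res)
    zero <- rep(FALSE, n_res)
    for (k in 1:3) {
      s <- apply(dr[, , k], 2, stats::sd)
      zk <- s <= 1e-300
      ck <- suppressWarnings(stats::cor(dr[, , k]))
      ck[zk, ] <- 0; ck[, zk] <- 0; diag(ck) <- 1
      rho <- rho + ck
      zero <- zero | zk
    }
    rho <- rho / 3
  }
  if (any(zero)) {
    warning("zero-variance residues: ",
            paste(atraj$atoms$resno[zero], collapse = ", "))
    rho[zero, ] <- NA_real_; rho[, zero] <- NA_real_
  }
  diag(rho)[!zero] <- 1
  rho <- (rho + t(rho)) / 2
  labels <- as.character(atraj$atoms$resno)
  dimnames(rho) <- list(labels, labels)
  structure(rho, mode = mode, n_frames = d[[1]], class = c("dccm_matrix", "matrix"))
}

#' Differential correlation map and ranked pair shifts
#'
#' Delta-rho = target - reference, computed entrywise on two DCCMs sharing a
#' residue indexing. Entries with |Delta-rho| below `threshold` are zeroed in
#' the thresholded copy (the raw matrix is preserved), and the `top_k` most
#' positive and most negative upper-triangle pairs are ranked.
#'
#' @param target,reference `dccm_matrix` objects with identical residue
#'   labels.
#' @param threshold Magnitude cutoff for the thresholded copy (default 0.5).
#' @param top_k Pairs to rank in each direction (default 25).
#' @return A `delta_correlation`: `delta` (raw), `thresholded`,
#'   `top_positive` and `top_negative` (data.frames: res_i, res_j, delta_rho),
#'   `threshold`.
#' @export
delta_correlation <- function(target, reference, threshold = 0.5, top_k = 25) {
  if (!identical(dimnames(target), dimnames(reference))) {
    a <- rownames(target); b <- rownames(reference)
    stop("residue indexing mismatch; symmetric difference: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "),
         call. = FALSE)
  }
  delta <- unclass(target) - unclass(reference)
  thr <- delta
  thr[abs(thr) < threshold] <- 0
  ut <- which(upper.tri(delta), arr.ind = TRUE)
  vals <- delta[ut]
  rank_side <- function(ord) {
    sel <- utils::head(ord, top_k)
    data.frame(res_i = rownames(delta)[ut[sel, 1]],
               res_j = colnames(delta)[ut[sel, 2]],
               delta_rho = vals[sel], stringsAsFactors = FALSE)
  }
  pos <- rank_side(order(-vals))
  neg <- rank_side(order(vals))
  pos <- pos[pos$delta_rho >= threshold, , drop = FALSE]
  neg <- neg[neg$delta_rho <= -threshold, , drop = FALSE]
  structure(list(delta = delta, thresholded = thr,
                 top_positive = pos, top_negative = neg,
                 threshold = threshold),
            class = "delta_correlation")
}

#' @export
print.delta_correlation <- function(x, ...) {
  cat(sprintf("delta_correlation: %d x %d, threshold %.2f; %d pairs >= +thr, %d <= -thr shown\n",
              nrow(x$delta), ncol(x$delta), x$threshold,
              nrow(x$top_positive), nrow(x$top_negative)))
  invisible(x)
}
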