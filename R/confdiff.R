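## Conformer comparison: iterative trimmed Kabsch superposition, per-residue
## distal-carbon displacement scanning, intra-structure residue-pair distances
## and per-atom/per-residue deviation maps.

## Closed-form least-squares rigid superposition (Kabsch, via SVD) of two
## matched n x 3 coordinate sets. Returns rotation R and translation t such
## that mobile %*% R + t approximates reference.
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))     # reflection guard
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)          # mobile %*% R aligns onto reference
  t <- unname(cr) - as.numeric(cm %*% R)
  list(rotation = R, translation = t)
}

apply_transform <- function(xyz, sup) {
  sweep(xyz %*% sup$rotation, 2, sup$translation, `+`)
}

## Matched backbone coordinate pairs shared by two structures. Pairing is by
## residue number + insertion code (both antithrombin entries use mature
## numbering), never by sequence alignment.
backbone_pairs <- function(a, b, atoms = c("N", "CA", "C")) {
  ka <- with(a$atoms, paste(resno, insert, elety, sep = "|"))
  kb <- with(b$atoms, paste(resno, insert, elety, sep = "|"))
  sel_a <- a$atoms$elety %in% atoms
  shared <- intersect(ka[sel_a], kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  list(keys = shared,
       a = as.matrix(a$atoms[ia, c("x", "y", "z")]),
       b = as.matrix(b$atoms[ib, c("x", "y", "z")]))
}

#' Iterative trimmed Kabsch superposition of two structures
#'
#' Repeated least-squares backbone alignment: each cycle fits the retained
#' atom pairs by the Kabsch algorithm, then drops pairs whose post-fit
#' deviation exceeds `trim_sigma` standard deviations of the deviation
#' distribution. Iteration stops when the retained set is stable or
#' `max_cycles` is reached; the reported RMSD is computed on the retained
#' pairs of the final fit.
#'
#' @param mobile,reference `at_structure` objects; `mobile` is mapped into the
#'   frame of `reference`.
#' @param atoms Backbone atom set used for the fit (default `N`, `CA`, `C`;
#'   add `"O"` to include carbonyl oxygens).
#' @param trim_sigma Outlier-rejection multiplier (default 2).
#' @param max_cycles Maximum trim cycles (default 5).
#' @return A `superposition`: list with `rotation` (3x3, det +1),
#'   `translation` (Angstrom), `rmsd` (Angstrom, retained pairs),
#'   `retained_pairs` (keys), `n_start`, `cycles_run`.
#' @export
iterative_superpose <- function(mobile, reference, atoms = c("N", "CA", "C"),
                                trim_sigma = 2, max_cycles = 5) {
  bp <- backbone_pairs(mobile, reference, atoms)
  n <- length(bp$keys)
  if (n < 3) stop("fewer than 3 shared backbone atom pairs", call. = FALSE)

  keep <- rep(TRUE, n)
  cycles <- 0L
  sup <- NULL
  repeat {
    if (sum(keep) < 3) stop("all atom pairs trimmed", call. = FALSE)
    sup <- kabsch(bp$a[keep, , drop = FALSE], bp$b[keep, , drop = FALSE])
    cycles <- cycles + 1L
    moved <- apply_transform(bp$a, sup)
    dev <- sqrt(rowSums((moved - bp$b)^2))
    if (cycles >= max_cycles) break
    cut <- mean(dev[keep]) + trim_sigma * stats::sd(dev[keep])
    new_keep <- keep & (dev <= cut)
    if (identical(new_keep, keep) || sum(new_keep) < 3) break
    keep <- new_keep
  }
  moved <- apply_transform(bp$a, sup)
  dev <- sqrt(rowSums((moved - bp$b)^2))
  structure(list(rotation = sup$rotation, translation = sup$translation,
                 rmsd = sqrt(mean(dev[keep]^2)),
                 retained_pairs = bp$keys[keep],
                 n_start = n, cycles_run = cycles,
                 atoms = atoms, trim_sigma = trim_sigma),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "superposition: rmsd %.3f A over %d/%d backbone pairs (%s), %d cycle(s)\n",
    x$rmsd, length(x$retained_pairs), x$n_start,
    paste(x$atoms, collapse = ","), x$cycles_run))
  invisible(x)
}

#' Per-residue distal side-chain carbon displacement scan
#'
#' Maps structure `a` into the frame of `b` with a precomputed superposition
#' and measures, for every residue shared by both models, the distance between
#' the most distal side-chain carbons (see [distal_side_chain_carbon()]).
#' Records are ranked by decreasing displacement; residues lacking a distal
#' carbon in either conformer (glycine, truncated side chains with no carbon)
#' are omitted.
#'
#' @param a,b `at_structure` objects (`a` is the mobile one the superposition
#'   was computed for).
#' @param sup `superposition` from [iterative_superpose()] mapping `a` onto
#'   `b`'s frame.
#' @param table Distal-carbon table.
#' @return A `displacement_scan`: data.frame with columns `resno`, `insert`,
#'   `resid`, `atom_a`, `atom_b`, `displacement` (Angstrom), `fallback`,
#'   `rank`, sorted by rank.
#' @export
displacement_scan <- function(a, b, sup, table = distal_atom_table()) {
  short <- function(k) sub("^[^|]*\\|", "", k)  # drop chain: pair across chains
  ka <- residue_keys(a); kb <- residue_keys(b)
  shared <- intersect(short(ka), short(kb))
  if (length(shared) == 0) stop("no shared residues", call. = FALSE)

  rows <- lapply(shared, function(k) {
    ra <- residue_rows(a, ka[match(k, short(ka))])
    rb <- residue_rows(b, kb[match(k, short(kb))])
    da <- distal_side_chain_carbon(ra, table = table)
    db <- distal_side_chain_carbon(rb, table = table)
    if (is.na(da$atom) || is.na(db$atom)) return(NULL)
    pa <- as.numeric(c(da$coords) %*% sup$rotation) + sup$translation
    part <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(resno = as.integer(part[[1]]),
               insert = if (length(part) > 2) part[[2]] else "",
               resid = part[[length(part)]],
               atom_a = da$atom, atom_b = db$atom,
               displacement = sqrt(sum((pa - db$coords)^2)),
               fallback = da$fallback || db$fallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no residues with distal carbons in both models",
                                           call. = FALSE)
  out <- out[order(-out$displacement, out$resno), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("displacement_scan", "data.frame")
  out
}

#' @export
print.displacement_scan <- function(x, n = 10, ...) {
  cat(sprintf("displacement_scan: %d residues; top %d by displacement (A):\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 3)
  invisible(x)
}

#' Distance between two residues' distal side-chain carbons
#'
#' Plain Euclidean distance within one structure; no superposition involved.
#' Symmetric in its residue arguments.
#'
#' @param s An `at_structure`.
#' @param res_a,res_b Residue numbers (optionally with insertion code, e.g.
#'   `"120"` or `120` or `"27A"`).
#' @param table Distal-carbon table.
#' @return Distance in Angstrom.
#' @export
intra_pair_distance <- function(s, res_a, res_b, table = distal_atom_table()) {
  find <- function(r) {
    r <- as.character(r)
    m <- regmatches(r, regexec("^([0-9]+)([A-Za-z]?)$", r))[[1]]
    if (length(m) == 0) stop("bad residue spec: ", r, call. = FALSE)
    sel <- s$atoms$resno == as.integer(m[[2]]) & s$atoms$insert == m[[3]]
    if (!any(sel)) stop("residue not found: ", r, call. = FALSE)
    distal_side_chain_carbon(s$atoms[sel, , drop = FALSE], table = table)
  }
  da <- find(res_a); db <- find(res_b)
  if (is.na(da$atom)) stop("no distal carbon for residue ", res_a, call. = FALSE)
  if (is.na(db$atom)) stop("no distal carbon for residue ", res_b, call. = FALSE)
  sqrt(sum((da$coords - db$coords)^2))
}

#' Per-atom and per-residue deviation map between superposed structures
#'
#' Computes the deviation of every matched atom after mapping `a` into `b`'s
#' frame, and the per-residue root-mean-square of those atom deviations.
#' Numeric output is never clipped; `scale_max` only caps the `color` channel
#' intended for structure-painting exports.
#'
#' @param a,b `at_structure` objects with matched atom sets (equal rosters
#'   after pairing by residue number, insertion code and atom name).
#' @param sup `superposition` mapping `a` onto `b`.
#' @param scale_max Color-channel cap in Angstrom (default 5).
#' @return A `deviation_map`: list with `atoms` (data.frame: key, deviation,
#'   color) and `residues` (data.frame: resno, insert, resid, rmsd).
#' @export
deviation_map <- function(a, b, sup, scale_max = 5) {
  ka <- with(a$atoms, paste(resno, insert, resid, elety, sep = "|"))
  kb <- with(b$atoms, paste(resno, insert, resid, elety, sep = "|"))
  if (length(ka) != length(kb) || !setequal(ka, kb))
    stop("atom-count/roster mismatch between structures", call. = FALSE)
  ib <- match(ka, kb)
  moved <- apply_transform(as.matrix(a$atoms[c("x", "y", "z")]), sup)
  dev <- sqrt(rowSums((moved - as.matrix(b$atoms[ib, c("x", "y", "z")]))^2))
  atoms <- data.frame(key = ka, deviation = dev,
                      color = pmin(pmax(dev, 0), scale_max),
                      stringsAsFactors = FALSE)
  rk <- with(a$atoms, paste(resno, insert, resid, sep = "|"))
  per_res <- vapply(split(dev, rk), function(d) sqrt(mean(d^2)), numeric(1))
  ord <- match(unique(rk), names(per_res))
  part <- do.call(rbind, strsplit(names(per_res)[ord], "|", fixed = TRUE))
  residues <- data.frame(resno = as.integer(part[, 1]), insert = part[, 2],
                         resid = part[, 3], rmsd = unname(per_res[ord]),
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues, scale_max = scale_max),
            class = "deviation_map")
}

#' Difference of two deviation maps
#'
#' Signed per-atom and per-residue differences (e.g. mutant minus wild type).
#' Maps must share atom keys.
#'
#' @param x,y `deviation_map` objects.
#' @return A `deviation_map` with signed `deviation`/`rmsd` columns.
#' @export
deviation_map_diff <- function(x, y) {
  if (!setequal(x$atoms$key, y$atoms$key))
    stop("deviation maps cover different atoms", call. = FALSE)
  i <- match(x$atoms$key, y$atoms$key)
  atoms <- x$atoms
  atoms$deviation <- x$atoms$deviation - y$atoms$deviation[i]
  atoms$color <- pmin(pmax(atoms$deviation, -x$scale_max), x$scale_max)
  rkx <- with(x$residues, paste(resno, insert, resid, sep = "|"))
  rky <- with(y$residues, paste(resno, insert, resid, sep = "|"))
  residues <- x$residues
  residues$rmsd <- x$residues$rmsd - y$residues$rmsd[match(rkx, rky)]
  structure(list(atoms = atoms, residues = residues, scale_max = x$scale_max),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat(sprintf("deviation_map: %d atoms, %d residues; per-residue rmsd range %.3f-%.3f A\n",
              nrow(x$atoms), nrow(x$residues),
              min(x$residues$rmsd), max(x$residues$rmsd)))
  invisible(x)
}
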