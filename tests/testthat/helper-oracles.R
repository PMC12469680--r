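## Independent oracles used across the suite. These stay deliberately
## separate from the package's own code paths: the bond-graph BFS works from
## raw residue connectivity, the PCA oracle from a brute-force covariance
## eigen-decomposition, and the Kabsch check from random-rotation search.

## --- side-chain bond graphs of the 20 standard residues ------------------
## Edges within the side chain (plus CA anchor). PRO's CD-N closure is listed
## so the oracle can demonstrate that the side-chain traversal must not use
## the backbone shortcut.
side_chain_edges <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","NE"),
             c("NE","CZ"), c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CA","CB"), c("CB","SG")),
  GLN = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","NE2")),
  GLU = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","OE2")),
  GLY = list(),
  HIS = list(c("CA","CB"), c("CB","CG"), c("CG","ND1"), c("CG","CD2"),
             c("ND1","CE1"), c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","CE"),
             c("CE","NZ")),
  MET = list(c("CA","CB"), c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CA","CB"), c("CB","CG"), c("CG","CD")),
  SER = list(c("CA","CB"), c("CB","OG")),
  THR = list(c("CA","CB"), c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","NE1"), c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"),
             c("CE2","CZ2"), c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"),
             c("CZ","OH")),
  VAL = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"))
)

## BFS bond distances from CA over the side-chain graph; returns named
## distances for every atom reached.
bfs_from_ca <- function(resid) {
  edges <- side_chain_edges[[resid]]
  if (length(edges) == 0) return(stats::setNames(numeric(0), character(0)))
  adj <- list()
  for (e in edges) {
    adj[[e[[1]]]] <- c(adj[[e[[1]]]], e[[2]])
    adj[[e[[2]]]] <- c(adj[[e[[2]]]], e[[1]])
  }
  dist <- c(CA = 0)
  queue <- "CA"
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    for (v in adj[[u]]) if (is.null(dist[v]) || is.na(dist[v])) {
      dist[v] <- dist[[u]] + 1
      queue <- c(queue, v)
    }
  }
  dist[names(dist) != "CA"]
}

## Most distal side-chain carbons by BFS (may be a tied set).
oracle_distal_carbons <- function(resid) {
  d <- bfs_from_ca(resid)
  carbons <- d[grepl("^C", names(d))]
  if (length(carbons) == 0) return(character(0))
  names(carbons)[carbons == max(carbons)]
}

## --- rigid geometry helpers ----------------------------------------------
random_rotation_oracle <- function() {
  repeat {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1-2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
                  2*(x*y + w*z), 1-2*(x^2+z^2), 2*(y*z - w*x),
                  2*(x*z - w*y), 2*(y*z + w*x), 1-2*(x^2+y^2)),
                nrow = 3, byrow = TRUE)
    if (abs(det(R) - 1) < 1e-9) return(R)
  }
}

## Best achievable RMSD for a fixed rotation (translation optimized by
## centering both clouds).
rmsd_given_rotation <- function(mobile, reference, R) {
  P <- sweep(mobile, 2, colMeans(mobile)) %*% R
  Q <- sweep(reference, 2, colMeans(reference))
  sqrt(mean(rowSums((P - Q)^2)))
}

## Apply a rigid motion to the atom table of an at_structure.
rigid_move_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% R
  s$atoms[c("x", "y", "z")] <- sweep(xyz, 2, t, `+`)
  s
}

## Brute-force covariance PCA: eigenvalues of the sample covariance of the
## flattened frames (independent of the package's SVD route).
oracle_pca_ratios <- function(atraj) {
  d <- dim(atraj$coords)
  X <- do.call(cbind, lapply(seq_len(d[[2]]), function(j) atraj$coords[, j, ]))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

## Package-route RMSD of a plain point-cloud pair (wrapped as CA-only
## structures so the public superposition surface is exercised).
kabsch_rmsd_via_package <- function(mobile, reference) {
  mk <- function(m) as_at_structure(data.frame(
    chain = "A", resno = seq_len(nrow(m)), insert = "", resid = "ALA",
    elety = "CA", x = m[, 1], y = m[, 2], z = m[, 3],
    stringsAsFactors = FALSE))
  iterative_superpose(mk(mobile), mk(reference), atoms = "CA",
                      trim_sigma = Inf, max_cycles = 1)$rmsd
}
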