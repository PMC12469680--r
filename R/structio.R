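## Structure input and residue topology services.
##
## Structures are held as an `at_structure`: a light S3 wrapper around an atom
## table (one row per atom after altloc resolution) with the accession id and
## the parsing choices stamped on as attributes. Coordinates are Angstrom and
## residue numbering is always the file's own numbering (mature antithrombin
## numbering for the entries this package targets) -- never renumbered.

#' Ordered distal side-chain carbon table
#'
#' For each standard amino acid, the side-chain carbon atom names ordered by
#' decreasing bond-graph distance from CA, traversing the side chain only
#' (CA to CB onward; the proline backbone-nitrogen shortcut is excluded, so
#' PRO ends at CD). Only carbons are listed: LYS stops at CE (NZ is nitrogen),
#' ARG at CZ, MET at CE (reached through SD). Glycine has no side-chain carbon
#' and maps to an empty vector.
#'
#' Within one bond-graph distance, topologically equivalent carbons (LEU
#' CD1/CD2, VAL CG1/CG2, ILE branch) are listed in lexicographic order; ties
#' are broken at lookup time by Euclidean distance from CA in the conformer at
#' hand (see [distal_side_chain_carbon()]).
#'
#' @return Named list: residue 3-letter code -> character vector of carbon
#'   atom names, most distal first.
#' @export
distal_atom_table <- function() {
  list(
    ALA = c("CB"),
    ARG = c("CZ", "CD", "CG", "CB"),
    ASN = c("CG", "CB"),
    ASP = c("CG", "CB"),
    CYS = c("CB"),
    GLN = c("CD", "CG", "CB"),
    GLU = c("CD", "CG", "CB"),
    GLY = character(0),
    HIS = c("CE1", "CD2", "CG", "CB"),
    ILE = c("CD1", "CG1", "CG2", "CB"),
    LEU = c("CD1", "CD2", "CG", "CB"),
    LYS = c("CE", "CD", "CG", "CB"),
    MET = c("CE", "CG", "CB"),
    PHE = c("CZ", "CE1", "CE2", "CD1", "CD2", "CG", "CB"),
    PRO = c("CD", "CG", "CB"),
    SER = c("CB"),
    THR = c("CG2", "CB"),
    TRP = c("CH2", "CZ2", "CZ3", "CE2", "CE3", "CD1", "CD2", "CG", "CB"),
    TYR = c("CZ", "CE1", "CE2", "CD1", "CD2", "CG", "CB"),
    VAL = c("CG1", "CG2", "CB")
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses one chain of a PDB entry into an `at_structure`. Alternate locations
#' are resolved to a single conformer per atom, waters and heteroatoms are
#' excluded by default, and residue numbering is preserved exactly as in the
#' file.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier, or `"auto"` to pick the first chain that
#'   contains residue 393 (the serpin P1 position; falls back to the first
#'   chain if none does). Multi-copy asymmetric units are common for
#'   antithrombin crystals, so the chain is an explicit choice.
#' @param altloc_policy `"highest-occupancy"` (default) keeps, for each atom
#'   with alternate locations, the location with the highest occupancy
#'   (first on ties); `"first"` keeps the first location in file order.
#' @param include_het Keep non-water HETATM records? Default `FALSE`.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return An `at_structure`: list with `id`, `chain`, and `atoms`, a
#'   data.frame with columns `chain`, `resno`, `insert`, `resid`, `elety`
#'   (atom name), `elesy` (element), `x`, `y`, `z`, `o` (occupancy), `altloc`.
#' @export
read_structure <- function(path, chain = "auto",
                           altloc_policy = c("highest-occupancy", "first"),
                           include_het = FALSE, id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  if (identical(chain, "auto")) {
    chains <- unique(at$chain)
    hit <- chains[vapply(chains, function(ch)
      any(at$resno[at$chain == ch] == 393), logical(1))]
    chain <- if (length(hit)) hit[[1]] else chains[[1]]
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0)
    stop("chain not found or empty: '", chain, "'", call. = FALSE)

  at <- resolve_altloc(at, altloc_policy)
  if (nrow(at) == 0) stop("zero protein residues after filtering", call. = FALSE)

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z, o = at$o, altloc = at$alt,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  structure(
    list(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
         chain = chain, atoms = atoms),
    altloc_policy = altloc_policy,
    class = "at_structure"
  )
}

## One conformer per atom: group by (resno, insert, resid, atom name), keep a
## single row per group according to the policy. Atoms without altlocs pass
## through untouched.
resolve_altloc <- function(at, policy) {
  key <- paste(at$resno, at$insert, at$resid, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    if (policy == "first") idx[[1]]
    else idx[[which.max(at$o[idx])]]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Construct an `at_structure` from an atom table
#'
#' Low-level constructor used by the synthetic generators and tests.
#'
#' @param atoms data.frame with at least `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`; missing `elesy`, `o`, `altloc` are filled.
#' @param id Structure identifier.
#' @param chain Chain id recorded on the object (default from the table).
#' @return An `at_structure`.
#' @export
as_at_structure <- function(atoms, id = "synthetic", chain = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(atoms$elesy)) atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  structure(list(id = id,
                 chain = if (is.null(chain)) atoms$chain[[1]] else chain,
                 atoms = atoms),
            class = "at_structure")
}

#' @export
print.at_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("at_structure '%s'  chain %s: %d residues, %d atoms\n",
              x$id, x$chain, length(rk), nrow(x$atoms)))
  invisible(x)
}

#' Unique residue keys of a structure
#'
#' @param s An `at_structure`.
#' @return Character vector `"<chain>|<resno>|<insert>|<resid>"` in file order.
#' @export
residue_keys <- function(s) {
  a <- s$atoms
  unique(paste(a$chain, a$resno, a$insert, a$resid, sep = "|"))
}

## Rows of the atom table belonging to one residue key.
residue_rows <- function(s, key) {
  a <- s$atoms
  k <- paste(a$chain, a$resno, a$insert, a$resid, sep = "|")
  a[k == key, , drop = FALSE]
}

#' Write a structure back to PDB text
#'
#' Round-trip companion of [read_structure()]; residue keys and coordinates
#' survive a write/re-read cycle to 1e-3 Angstrom (the PDB fixed-format
#' precision).
#'
#' @param s An `at_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resid, eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  invisible(path)
}

#' Locate the most distal side-chain carbon of a residue
#'
#' Returns the side-chain carbon with maximal bond-graph distance from CA
#' (see [distal_atom_table()]). If the top-ranked atom is missing from the
#' model, the next entry in the table is used and the fallback is flagged.
#' Ties at equal bond-graph distance are broken by larger Euclidean distance
#' from CA in this conformer, then lexicographic atom name, so the choice is
#' deterministic and conformer-aware.
#'
#' @param residue One residue's atom rows (as returned by the internal
#'   residue accessor), or an `at_structure` together with `key`.
#' @param key Residue key (required when `residue` is an `at_structure`).
#' @param table Distal-carbon table; default [distal_atom_table()].
#' @return List with `atom` (name or `NA` for a no-distal-carbon residue such
#'   as glycine), `coords` (length-3 numeric or `NULL`), `fallback` (logical),
#'   `resid`.
#' @export
distal_side_chain_carbon <- function(residue, key = NULL,
                                     table = distal_atom_table()) {
  if (inherits(residue, "at_structure")) {
    if (is.null(key)) stop("key required with an at_structure", call. = FALSE)
    residue <- residue_rows(residue, key)
    if (nrow(residue) == 0) stop("residue not found: ", key, call. = FALSE)
  }
  resid <- residue$resid[[1]]
  if (!resid %in% names(table))
    stop("nonstandard residue: ", resid, call. = FALSE)
  cand <- table[[resid]]
  if (length(cand) == 0)
    return(list(atom = NA_character_, coords = NULL, fallback = FALSE,
                resid = resid))
  present <- cand[cand %in% residue$elety]
  if (length(present) == 0)
    return(list(atom = NA_character_, coords = NULL, fallback = FALSE,
                resid = resid))

  ## Atoms tied at the top bond-graph distance: same rank as present[1].
  rank1 <- distal_rank(resid, present[[1]], table)
  tied <- present[vapply(present, distal_rank, numeric(1),
                         resid = resid, table = table) == rank1]
  pick <- tied[[1]]
  if (length(tied) > 1) {
    ca <- residue[residue$elety == "CA", c("x", "y", "z")]
    if (nrow(ca) == 1) {
      d <- vapply(tied, function(nm) {
        p <- residue[residue$elety == nm, c("x", "y", "z")][1, ]
        sqrt(sum((as.numeric(p) - as.numeric(ca[1, ]))^2))
      }, numeric(1))
      ## larger CA distance wins; lexicographic name on exact ties
      ord <- order(-d, tied)
      pick <- tied[[ord[[1]]]]
    } else pick <- sort(tied)[[1]]
  }
  row <- residue[residue$elety == pick, , drop = FALSE][1, ]
  list(atom = pick, coords = c(row$x, row$y, row$z),
       fallback = !identical(pick, cand[[1]]) &&
         distal_rank(resid, pick, table) < distal_rank(resid, cand[[1]], table),
       resid = resid)
}

## Bond-graph distance rank of an atom within a residue's table: atoms are
## stored most-distal-first, grouped by decreasing distance; we recover the
## distance class from the side-chain bond graph used to build the table.
distal_rank <- function(resid, atom, table = distal_atom_table()) {
  d <- side_chain_carbon_depths()[[resid]]
  if (is.null(d) || !atom %in% names(d)) return(-Inf)
  d[[atom]]
}

## Bond-graph distances (number of bonds from CA, side-chain traversal only)
## for every side-chain carbon of the 20 standard residues. PRO is traversed
## CA->CB->CG->CD; the CA->N->CD shortcut through the backbone is not a
## side-chain path.
side_chain_carbon_depths <- function() {
  list(
    ALA = c(CB = 1),
    ARG = c(CB = 1, CG = 2, CD = 3, CZ = 5),
    ASN = c(CB = 1, CG = 2),
    ASP = c(CB = 1, CG = 2),
    CYS = c(CB = 1),
    GLN = c(CB = 1, CG = 2, CD = 3),
    GLU = c(CB = 1, CG = 2, CD = 3),
    GLY = stats::setNames(numeric(0), character(0)),
    HIS = c(CB = 1, CG = 2, CD2 = 3, CE1 = 4),
    ILE = c(CB = 1, CG1 = 2, CG2 = 2, CD1 = 3),
    LEU = c(CB = 1, CG = 2, CD1 = 3, CD2 = 3),
    LYS = c(CB = 1, CG = 2, CD = 3, CE = 4),
    MET = c(CB = 1, CG = 2, CE = 4),
    PHE = c(CB = 1, CG = 2, CD1 = 3, CD2 = 3, CE1 = 4, CE2 = 4, CZ = 5),
    PRO = c(CB = 1, CG = 2, CD = 3),
    SER = c(CB = 1),
    THR = c(CB = 1, CG2 = 2),
    TRP = c(CB = 1, CG = 2, CD1 = 3, CD2 = 3, CE2 = 4, CE3 = 4,
            CZ2 = 5, CZ3 = 5, CH2 = 6),
    TYR = c(CB = 1, CG = 2, CD1 = 3, CD2 = 3, CE1 = 4, CE2 = 4, CZ = 5),
    VAL = c(CB = 1, CG1 = 2, CG2 = 2)
  )
}

#' Fetch a PDB entry from the RCSB archive
#'
#' Downloads `<id>.pdb` into `dest` unless already present. Requires network
#' access; offline use should point [read_structure()] at a local copy.
#'
#' @param id 4-character PDB accession (e.g. "1T1F").
#' @param dest Destination directory (default `tempdir()`).
#' @param quiet Suppress download progress.
#' @return Path to the downloaded file.
#' @export
fetch_structure <- function(id, dest = tempdir(), quiet = TRUE) {
  path <- file.path(dest, paste0(toupper(id), ".pdb"))
  if (file.exists(path)) return(path)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch(utils::download.file(url, path, quiet = quiet, mode = "wb") == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path) || file.size(path) == 0) {
    unlink(path)
    stop("could not fetch PDB entry ", id,
         " (no network access?); supply a local file instead", call. = FALSE)
  }
  path
}
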