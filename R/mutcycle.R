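## Double- and triple-mutant thermodynamic coupling analysis on tables of
## second-order association rate constants.
##
## A mutation set is a character vector of mutation identifiers (empty = wild
## type), order-insensitive. Tables are stored keyed by a canonical
## sorted-and-joined form of the set.

#' Gas constant, kcal/(mol K)
#' @export
R_GAS <- 1.987e-3

mutset_key <- function(muts) paste(sort(unique(as.character(muts))), collapse = ";")

#' Build a mutant rate table
#'
#' @param mutations List of character vectors (each a mutation set;
#'   `character(0)` or `""` is the wild type), or a character vector of
#'   semicolon-joined sets.
#' @param k2 Second-order rate constants, 1/M/s, all positive.
#' @param se Optional standard errors of `k2`.
#' @return A `mutant_rate_table` data.frame with columns `mutations`
#'   (canonical key), `k2`, `se`.
#' @export
mutant_rate_table <- function(mutations, k2, se = NULL) {
  if (is.character(mutations)) mutations <- strsplit(mutations, ";", fixed = TRUE)
  keys <- vapply(mutations, mutset_key, character(1))
  stopifnot(length(keys) == length(k2))
  if (anyDuplicated(keys)) stop("duplicate mutation sets", call. = FALSE)
  if (!("" %in% keys)) stop("wild-type entry (empty mutation set) required",
                            call. = FALSE)
  if (any(!is.finite(k2) | k2 <= 0)) stop("all rates must be positive", call. = FALSE)
  structure(data.frame(mutations = keys, k2 = k2,
                       se = if (is.null(se)) NA_real_ else se,
                       stringsAsFactors = FALSE),
            class = c("mutant_rate_table", "data.frame"))
}

#' Read a mutant rate table from TSV
#'
#' Columns: `mutations` (semicolon-joined identifiers, empty for wild type),
#' `k2_M1s1`, optional `se`.
#'
#' @param path TSV file path.
#' @return A `mutant_rate_table`.
#' @export
read_rate_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$mutations[is.na(d$mutations)] <- ""
  mutant_rate_table(d$mutations, d$k2_M1s1, d$se)
}

rate_lookup <- function(table, muts) {
  i <- match(mutset_key(muts), table$mutations)
  if (is.na(i)) return(list(k2 = NA_real_, se = NA_real_))
  list(k2 = table$k2[[i]], se = table$se[[i]])
}

#' Thermodynamic coupling index of a mutation pair
#'
#' For mutations a and b over a common background set, the coupling index is
#' CI = (k_{bg+a} * k_{bg+b}) / (k_bg * k_{bg+a+b}): the ratio of the
#' multiplicative (energetically additive) prediction for the double mutant
#' to its observed rate. CI = 1 means the two mutations act additively;
#' CI > 1 means the combined effect falls short of multiplicative —
#' cooperative linkage between the two positions. The interaction free
#' energy is dG_int = R T ln(CI). Set `reciprocal = TRUE` for the inverse
#' orientation; the convention used is stamped on the result.
#'
#' @param table A `mutant_rate_table`.
#' @param a,b Mutation identifiers.
#' @param background Character vector of background mutations (default none).
#' @param T Temperature in K (default 298.15, assays at 25 C).
#' @param reciprocal Use the reciprocal CI convention? Default `FALSE`.
#' @return A `coupling_result`: `pair`, `background`, `CI`, `dG_int`
#'   (kcal/mol), `se_lnCI` (when table has standard errors), `temperature`,
#'   `convention`.
#' @export
coupling_index <- function(table, a, b, background = character(0),
                           T = 298.15, reciprocal = FALSE) {
  need <- list(bg = background, a = c(background, a), b = c(background, b),
               ab = c(background, a, b))
  got <- lapply(need, rate_lookup, table = table)
  missing <- names(need)[vapply(got, function(g) is.na(g$k2), logical(1))]
  if (length(missing))
    stop("rate table missing entries: ",
         paste(vapply(need[missing], mutset_key, character(1)),
               collapse = ", "), call. = FALSE)
  CI <- (got$a$k2 * got$b$k2) / (got$bg$k2 * got$ab$k2)
  if (reciprocal) CI <- 1 / CI
  se_lnCI <- NA_real_
  rel <- vapply(got, function(g) g$se / g$k2, numeric(1))
  if (all(is.finite(rel))) se_lnCI <- sqrt(sum(rel^2))  # first-order in log space
  structure(list(pair = sort(c(a, b)), background = sort(background),
                 CI = CI, dG_int = R_GAS * T * log(CI),
                 se_lnCI = se_lnCI, temperature = T,
                 convention = if (reciprocal) "reciprocal" else
                   "CI>1 = cooperative (sub-multiplicative)"),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  bg <- if (length(x$background)) paste0(" | ", paste(x$background, collapse = ";")) else ""
  cat(sprintf("coupling %s-%s%s: CI = %.3f, dG_int = %.3f kcal/mol (T %.2f K)\n",
              x$pair[[1]], x$pair[[2]], bg, x$CI, x$dG_int, x$temperature))
  invisible(x)
}

#' All pairwise and conditional coupling indices
#'
#' Computes CI for every pair of `mutations` over the empty background, plus
#' every conditional CI over each single-mutation background drawn from the
#' remaining mutations. Pairs whose required table entries are absent are
#' reported in `missing`, never fabricated.
#'
#' @param table A `mutant_rate_table`.
#' @param mutations Character vector of mutation identifiers.
#' @param T Temperature, K.
#' @return A `coupling_matrix`: list with `results` (list of
#'   `coupling_result`) and `missing` (data.frame of skipped combinations).
#' @export
coupling_matrix <- function(table, mutations, T = 298.15) {
  results <- list(); missing <- list()
  combos <- utils::combn(mutations, 2, simplify = FALSE)
  jobs <- c(lapply(combos, function(p) list(a = p[[1]], b = p[[2]], bg = character(0))),
            unlist(lapply(combos, function(p) {
              lapply(setdiff(mutations, p), function(bg)
                list(a = p[[1]], b = p[[2]], bg = bg))
            }), recursive = FALSE))
  for (j in jobs) {
    r <- tryCatch(coupling_index(table, j$a, j$b, j$bg, T = T),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      missing[[length(missing) + 1L]] <-
        data.frame(a = j$a, b = j$b,
                   background = paste(j$bg, collapse = ";"),
                   reason = r, stringsAsFactors = FALSE)
    } else results[[length(results) + 1L]] <- r
  }
  structure(list(results = results,
                 missing = if (length(missing)) do.call(rbind, missing)
                           else data.frame()),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %d coupling results, %d missing combinations\n",
              length(x$results), nrow(x$missing)))
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
as.data.frame.coupling_matrix <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r)
    data.frame(a = r$pair[[1]], b = r$pair[[2]],
               background = paste(r$background, collapse = ";"),
               CI = r$CI, dG_int = r$dG_int, stringsAsFactors = FALSE)))
}

#' Three-body coupling term of a mutation triple
#'
#' Decomposes the conditional coupling of (a, b) over background c as
#' ln CI(a,b|c) = ln CI(a,b) + three-body term. The term is zero for any rate
#' table generated without three-body energies and quantifies how a third
#' mutation rewires the pairwise linkage (e.g. linkage loss when two network
#' residues are already mutated).
#'
#' @param table A `mutant_rate_table`.
#' @param a,b,c Mutation identifiers.
#' @param T Temperature, K.
#' @return List with `ln_CI_pair`, `ln_CI_conditional`, `three_body`
#'   (all dimensionless logs) and `dG_three_body` (kcal/mol).
#' @export
three_body_term <- function(table, a, b, c, T = 298.15) {
  plain <- coupling_index(table, a, b, T = T)
  cond <- coupling_index(table, a, b, background = c, T = T)
  tb <- log(cond$CI) - log(plain$CI)
  list(ln_CI_pair = log(plain$CI), ln_CI_conditional = log(cond$CI),
       three_body = tb, dG_three_body = R_GAS * T * tb)
}
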