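# Maximum common substructure: McGregor-style branch-and-bound search for
# the largest connected, bond-matched common subgraph of two structures.
# Exact on the small molecules the generator emits; a wall-clock budget
# bounds the search and the best mapping found so far is returned when it
# is exceeded.

# adjacency matrix of bond codes ("" = no bond, "a" aromatic, else order)
.bond_code_matrix <- function(mol) {
  nA <- length(mol$element)
  m <- matrix("", nA, nA)
  b <- mol$bonds
  if (nrow(b)) {
    code <- ifelse(b$aromatic, "a", as.character(b$order))
    for (k in seq_len(nrow(b))) {
      m[b$a1[k], b$a2[k]] <- code[k]
      m[b$a2[k], b$a1[k]] <- code[k]
    }
  }
  m
}

#' Maximum common substructure of two structures
#'
#' Finds the largest connected common subgraph with matching atom types
#' (element + aromaticity) and bond types, by branch-and-bound search over
#' atom correspondences.
#'
#' @param mol_a,mol_b `molgraph` objects or SMILES strings.
#' @param timeout search budget in seconds; on expiry the best-so-far
#'   mapping is returned (flagged via the `complete` field).
#' @return list with `map_a`, `map_b` (parallel atom index vectors),
#'   `size`, and `complete` (FALSE if the search hit the time budget).
#' @export
mcs_pair <- function(mol_a, mol_b, timeout = 1) {
  if (is.character(mol_a)) mol_a <- parse_smiles(strip_salts(mol_a))
  if (is.character(mol_b)) mol_b <- parse_smiles(strip_salts(mol_b))
  swap <- length(mol_b$element) < length(mol_a$element)
  if (swap) { tmp <- mol_a; mol_a <- mol_b; mol_b <- tmp }
  nA <- length(mol_a$element); nB <- length(mol_b$element)
  labA <- paste(mol_a$element, as.integer(mol_a$aromatic))
  labB <- paste(mol_b$element, as.integer(mol_b$aromatic))
  admA <- .bond_code_matrix(mol_a)
  admB <- .bond_code_matrix(mol_b)
  adjA <- lapply(seq_len(nA), function(a) which(admA[a, ] != ""))

  best_a <- integer(0); best_b <- integer(0)
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE

  recurse <- function(map_a, map_b, excluded) {
    if (timed_out) return(invisible(NULL))
    if (proc.time()[["elapsed"]] - t0 > timeout) { timed_out <<- TRUE; return(invisible(NULL)) }
    if (length(map_a) > length(best_a)) { best_a <<- map_a; best_b <<- map_b }
    avail_a <- setdiff(seq_len(nA), c(map_a, excluded))
    if (length(map_a) + length(avail_a) <= length(best_a)) return(invisible(NULL))
    if (nB - length(map_b) + length(map_a) <= length(best_a)) return(invisible(NULL))
    # next atom of A to branch on: frontier of the mapped set (connectedness)
    cand <- if (length(map_a) == 0L) avail_a else
      avail_a[vapply(avail_a, function(a) any(adjA[[a]] %in% map_a), logical(1))]
    if (length(cand) == 0L) return(invisible(NULL))
    a <- cand[1]
    for (bb in setdiff(which(labB == labA[a]), map_b)) {
      ok <- TRUE
      for (k in seq_along(map_a)) {
        if (admA[a, map_a[k]] != admB[bb, map_b[k]]) { ok <- FALSE; break }
      }
      if (ok) recurse(c(map_a, a), c(map_b, bb), excluded)
      if (timed_out) return(invisible(NULL))
    }
    recurse(map_a, map_b, c(excluded, a))
    invisible(NULL)
  }
  recurse(integer(0), integer(0), integer(0))

  if (swap) list(map_a = best_b, map_b = best_a, size = length(best_a),
                 complete = !timed_out)
  else list(map_a = best_a, map_b = best_b, size = length(best_a),
            complete = !timed_out)
}

#' MCS scaffold of a cluster of structures
#'
#' For a single structure, its Bemis-Murcko-style framework
#' ([murcko_framework()]); for several, the maximum common substructure
#' folded pairwise across members (MCS of the first two, then of that
#' result with the third, ...). Scaffolds smaller than `min_atoms` heavy
#' atoms are reported as empty (`""`); the cluster itself is retained by
#' callers.
#'
#' @param smiles character vector of member SMILES.
#' @param min_atoms minimum scaffold size in heavy atoms (default 3).
#' @param timeout per-pair MCS search budget in seconds.
#' @return scaffold SMILES string (possibly a non-ring-closed fragment when
#'   the common substructure cuts through rings), or `""`.
#' @export
mcs_scaffold <- function(smiles, min_atoms = 3L, timeout = 1) {
  if (length(smiles) == 0L) stop("empty cluster", call. = FALSE)
  if (length(smiles) == 1L) return(murcko_framework(smiles))
  cur <- parse_smiles(strip_salts(smiles[1]))
  for (s in smiles[-1]) {
    res <- mcs_pair(cur, parse_smiles(strip_salts(s)), timeout = timeout)
    if (res$size < min_atoms) return("")
    cur <- .subgraph_mol(cur, res$map_a)
  }
  if (length(cur$element) < min_atoms) return("")
  write_smiles(cur)
}
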