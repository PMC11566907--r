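# Circular (Morgan-style, ECFP-like) fingerprints over molgraph structures.
# Radius-2 / 2048-bit defaults correspond to the ECFP4 setting conventional
# in virtual-screening similarity work.

#' Morgan-style circular fingerprint
#'
#' Hashed circular substructure fingerprint: every atom environment of
#' radius 0..`radius` (atom invariant plus bond-order-annotated neighbor
#' identifiers, iteratively rehashed) sets one bit of a fixed-length binary
#' vector.
#'
#' @param mol `molgraph` or SMILES string. Multi-fragment input is
#'   salt-stripped first.
#' @param radius maximum environment radius (default 2, i.e. ECFP4-like).
#' @param nbits fingerprint length (default 2048).
#' @return logical vector of length `nbits`.
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(strip_salts(mol))
  nA <- length(mol$element)
  b <- mol$bonds
  nb <- vector("list", nA)
  code <- ifelse(b$aromatic, "a", as.character(b$order))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- rbind(nb[[b$a1[k]]], c(b$a2[k], code[k]))
    nb[[b$a2[k]]] <- rbind(nb[[b$a2[k]]], c(b$a1[k], code[k]))
  }
  deg <- vapply(nb, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  ids <- vapply(seq_len(nA), function(a)
    .st_hash(paste(mol$element[a], as.integer(mol$aromatic[a]), mol$hcount[a],
                   deg[a], sep = "|")), numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(nA), function(a) {
      m <- nb[[a]]
      env <- if (is.null(m)) "" else
        paste(sort(paste0(m[, 2], ":", format(ids[as.integer(m[, 1])], scientific = FALSE))),
              collapse = ",")
      .st_hash(paste0(format(ids[a], scientific = FALSE), "#", env))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  fp <- logical(nbits)
  fp[unique(all_ids %% nbits) + 1] <- TRUE
  fp
}

#' Fingerprint a set of structures into a binary matrix
#'
#' @param smiles character vector of SMILES (names, if present, become
#'   rownames; otherwise the vector itself does).
#' @inheritParams morgan_fingerprint
#' @return logical matrix, one row per structure, `nbits` columns.
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, nbits = 2048L) {
  m <- t(vapply(smiles, morgan_fingerprint, logical(nbits),
                radius = radius, nbits = nbits))
  rownames(m) <- if (!is.null(names(smiles))) names(smiles) else smiles
  m
}

#' Tanimoto similarity of two binary fingerprints
#'
#' Intersection over union of set bits. Two all-zero fingerprints are
#' defined to have similarity 1 (documented convention: featureless
#' structures are treated as indistinguishable).
#'
#' @param fp_a,fp_b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b),
         call. = FALSE)
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param fps logical/0-1 matrix of fingerprints (rows = compounds).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  m <- matrix(as.numeric(fps), nrow = nrow(fps), dimnames = dimnames(fps))
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  un <- outer(rs, rs, "+") - inter
  sim <- ifelse(un == 0, 1, inter / un)
  diag(sim) <- 1
  sim
}
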