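# Molecular graphs for the restricted SMILES dialect emitted by the library
# generator: elements C N O S F Cl Br (aromatic c n o s), branches, ring
# closures 1-9, bond symbols - = #, fragments separated by '.'. No bracket
# atoms, charges or stereo annotations. Aromaticity is carried as an atom and
# bond flag rather than kekulized, so fingerprints and substructure matching
# see chemically equivalent aromatic bonds as identical.

.ST_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1)
# conventional (2005 IUPAC-rounded) atomic weights, matching Open Babel
.ST_MASS <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
              S = 32.065, F = 18.9984032, Cl = 35.453, Br = 79.904)

#' Parse a SMILES string into a molecular graph
#'
#' Supports the restricted organic-subset dialect used throughout the
#' package: `C N O S F Cl Br`, aromatic `c n o s`, branches, ring-closure
#' digits 1-9, explicit `-`/`=`/`#` bonds and `.`-separated fragments.
#' Implicit hydrogens are assigned from standard valences; a bond written
#' between two aromatic atoms is aromatic only when it lies in a ring
#' (so biaryl linker bonds are single).
#'
#' @param smiles length-one character SMILES string.
#' @return An object of class `molgraph`: a list with `element`, `aromatic`,
#'   `hcount` (per-atom vectors) and `bonds` (data frame with columns
#'   `a1`, `a2`, `order`, `aromatic`).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("'smiles' must be a single character string", call. = FALSE)
  s <- gsub("[[:space:]]", "", smiles)
  if (!nzchar(s)) stop("empty SMILES string", call. = FALSE)

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  element <- character(0); aromatic <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0); barom <- logical(0)
  prev <- 0L
  stack <- integer(0)
  ring_atom <- rep(NA_integer_, 9L)
  ring_ord <- rep(NA_real_, 9L)
  pend <- NA_real_   # explicit bond order for the next bond; -1 == forced single

  add_atom <- function(sym) {
    arom <- sym %in% c("c", "n", "o", "s")
    element <<- c(element, if (arom) toupper(sym) else sym)
    aromatic <<- c(aromatic, arom)
    cur <- length(element)
    if (prev > 0L) {
      if (!is.na(pend)) {
        b1 <<- c(b1, prev); b2 <<- c(b2, cur)
        bord <<- c(bord, max(pend, 1)); barom <<- c(barom, FALSE)
      } else {
        ar <- aromatic[prev] && arom
        b1 <<- c(b1, prev); b2 <<- c(b2, cur)
        bord <<- c(bord, 1); barom <<- c(barom, ar)
      }
    }
    prev <<- cur
    pend <<- NA_real_
    invisible(NULL)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("C", "N", "O", "S", "F", "B")) {
      sym <- ch
      if (ch == "C" && i < n && chars[i + 1L] == "l") { sym <- "Cl"; i <- i + 1L }
      else if (ch == "B" && i < n && chars[i + 1L] == "r") { sym <- "Br"; i <- i + 1L }
      else if (ch == "B") stop("unsupported element in SMILES: B", call. = FALSE)
      add_atom(sym)
    } else if (ch %in% c("c", "n", "o", "s")) {
      add_atom(ch)
    } else if (ch %in% as.character(1:9)) {
      d <- as.integer(ch)
      if (prev == 0L) stop("ring-closure digit before any atom: ", smiles, call. = FALSE)
      if (is.na(ring_atom[d])) {
        ring_atom[d] <- prev
        ring_ord[d] <- pend
      } else {
        other <- ring_atom[d]
        ord <- if (!is.na(pend)) pend else ring_ord[d]
        if (!is.na(ord)) {
          b1 <- c(b1, other); b2 <- c(b2, prev)
          bord <- c(bord, max(ord, 1)); barom <- c(barom, FALSE)
        } else {
          ar <- aromatic[other] && aromatic[prev]
          b1 <- c(b1, other); b2 <- c(b2, prev)
          bord <- c(bord, 1); barom <- c(barom, ar)
        }
        ring_atom[d] <- NA_integer_; ring_ord[d] <- NA_real_
      }
      pend <- NA_real_
    } else if (ch == "(") {
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles, call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ch == "-") {
      pend <- -1
    } else if (ch == "=") {
      pend <- 2
    } else if (ch == "#") {
      pend <- 3
    } else if (ch == ".") {
      prev <- 0L
    } else {
      stop("unsupported SMILES token '", ch, "' in: ", smiles, call. = FALSE)
    }
    i <- i + 1L
  }
  if (any(!is.na(ring_atom))) stop("unclosed ring bond in SMILES: ", smiles, call. = FALSE)
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles, call. = FALSE)

  bonds <- data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom)
  mol <- structure(
    list(element = element, aromatic = aromatic, hcount = integer(length(element)),
         bonds = bonds),
    class = "molgraph")
  # demote aromatic-flagged bonds that are not in any ring (biaryl linkers)
  if (any(bonds$aromatic)) {
    inring <- .ring_bonds(mol)
    mol$bonds$aromatic <- mol$bonds$aromatic & inring
  }
  mol$hcount <- .implicit_h(mol)
  mol
}

.implicit_h <- function(mol) {
  nA <- length(mol$element)
  osum <- numeric(nA)
  b <- mol$bonds
  if (nrow(b)) {
    ord <- ifelse(b$aromatic, 1, b$order)
    for (k in seq_len(nrow(b))) {
      osum[b$a1[k]] <- osum[b$a1[k]] + ord[k]
      osum[b$a2[k]] <- osum[b$a2[k]] + ord[k]
    }
  }
  val <- .ST_VALENCE[mol$element]
  as.integer(pmax(0, val - osum - as.numeric(mol$aromatic)))
}

# logical vector over bond rows: TRUE if the bond lies in a ring (not a bridge)
.ring_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(logical(0))
  g <- igraph::graph_from_data_frame(b[, c("a1", "a2")], directed = FALSE,
                                     vertices = data.frame(name = seq_along(mol$element)))
  br <- igraph::bridges(g)
  inring <- rep(TRUE, nrow(b))
  inring[as.integer(br)] <- FALSE
  inring
}

# logical vector over atoms: TRUE if the atom lies in a ring
.ring_atoms <- function(mol) {
  out <- logical(length(mol$element))
  rb <- .ring_bonds(mol)
  if (any(rb)) {
    b <- mol$bonds[rb, , drop = FALSE]
    out[unique(c(b$a1, b$a2))] <- TRUE
  }
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat("molgraph:", length(x$element), "heavy atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Molecular weight of a parsed structure
#'
#' Average molecular weight (g/mol) including implicit hydrogens.
#'
#' @param mol a `molgraph` from [parse_smiles()], or a SMILES string.
#' @return numeric scalar, g/mol.
#' @export
mol_mw <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  sum(.ST_MASS[mol$element]) + .ST_MASS[["H"]] * sum(mol$hcount)
}

#' Strip salts/counterions from a SMILES string
#'
#' Keeps the largest fragment (most heavy atoms; ties broken by molecular
#' weight, then first occurrence) of a `.`-separated SMILES.
#'
#' @param smiles SMILES string, possibly multi-fragment.
#' @return single-fragment SMILES string.
#' @export
strip_salts <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) stop("empty SMILES string", call. = FALSE)
  if (length(frags) == 1L) return(frags)
  mols <- lapply(frags, parse_smiles)
  na <- vapply(mols, function(m) length(m$element), integer(1))
  mw <- vapply(mols, mol_mw, numeric(1))
  frags[order(-na, -mw)][1]
}

# extract the induced subgraph on `atoms` (indices), recomputing implicit H
.subgraph_mol <- function(mol, atoms) {
  atoms <- sort(unique(atoms))
  idx <- match(seq_along(mol$element), atoms)
  b <- mol$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  b <- b[keep, , drop = FALSE]
  b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2]
  out <- structure(
    list(element = mol$element[atoms], aromatic = mol$aromatic[atoms],
         hcount = integer(length(atoms)),
         bonds = b),
    class = "molgraph")
  out$hcount <- .implicit_h(out)
  out
}

#' Bemis-Murcko-style framework of a structure
#'
#' Iteratively removes acyclic terminal atoms, leaving ring systems and the
#' linkers connecting them (exocyclic substituents, including carbonyl
#' oxygens, are removed). Returns the canonical SMILES of the framework, or
#' `""` for acyclic structures.
#'
#' @param mol `molgraph` or SMILES string.
#' @return framework SMILES string.
#' @export
murcko_framework <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ring <- .ring_atoms(mol)
  if (!any(ring)) return("")
  keep <- rep(TRUE, length(mol$element))
  repeat {
    deg <- integer(length(mol$element))
    b <- mol$bonds
    live <- keep[b$a1] & keep[b$a2]
    for (k in which(live)) {
      deg[b$a1[k]] <- deg[b$a1[k]] + 1L
      deg[b$a2[k]] <- deg[b$a2[k]] + 1L
    }
    drop <- keep & !ring & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  write_smiles(.subgraph_mol(mol, which(keep)))
}

# order-independent polynomial hash onto [0, 2^31)
.st_hash <- function(s) {
  h <- 7
  for (x in utf8ToInt(s)) h <- (h * 131 + x) %% 2147483647
  h
}

# canonical atom ranks via iterative invariant refinement (Morgan-style);
# residual ties (automorphic atoms in this dialect) split deterministically
.canonical_ranks <- function(mol) {
  nA <- length(mol$element)
  b <- mol$bonds
  nb <- vector("list", nA)
  code <- ifelse(b$aromatic, "a", as.character(b$order))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- rbind(nb[[b$a1[k]]], c(b$a2[k], code[k]))
    nb[[b$a2[k]]] <- rbind(nb[[b$a2[k]]], c(b$a1[k], code[k]))
  }
  inv <- paste(mol$element, as.integer(mol$aromatic), mol$hcount,
               vapply(nb, function(m) if (is.null(m)) 0L else nrow(m), integer(1)),
               sep = "|")
  rank <- match(inv, sort(unique(inv)))
  refine <- function(rank) {
    repeat {
      # zero-pad ranks so lexicographic string order equals numeric order,
      # keeping the relabelling stable across iterations
      rs <- sprintf("%05d", rank)
      inv2 <- vapply(seq_len(nA), function(a) {
        m <- nb[[a]]
        nbr <- if (is.null(m)) "" else
          paste(sort(paste0(m[, 2], ":", rs[as.integer(m[, 1])])), collapse = ",")
        paste0(rs[a], "#", nbr)
      }, character(1))
      new <- match(inv2, sort(unique(inv2)))
      if (identical(new, rank)) return(rank)
      rank <- new
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < nA) {
    tied <- which(table(rank) > 1L)
    cls <- as.integer(names(tied))[1]
    a <- which(rank == cls)[1]
    rank <- rank * 2L
    rank[a] <- rank[a] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

#' Write a molecular graph as a canonical SMILES string
#'
#' Atoms are ordered by canonical ranks from iterative invariant refinement,
#' so chemically identical inputs written in different atom orders produce
#' the same string.
#'
#' @param mol a `molgraph`.
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  nA <- length(mol$element)
  if (nA == 0L) return("")
  b <- mol$bonds
  # connected components: emit each as a fragment, '.'-joined
  comp <- if (nrow(b)) {
    g <- igraph::graph_from_data_frame(b[, c("a1", "a2")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(nA)))
    as.integer(igraph::components(g)$membership)
  } else seq_len(nA)
  rank <- .canonical_ranks(mol)

  adj <- vector("list", nA)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  other <- function(k, a) if (b$a1[k] == a) b$a2[k] else b$a1[k]
  bondsym <- function(k) {
    if (b$aromatic[k]) return("")
    if (b$order[k] == 2) return("=")
    if (b$order[k] == 3) return("#")
    if (mol$aromatic[b$a1[k]] && mol$aromatic[b$a2[k]]) return("-")
    ""
  }
  atomsym <- function(a) {
    e <- mol$element[a]
    if (mol$aromatic[a]) tolower(e) else e
  }

  frags <- character(0)
  for (cc in unique(comp[order(rank)])) {
    atoms_cc <- which(comp == cc)
    start <- atoms_cc[which.min(rank[atoms_cc])]
    # pass 1: DFS to classify tree vs closure edges
    visited <- logical(nA); used <- logical(nrow(b))
    closures <- integer(0)
    dfs1 <- function(a) {
      visited[a] <<- TRUE
      ks <- adj[[a]]
      ks <- ks[order(rank[vapply(ks, other, integer(1), a = a)])]
      for (k in ks) {
        if (used[k]) next
        o <- other(k, a)
        if (visited[o]) { used[k] <<- TRUE; closures <<- c(closures, k) }
        else { used[k] <<- TRUE; dfs1(o) }
      }
    }
    dfs1(start)
    digit_of <- integer(nrow(b))
    open_digits <- logical(9)
    emitted <- logical(nA)
    # pass 2: emit
    dfs2 <- function(a, via) {
      out <- if (is.na(via)) "" else bondsym(via)
      out <- paste0(out, atomsym(a))
      emitted[a] <<- TRUE
      ks <- adj[[a]]
      ks <- ks[order(rank[vapply(ks, other, integer(1), a = a)])]
      for (k in ks[ks %in% closures]) {
        if (digit_of[k] == 0L) {
          d <- which(!open_digits)[1]
          if (is.na(d)) stop("more than 9 concurrent ring closures", call. = FALSE)
          digit_of[k] <<- d; open_digits[d] <<- TRUE
          out <- paste0(out, bondsym(k), d)
        } else {
          open_digits[digit_of[k]] <<- FALSE
          out <- paste0(out, digit_of[k])
        }
      }
      tree_ks <- ks[!(ks %in% closures)]
      tree_ks <- tree_ks[!emitted[vapply(tree_ks, other, integer(1), a = a)]]
      if (length(tree_ks)) {
        for (k in tree_ks[-length(tree_ks)])
          out <- paste0(out, "(", dfs2(other(k, a), k), ")")
        k <- tree_ks[length(tree_ks)]
        out <- paste0(out, dfs2(other(k, a), k))
      }
      out
    }
    frags <- c(frags, dfs2(start, NA_integer_))
  }
  paste(frags, collapse = ".")
}

#' Canonicalize a SMILES string
#'
#' Strips salts (keeps the largest fragment) and rewrites the structure in
#' the package's canonical atom order.
#'
#' @param smiles SMILES string.
#' @return canonical single-fragment SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  write_smiles(parse_smiles(strip_salts(smiles)))
}
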