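# Hit triage: threshold hit calling on normalized activity, Tanimoto-graph
# Louvain clustering, per-cluster MCS scaffolds, ligand-efficiency
# diversification, potency labels and nearest-neighbor novelty counts.

#' Call hits at a normalized-inhibition threshold
#'
#' A compound is a hit when its normalized relative inhibition meets the
#' threshold (boundary inclusive: `k_norm >= threshold`).
#'
#' @param records data frame with `compound_id` and `k_norm` (percent).
#' @param threshold hit threshold in percent (default 50).
#' @return character vector of hit compound ids.
#' @export
call_hits <- function(records, threshold = 50) {
  if (any(is.na(records$k_norm)))
    stop("k_norm missing for some records; normalize first", call. = FALSE)
  records$compound_id[records$k_norm >= threshold]
}

#' Ligand-efficiency proxy
#'
#' Normalized inhibition divided by molecular weight (percent * mol / g):
#' a size-corrected activity used to pick cluster representatives.
#'
#' @param k_norm normalized inhibition, percent.
#' @param mw molecular weight, g/mol, positive.
#' @return numeric vector.
#' @export
ligand_efficiency_proxy <- function(k_norm, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  k_norm / mw
}

#' Build a Tanimoto similarity graph over compounds
#'
#' Undirected graph with an edge `(i, j)` whenever the pairwise Tanimoto
#' similarity meets `edge_threshold`; edge weight is the similarity. No
#' self loops. Compounds with no neighbor stay as isolated vertices.
#'
#' @param fps logical fingerprint matrix (rows named by compound id), e.g.
#'   from [fingerprint_matrix()].
#' @param edge_threshold minimum similarity for an edge (default 0.4).
#' @return igraph object whose vertex names are compound ids.
#' @export
build_similarity_graph <- function(fps, edge_threshold = 0.4) {
  if (is.null(rownames(fps))) stop("fingerprint matrix must have rownames",
                                   call. = FALSE)
  sim <- tanimoto_matrix(fps)
  n <- nrow(sim)
  keep <- which(upper.tri(sim) & sim >= edge_threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- rownames(sim)
  if (nrow(keep)) {
    g <- igraph::add_edges(g, t(keep),
                           weight = sim[keep])
  }
  g
}

#' Louvain clustering of a similarity graph
#'
#' Modularity-maximizing Louvain communities (igraph implementation,
#' weighted by similarity). Isolated vertices become singleton clusters.
#' Seeded for reproducibility.
#'
#' @param graph igraph object from [build_similarity_graph()].
#' @param seed integer RNG seed.
#' @return object of class `cluster_set`: data frame `compound_id`,
#'   `cluster_id`.
#' @export
louvain_cluster <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph)
  out <- data.frame(compound_id = igraph::V(graph)$name,
                    cluster_id = as.integer(igraph::membership(comm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_set", class(out))
  out
}

#' MCS scaffolds for every cluster
#'
#' @param clusters a `cluster_set` from [louvain_cluster()].
#' @param library data frame with `compound_id`, `smiles`.
#' @param ... passed to [mcs_scaffold()] (`min_atoms`, `timeout`).
#' @return data frame `cluster_id`, `n_members`, `scaffold_smiles`.
#' @export
cluster_scaffolds <- function(clusters, library, ...) {
  smi <- stats::setNames(library$smiles, library$compound_id)
  rows <- lapply(split(clusters$compound_id, clusters$cluster_id), function(ids)
    data.frame(n_members = length(ids),
               scaffold_smiles = mcs_scaffold(unname(smi[ids]), ...),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- cbind(cluster_id = as.integer(names(rows)), out)
  rownames(out) <- NULL
  out
}

#' Diversified hit selection by ligand efficiency
#'
#' From each cluster, selects the `min(k, cluster size)` members with the
#' greatest ligand-efficiency proxy (ties broken by compound id, ascending)
#' and returns the union with cluster provenance.
#'
#' @param clusters a `cluster_set`.
#' @param records data frame with `compound_id`, `k_norm`, `mw`.
#' @param k_per_cluster representatives per cluster (default 5).
#' @return data frame `compound_id`, `cluster_id`, `le_proxy`, ordered by
#'   cluster then descending ligand efficiency.
#' @export
diversify <- function(clusters, records, k_per_cluster = 5L) {
  m <- merge(as.data.frame(clusters), records[, c("compound_id", "k_norm", "mw")],
             by = "compound_id")
  if (nrow(m) < nrow(clusters))
    stop("k_norm/mw missing for some cluster members", call. = FALSE)
  m$le_proxy <- ligand_efficiency_proxy(m$k_norm, m$mw)
  rows <- lapply(split(m, m$cluster_id), function(df) {
    df <- df[order(-df$le_proxy, df$compound_id), , drop = FALSE]
    utils::head(df, k_per_cluster)
  })
  out <- do.call(rbind, rows)[, c("compound_id", "cluster_id", "le_proxy")]
  rownames(out) <- NULL
  out
}

#' Label clusters by the potency of their most active member
#'
#' A cluster's label is the activity class of its maximum-pIC50 assayed
#' member; clusters with no assayed member are `unlabeled`.
#'
#' @param clusters a `cluster_set`.
#' @param pic50_table data frame with `compound_id`, `pic50`.
#' @return data frame `cluster_id`, `best_pic50`, `label`.
#' @export
label_scaffolds <- function(clusters, pic50_table) {
  rows <- lapply(split(clusters$compound_id, clusters$cluster_id), function(ids) {
    p <- pic50_table$pic50[pic50_table$compound_id %in% ids]
    if (length(p) == 0L)
      data.frame(best_pic50 = NA_real_, label = "unlabeled",
                 stringsAsFactors = FALSE)
    else
      data.frame(best_pic50 = max(p), label = classify_activity(max(p)),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(cluster_id = as.integer(names(rows)), out)
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor novelty counts against a reference set
#'
#' For each similarity threshold `t`, counts the hits whose nearest
#' reference neighbor exceeds `t` (strict), and the distinct clusters
#' ("scaffolds") containing at least one such hit. An empty reference set
#' yields all-zero counts.
#'
#' @param hit_fps fingerprint matrix of the hits (rownames = ids).
#' @param ref_fps fingerprint matrix of the reference actives (same
#'   fingerprint settings).
#' @param thresholds numeric vector of Tanimoto thresholds.
#' @param clusters optional `cluster_set` over the hits, for scaffold
#'   counts.
#' @return data frame `threshold`, `n_hits`, `n_scaffolds` (the latter NA
#'   without `clusters`).
#' @export
novelty_counts <- function(hit_fps, ref_fps, thresholds, clusters = NULL) {
  nn <- if (is.null(ref_fps) || nrow(ref_fps) == 0L) {
    rep(-Inf, nrow(hit_fps))
  } else {
    if (ncol(hit_fps) != ncol(ref_fps))
      stop("fingerprint length mismatch between hits and reference",
           call. = FALSE)
    m_h <- matrix(as.numeric(hit_fps), nrow = nrow(hit_fps))
    m_r <- matrix(as.numeric(ref_fps), nrow = nrow(ref_fps))
    inter <- tcrossprod(m_h, m_r)
    un <- outer(rowSums(m_h), rowSums(m_r), "+") - inter
    sim <- ifelse(un == 0, 1, inter / un)
    apply(sim, 1, max)
  }
  cl <- if (!is.null(clusters))
    clusters$cluster_id[match(rownames(hit_fps), clusters$compound_id)]
  rows <- lapply(thresholds, function(t) {
    sel <- nn > t
    data.frame(threshold = t, n_hits = sum(sel),
               n_scaffolds = if (is.null(cl)) NA_integer_ else
                 length(unique(cl[sel])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
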