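# Virtual-screening ranking evaluation: hit discovery-rate curves across
# library fractions and activity thresholds, scaffold discovery counts,
# and method comparison with fold-enrichment ratios.

.default_fractions <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)

#' Construct a deterministic compound ranking
#'
#' Orders compounds by descending score; ties broken by compound id
#' (ascending), so rankings are total and reproducible.
#'
#' @param method method name.
#' @param compound_id character vector (unique).
#' @param score numeric scores, higher = better.
#' @return object of class `ranking_result`: data frame `method`,
#'   `compound_id`, `score`, `rank`.
#' @export
ranking_result <- function(method, compound_id, score) {
  if (anyDuplicated(compound_id))
    stop("duplicate compound ids in ranking", call. = FALSE)
  if (length(compound_id) != length(score))
    stop("compound_id and score lengths differ", call. = FALSE)
  o <- order(-score, compound_id)
  out <- data.frame(method = method, compound_id = compound_id[o],
                    score = score[o], rank = seq_along(o),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_result", class(out))
  out
}

#' Rankings from a long score table
#'
#' @param scores data frame `method`, `compound_id`, `score`.
#' @return named list of `ranking_result` objects.
#' @export
rankings_from_scores <- function(scores) {
  out <- lapply(split(scores, scores$method), function(df)
    ranking_result(df$method[1], df$compound_id, df$score))
  out[unique(scores$method)]
}

#' Hit discovery-rate curve
#'
#' At each library fraction `f`, the top `ceiling(f * N)` ranked compounds
#' are selected and the value is the fraction of all hits they contain.
#' The curve is monotone non-decreasing and reaches 1 at `f = 1`.
#'
#' @param ranking a `ranking_result`.
#' @param hits character vector of hit ids (subset of the ranking's
#'   universe; non-empty).
#' @param fractions fractions of the library screened, in `(0, 1]`.
#' @return object of class `discovery_curve`: data frame `method`,
#'   `fraction`, `n_top`, `value` plus attribute `n_hits_total`.
#' @export
hit_discovery_curve <- function(ranking, hits, fractions = .default_fractions) {
  if (length(hits) == 0L) stop("empty hit set", call. = FALSE)
  missing <- setdiff(hits, ranking$compound_id)
  if (length(missing))
    stop("hits outside ranking universe: ", paste(utils::head(missing, 5),
                                                  collapse = ", "), call. = FALSE)
  n <- nrow(ranking)
  is_hit <- ranking$compound_id %in% hits
  cum_hits <- cumsum(is_hit)
  k <- pmin(ceiling(fractions * n), n)
  out <- data.frame(method = ranking$method[1], fraction = fractions,
                    n_top = k, value = cum_hits[k] / length(hits),
                    stringsAsFactors = FALSE)
  attr(out, "n_hits_total") <- length(hits)
  class(out) <- c("discovery_curve", class(out))
  out
}

#' Discovery curves across a sweep of hit-calling thresholds
#'
#' Recomputes the hit set at each normalized-inhibition threshold via
#' [call_hits()] and builds one discovery curve per threshold. Thresholds
#' yielding an empty hit set are skipped with a warning.
#'
#' @param ranking a `ranking_result`.
#' @param records normalized records (`compound_id`, `k_norm`).
#' @param thresholds percent thresholds (non-empty).
#' @param fractions library fractions.
#' @return data frame of stacked curves with a `threshold` column.
#' @export
threshold_sweep <- function(ranking, records, thresholds,
                            fractions = .default_fractions) {
  if (length(thresholds) == 0L) stop("no thresholds supplied", call. = FALSE)
  out <- lapply(thresholds, function(t) {
    h <- call_hits(records, t)
    if (length(h) == 0L) {
      warning("threshold ", t, "% yields no hits; skipped", call. = FALSE)
      return(NULL)
    }
    cv <- hit_discovery_curve(ranking, h, fractions)
    cv$threshold <- t
    cv$n_hits <- length(h)
    as.data.frame(cv)
  })
  do.call(rbind, out)
}

#' Scaffold discovery-rate curve
#'
#' A cluster ("scaffold") counts as discovered at fraction `f` when at
#' least one of its members appears in the top `ceiling(f * N)` ranked
#' compounds. Optionally restricted to clusters with given potency labels
#' (e.g. `"nanomolar"` or sub-micromolar classes).
#'
#' @param ranking a `ranking_result`.
#' @param clusters a `cluster_set` over (a subset of) the ranked
#'   compounds.
#' @param labels optional cluster-label table from [label_scaffolds()].
#' @param label_filter optional character vector of labels to keep.
#' @param fractions library fractions.
#' @return data frame `method`, `fraction`, `n_top`, `value` (count of
#'   discovered scaffolds), with attribute `n_scaffolds_total`.
#' @export
scaffold_discovery_curve <- function(ranking, clusters, labels = NULL,
                                     label_filter = NULL,
                                     fractions = .default_fractions) {
  keep_clusters <- unique(clusters$cluster_id)
  if (!is.null(label_filter)) {
    if (is.null(labels)) stop("label_filter requires 'labels'", call. = FALSE)
    keep_clusters <- labels$cluster_id[labels$label %in% label_filter]
  }
  cl <- clusters[clusters$cluster_id %in% keep_clusters, , drop = FALSE]
  n <- nrow(ranking)
  pos <- match(cl$compound_id, ranking$compound_id)
  if (any(is.na(pos)))
    stop("cluster members missing from ranking universe", call. = FALSE)
  best_rank <- tapply(pos, cl$cluster_id, min)
  k <- pmin(ceiling(fractions * n), n)
  out <- data.frame(method = ranking$method[1], fraction = fractions, n_top = k,
                    value = vapply(k, function(kk) sum(best_rank <= kk),
                                   numeric(1)),
                    stringsAsFactors = FALSE)
  attr(out, "n_scaffolds_total") <- length(best_rank)
  class(out) <- c("discovery_curve", class(out))
  out
}

#' Compare virtual-screening methods
#'
#' Hit (and optionally scaffold) discovery values per method and library
#' fraction, a random-screening baseline row (expected value = fraction
#' screened), and pairwise fold-ratios of hit discovery at each fraction.
#'
#' @param rankings list of `ranking_result` objects over the same compound
#'   universe.
#' @param hits hit id vector.
#' @param clusters optional `cluster_set` for scaffold counts.
#' @param fractions library fractions.
#' @return list with `table` (method x fraction values) and `ratios`
#'   (`method_a`, `method_b`, `fraction`, `ratio`).
#' @export
compare_methods <- function(rankings, hits, clusters = NULL,
                            fractions = .default_fractions) {
  if (length(rankings) < 1L) stop("no rankings supplied", call. = FALSE)
  universe <- sort(rankings[[1]]$compound_id)
  for (r in rankings[-1]) {
    miss <- setdiff(universe, r$compound_id)
    if (length(miss) || nrow(r) != length(universe))
      stop("ranking universes differ; missing ids e.g.: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, lapply(rankings, function(r) {
    cv <- hit_discovery_curve(r, hits, fractions)
    df <- as.data.frame(cv)[, c("method", "fraction", "value")]
    if (!is.null(clusters)) {
      sc <- scaffold_discovery_curve(r, clusters, fractions = fractions)
      df$scaffolds <- sc$value
    }
    df
  }))
  baseline <- data.frame(method = "random_baseline", fraction = fractions,
                         value = fractions, stringsAsFactors = FALSE)
  if (!is.null(clusters))
    baseline$scaffolds <- NA_real_
  tab <- rbind(tab, baseline)
  rownames(tab) <- NULL

  methods <- unique(tab$method)
  ratios <- do.call(rbind, lapply(fractions, function(f) {
    v <- stats::setNames(tab$value[tab$fraction == f], tab$method[tab$fraction == f])
    prs <- expand.grid(method_a = methods, method_b = methods,
                       stringsAsFactors = FALSE)
    prs <- prs[prs$method_a != prs$method_b, ]
    data.frame(method_a = prs$method_a, method_b = prs$method_b, fraction = f,
               ratio = v[prs$method_a] / v[prs$method_b],
               stringsAsFactors = FALSE)
  }))
  rownames(ratios) <- NULL
  list(table = tab, ratios = ratios)
}
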