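# Continuous pharmacophore scoring: sub-hypotheses of a feature-point
# hypothesis are matched against conformer feature sets by injective,
# type-compatible assignment under a single rigid (Kabsch) superposition,
# and the subset matches are combined into one score in [0, 1].

.PH_TYPES <- c("donor", "acceptor", "aromatic", "hydrophobic",
               "positive", "negative")

#' Construct a pharmacophore hypothesis
#'
#' @param points data frame with columns `type` (one of donor, acceptor,
#'   aromatic, hydrophobic, positive, negative), `x`, `y`, `z` (Angstrom)
#'   and `radius` (tolerance radius, Angstrom, > 0).
#' @return object of class `pharmacophore` (the validated data frame).
#' @export
pharmacophore_hypothesis <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("type", "x", "y", "z", "radius") %in% names(points)))
  if (nrow(points) < 1L) stop("hypothesis needs at least 1 point", call. = FALSE)
  if (!all(points$type %in% .PH_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(points$type, .PH_TYPES), collapse = ", "), call. = FALSE)
  if (any(points$radius <= 0)) stop("tolerance radii must be > 0", call. = FALSE)
  if (any(!is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("feature positions must be finite", call. = FALSE)
  structure(points, class = c("pharmacophore", class(points)))
}

#' Enumerate sub-hypotheses of a pharmacophore
#'
#' All subsets with at least `min_size` points; there are
#' `sum_{k=min_size}^{n} choose(n, k)` of them.
#'
#' @param hypothesis a [pharmacophore_hypothesis()].
#' @param min_size smallest subset size (1..n).
#' @return list of `pharmacophore` objects.
#' @export
enumerate_subsets <- function(hypothesis, min_size) {
  n <- nrow(hypothesis)
  if (min_size < 1 || min_size > n)
    stop("min_size must lie in 1..", n, call. = FALSE)
  out <- list()
  for (k in min_size:n) {
    idx <- utils::combn(n, k, simplify = FALSE)
    out <- c(out, lapply(idx, function(i)
      pharmacophore_hypothesis(as.data.frame(hypothesis)[i, , drop = FALSE])))
  }
  out
}

# optimal rigid superposition (Kabsch): rotation R and translation t
# minimizing || (Q %*% R + t) - P ||; returns transformed Q
.kabsch_align <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Qc, Pc))
  d <- sign(det(s$u %*% t(s$v)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(Qc %*% Rm, 2, cp, "+")
}

#' Match a (sub-)hypothesis against one conformer's features
#'
#' TRUE when an injective assignment of hypothesis points to same-type
#' conformer features exists such that one rigid superposition places every
#' assigned feature within its point's tolerance radius. Search enumerates
#' type-compatible correspondences with pairwise-distance pruning and
#' verifies each candidate by Kabsch superposition.
#'
#' @param sub a `pharmacophore` (hypothesis or subset).
#' @param conformer data frame with `type`, `x`, `y`, `z` (a compound
#'   conformer's pharmacophoric features; may be empty).
#' @return logical.
#' @export
match_subset <- function(sub, conformer) {
  np <- nrow(sub)
  if (is.null(conformer) || nrow(conformer) == 0L) return(FALSE)
  H <- as.matrix(sub[, c("x", "y", "z")])
  Fm <- as.matrix(conformer[, c("x", "y", "z")])
  cand <- lapply(sub$type, function(tp) which(conformer$type == tp))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(FALSE)
  dH <- as.matrix(stats::dist(H))
  dF <- as.matrix(stats::dist(Fm))
  tol <- outer(sub$radius, sub$radius, "+")

  verify <- function(assign) {
    Ft <- .kabsch_align(H, Fm[assign, , drop = FALSE])
    all(sqrt(rowSums((Ft - H)^2)) <= sub$radius + 1e-9)
  }
  recurse <- function(assign) {
    i <- length(assign) + 1L
    if (i > np) return(verify(assign))
    for (f in setdiff(cand[[i]], assign)) {
      ok <- TRUE
      for (j in seq_along(assign)) {
        if (abs(dH[i, j] - dF[f, assign[j]]) > tol[i, j]) { ok <- FALSE; break }
      }
      if (ok && recurse(c(assign, f))) return(TRUE)
    }
    FALSE
  }
  recurse(integer(0))
}

#' Continuous pharmacophore score of a compound's conformer ensemble
#'
#' Let `K` be the largest subset size (of the `n`-point hypothesis) matched
#' by any conformer and `m_K` the number of distinct size-`K` subsets
#' matched. The score is `(K + m_K / choose(n, K) - 1) / n` when
#' `K >= min_size`, else 0. It lies in `[0, 1]`, equals 1 only on a full
#' match, and ranks compounds by deepest partial match, refined by the
#' breadth of matches at that depth.
#'
#' @param hypothesis a [pharmacophore_hypothesis()].
#' @param conformers list of conformer feature data frames (one compound's
#'   ensemble; non-empty list).
#' @param min_size smallest subset size worth scoring (default 3).
#' @return score in `[0, 1]`.
#' @export
continuous_score <- function(hypothesis, conformers, min_size = 3L) {
  if (length(conformers) == 0L) stop("no conformers supplied", call. = FALSE)
  n <- nrow(hypothesis)
  min_size <- min(min_size, n)
  hyp_df <- as.data.frame(hypothesis)
  for (k in n:min_size) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    m_k <- 0L
    for (idx in subsets) {
      sub <- pharmacophore_hypothesis(hyp_df[idx, , drop = FALSE])
      if (any(vapply(conformers, function(cf) match_subset(sub, cf),
                     logical(1))))
        m_k <- m_k + 1L
    }
    if (m_k > 0L)
      return((k + m_k / choose(n, k) - 1) / n)
  }
  0
}

#' Simulate conformer feature sets from a hypothesis
#'
#' Generates perturbed copies of the hypothesis's feature points: a random
#' rigid rotation + translation, Gaussian positional jitter, random feature
#' drops, and optional decoy features. Used by the synthetic pipeline to
#' exercise pharmacophore scoring without 3D conformer generation.
#'
#' @param hypothesis a [pharmacophore_hypothesis()].
#' @param n_conformers number of conformers.
#' @param jitter_sd positional noise SD (Angstrom).
#' @param drop_prob per-feature drop probability.
#' @param n_decoys number of random extra features per conformer.
#' @param seed integer seed.
#' @return list of conformer feature data frames.
#' @export
simulate_conformers <- function(hypothesis, n_conformers = 5L, jitter_sd = 0.2,
                                drop_prob = 0.1, n_decoys = 0L, seed = 1L) {
  set.seed(seed)
  H <- as.matrix(hypothesis[, c("x", "y", "z")])
  lapply(seq_len(n_conformers), function(i) {
    keep <- stats::runif(nrow(H)) >= drop_prob
    if (!any(keep)) keep[sample.int(nrow(H), 1)] <- TRUE
    Rm <- .random_rotation()
    pos <- sweep(H[keep, , drop = FALSE] %*% Rm, 2,
                 stats::rnorm(3, 0, 5), "+") +
      matrix(stats::rnorm(3 * sum(keep), 0, jitter_sd), ncol = 3)
    types <- hypothesis$type[keep]
    if (n_decoys > 0L) {
      pos <- rbind(pos, matrix(stats::runif(3 * n_decoys, -8, 8), ncol = 3))
      types <- c(types, sample(.PH_TYPES, n_decoys, replace = TRUE))
    }
    data.frame(type = types, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE)
  })
}

# uniform-ish random rotation via QR of a Gaussian matrix, det +1
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Rm <- qr.Q(qr_)
  if (det(Rm) < 0) Rm[, 1] <- -Rm[, 1]
  Rm
}
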