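# Shared fixtures and independent oracles, built in code at test time.

# control wells with exact sample mean/SD (n-1), via affine rescale
exact_controls <- function(n, mu, sigma, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  mu + sigma * x
}

# a single synthetic plate data frame with given exact control stats
make_plate <- function(plate_id = "P001", mu_neg = 0, sigma_neg = 5,
                       mu_pos = 100, sigma_pos = 5, n_ctrl = 32, seed = 1) {
  data.frame(
    plate_id = plate_id,
    well = sprintf("W%02d", seq_len(2 * n_ctrl)),
    role = rep(c("neg", "pos"), each = n_ctrl),
    compound_id = "",
    raw_value = c(exact_controls(n_ctrl, mu_neg, sigma_neg, seed),
                  exact_controls(n_ctrl, mu_pos, sigma_pos, seed + 1)),
    stringsAsFactors = FALSE)
}

# fingerprint row with exactly the given bits set
bits_fp <- function(bits, len = 16) {
  v <- logical(len)
  v[bits] <- TRUE
  v
}

# --- independent oracle: every prefix of a ranking, enumerated directly ---
oracle_hit_curve <- function(ordered_ids, hits, fractions) {
  n <- length(ordered_ids)
  vapply(fractions, function(f) {
    top <- ordered_ids[seq_len(min(ceiling(f * n), n))]
    length(intersect(top, hits)) / length(hits)
  }, numeric(1))
}

# --- independent oracle: exhaustive-partition modularity maximum ---
all_set_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_set_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

best_modularity_partition <- function(g) {
  parts <- all_set_partitions(igraph::vcount(g))
  mods <- vapply(parts, function(p) igraph::modularity(g, p), numeric(1))
  list(membership = parts[[which.max(mods)]], modularity = max(mods))
}

# --- independent oracle: exhaustive injective assignment pharmacophore match
oracle_kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(t(Qc) %*% Pc)
  d <- sign(det(s$u %*% t(s$v)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(Qc %*% Rm, 2, cp, "+")
}

oracle_match <- function(sub, conf) {
  np <- nrow(sub)
  if (nrow(conf) == 0) return(FALSE)
  H <- as.matrix(sub[, c("x", "y", "z")])
  Fm <- as.matrix(conf[, c("x", "y", "z")])
  found <- FALSE
  assign_next <- function(assign) {
    if (found) return(invisible(NULL))
    i <- length(assign) + 1L
    if (i > np) {
      Ft <- oracle_kabsch(H, Fm[assign, , drop = FALSE])
      if (all(sqrt(rowSums((Ft - H)^2)) <= sub$radius + 1e-9)) found <<- TRUE
      return(invisible(NULL))
    }
    for (f in setdiff(which(conf$type == sub$type[i]), assign))
      assign_next(c(assign, f))
  }
  assign_next(integer(0))
  found
}

# random rigid transform of a coordinate matrix
apply_random_rigid <- function(X, seed) {
  set.seed(seed)
  q <- qr(matrix(rnorm(9), 3))
  Rm <- qr.Q(q)
  if (det(Rm) < 0) Rm[, 1] <- -Rm[, 1]
  sweep(X %*% Rm, 2, rnorm(3, 0, 10), "+")
}

# small non-degenerate 6-point hypothesis used across pharmacophore tests
hyp6 <- function() {
  pharmacophore_hypothesis(data.frame(
    type = c("donor", "acceptor", "aromatic", "hydrophobic", "acceptor", "donor"),
    x = c(0, 3, 1, 4, 2, 5), y = c(0, 0, 2, 3, 5, 1), z = c(0, 1, 4, 0, 2, 3),
    radius = 1))
}
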