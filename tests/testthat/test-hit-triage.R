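# Hit calling, similarity graphs, Louvain clustering with an exhaustive
# modularity oracle, scaffolds, diversification and novelty counts.

test_that("hit calling is boundary-inclusive at the threshold", {
  rec <- data.frame(compound_id = c("a", "b", "c"), k_norm = c(60, 40, 55))
  expect_setequal(call_hits(rec, 50), c("a", "c"))
  expect_setequal(call_hits(rec, 55), c("a", "c"))  # >= is inclusive
  rec2 <- rbind(rec, data.frame(compound_id = "d", k_norm = -3))
  expect_setequal(call_hits(rec2, 0), c("a", "b", "c"))
  expect_error(call_hits(data.frame(compound_id = "a", k_norm = NA)), "normalize")
})

test_that("ligand-efficiency proxy is activity per unit mass", {
  expect_equal(ligand_efficiency_proxy(80, 400), 0.2)
  expect_equal(ligand_efficiency_proxy(0, 350), 0)
  expect_gt(ligand_efficiency_proxy(50, 300), ligand_efficiency_proxy(50, 400))
  expect_error(ligand_efficiency_proxy(50, 0), "> 0")
})

test_that("similarity graph edges respect the threshold", {
  fps <- rbind(a = bits_fp(1:6, 16), b = bits_fp(c(1:5, 7), 16),
               c = bits_fp(9:14, 16), d = bits_fp(c(9:13, 15), 16))
  # within families TS = 5/7 ~ 0.714; across = 0
  g <- build_similarity_graph(fps, 1.01)
  expect_equal(igraph::ecount(g), 0)
  g0 <- build_similarity_graph(fps, 0)
  expect_equal(igraph::ecount(g0), 4 * 3 / 2)
  g4 <- build_similarity_graph(fps, 0.4)
  expect_equal(igraph::count_components(g4), 2)
  expect_equal(igraph::ecount(g4), 2)
  expect_equal(unname(igraph::E(g4)$weight), c(5 / 7, 5 / 7))
})

test_that("Louvain recovers cliques and matches the exhaustive modularity oracle", {
  # edgeless graph: all singletons
  fps <- diag(6) > 0
  rownames(fps) <- paste0("x", 1:6)
  ge <- build_similarity_graph(fps, 0.5)
  cl <- louvain_cluster(ge, seed = 1)
  expect_equal(length(unique(cl$cluster_id)), 6)
  # two disjoint triangles: recovered for any seed, and modularity equals
  # the exhaustive-partition maximum
  g2 <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::V(g2)$name <- paste0("v", 1:6)
  igraph::E(g2)$weight <- 1
  oracle <- best_modularity_partition(g2)
  for (s in 1:5) {
    cls <- louvain_cluster(g2, seed = s)
    expect_equal(length(unique(cls$cluster_id)), 2)
    expect_equal(cls$cluster_id[1:3], rep(cls$cluster_id[1], 3))
    expect_equal(igraph::modularity(g2, cls$cluster_id), oracle$modularity)
  }
  # determinism for a fixed seed on a harder graph
  set.seed(99)
  g3 <- igraph::sample_gnp(40, 0.15)
  igraph::V(g3)$name <- paste0("n", 1:40)
  igraph::E(g3)$weight <- runif(igraph::ecount(g3), 0.4, 1)
  expect_identical(louvain_cluster(g3, seed = 7), louvain_cluster(g3, seed = 7))
})

test_that("clustering output is an exact partition of the hit set", {
  cfg <- sim_config(n_compounds = 2000, active_fraction = 0.05, seed = 21)
  lib <- generate_library(cfg)
  scr <- simulate_primary_screen(lib, cfg)
  ns <- normalize_screen(scr)
  samp <- ns$readings[ns$readings$role == "sample", ]
  hits <- call_hits(samp, 50)
  fps <- fingerprint_matrix(stats::setNames(
    lib$smiles[match(hits, lib$compound_id)], hits))
  cl <- louvain_cluster(build_similarity_graph(fps, 0.4), seed = 1)
  expect_setequal(cl$compound_id, hits)
  expect_equal(anyDuplicated(cl$compound_id), 0)
})

test_that("cluster scaffolds use MCS for groups and frameworks for singletons", {
  lib <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("O=C(NC)c1ccc(F)cc1", "O=C(NCC)c1ccc(Cl)cc1", "Cc1ccncc1"))
  cl <- data.frame(compound_id = c("a", "b", "c"), cluster_id = c(1L, 1L, 2L))
  class(cl) <- c("cluster_set", class(cl))
  sc <- cluster_scaffolds(cl, lib)
  expect_equal(sc$n_members, c(2, 1))
  # shared benzamide substructure O=C(N-)c1ccc(-)cc1 has 10 heavy atoms
  expect_equal(length(parse_smiles(sc$scaffold_smiles[1])$element), 10)
  expect_equal(sc$scaffold_smiles[2], canonical_smiles("c1ccncc1"))
})

test_that("diversification takes the top-LE members per cluster", {
  rec <- data.frame(compound_id = sprintf("c%02d", 1:10),
                    k_norm = c(90, 80, 70, 60, 50, 40, 95, 20, 95, 30),
                    mw = rep(c(300, 400), 5))
  cl <- data.frame(compound_id = rec$compound_id,
                   cluster_id = c(rep(1L, 7), rep(2L, 3)))
  class(cl) <- c("cluster_set", class(cl))
  div <- diversify(cl, rec, k_per_cluster = 5)
  expect_equal(sum(div$cluster_id == 1), 5)
  expect_equal(sum(div$cluster_id == 2), 3)   # smaller cluster kept whole
  # every selected member has LE >= every unselected member of its cluster
  le <- ligand_efficiency_proxy(rec$k_norm, rec$mw)
  names(le) <- rec$compound_id
  sel1 <- div$compound_id[div$cluster_id == 1]
  uns1 <- setdiff(rec$compound_id[cl$cluster_id == 1], sel1)
  expect_gte(min(le[sel1]), max(le[uns1]))
  # size identity: sum over clusters of min(k, size)
  expect_equal(nrow(div), min(5, 7) + min(5, 3))
})

test_that("ties in ligand efficiency break by compound id", {
  rec <- data.frame(compound_id = c("b", "a", "c"), k_norm = 50, mw = 250)
  cl <- data.frame(compound_id = rec$compound_id, cluster_id = 1L)
  class(cl) <- c("cluster_set", class(cl))
  expect_equal(diversify(cl, rec, 2)$compound_id, c("a", "b"))
})

test_that("scaffold labels follow the most active member", {
  cl <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                   cluster_id = c(1L, 1L, 2L, 2L, 3L))
  class(cl) <- c("cluster_set", class(cl))
  p <- data.frame(compound_id = c("a", "b", "c", "d"),
                  pic50 = c(7.3, 5.0, 5.2, 4.6))
  lab <- label_scaffolds(cl, p)
  expect_equal(lab$label, c("nanomolar", "micromolar", "unlabeled"))
  expect_equal(lab$best_pic50, c(7.3, 5.2, NA))
})

test_that("novelty counts use strict nearest-neighbor thresholds", {
  # fixture with known nearest-neighbor similarities 0.3, 0.5, 0.9
  # (hits occupy disjoint bit blocks so each has exactly one near reference)
  hits <- rbind(h1 = bits_fp(1:6, 64), h2 = bits_fp(11:16, 64),
                h3 = bits_fp(21:29, 64))
  refs <- rbind(r1 = bits_fp(c(1:3, 7:10), 64),      # TS(h1) = 3/10 = 0.3
                r2 = bits_fp(c(11:14, 17, 18), 64),  # TS(h2) = 4/8  = 0.5
                r3 = bits_fp(21:30, 64))             # TS(h3) = 9/10 = 0.9
  # brute-force all-pairs oracle for the nearest neighbor
  nn <- apply(hits, 1, function(h) max(apply(refs, 1, tanimoto, fp_b = h)))
  expect_equal(unname(nn), c(0.3, 0.5, 0.9))
  nv <- novelty_counts(hits, refs, c(0.4, 0.6, 0.95))
  expect_equal(nv$n_hits, c(2, 1, 0))
  # monotone non-increasing in the threshold
  expect_true(all(diff(nv$n_hits) <= 0))
  # reference = hits: everything counted below 1
  nv2 <- novelty_counts(hits, hits, c(0, 0.4, 0.99))
  expect_equal(nv2$n_hits, c(3, 3, 3))
  # empty reference: zero counts
  nv3 <- novelty_counts(hits, hits[0, , drop = FALSE], c(0.4))
  expect_equal(nv3$n_hits, 0)
  # scaffold counts via cluster membership
  cl <- data.frame(compound_id = c("h1", "h2", "h3"), cluster_id = c(1L, 1L, 2L))
  nv4 <- novelty_counts(hits, refs, c(0.4), clusters = cl)
  expect_equal(nv4$n_scaffolds, 2)
})
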