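# Discovery-rate curves, threshold sweeps, scaffold discovery and method
# comparison, checked against a direct prefix-enumeration oracle.

test_that("rankings are total, deterministic and tie-broken by id", {
  r <- ranking_result("m", c("b", "a", "c"), c(1, 2, 1))
  expect_equal(r$compound_id, c("a", "b", "c"))
  expect_equal(r$rank, 1:3)
  expect_error(ranking_result("m", c("a", "a"), c(1, 2)), "duplicate")
})

test_that("discovery curves equal the prefix-enumeration oracle for N <= 50", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    ids <- sprintf("c%03d", seq_len(n))
    score <- runif(n)
    hits <- sample(ids, sample(1:5, 1))
    fr <- sort(unique(c(runif(5), 1)))
    r <- ranking_result("m", ids, score)
    cv <- hit_discovery_curve(r, hits, fr)
    expect_equal(cv$value, oracle_hit_curve(r$compound_id, hits, fr))
  }
})

test_that("discovery curves are monotone and saturate at exactly 1", {
  set.seed(3)
  ids <- sprintf("c%04d", 1:500)
  r <- ranking_result("m", ids, runif(500))
  hits <- sample(ids, 40)
  cv <- hit_discovery_curve(r, hits)
  expect_true(all(diff(cv$value) >= 0))
  expect_equal(cv$value[cv$fraction == 1], 1)
  # all hits ranked first: saturated already at f = |hits|/N
  r2 <- ranking_result("m", ids, ifelse(ids %in% hits, 2, runif(500)))
  cv2 <- hit_discovery_curve(r2, hits, c(40 / 500, 0.5, 1))
  expect_equal(cv2$value, c(1, 1, 1))
  expect_error(hit_discovery_curve(r, character(0)), "empty hit set")
  expect_error(hit_discovery_curve(r, "zzz"), "outside ranking universe")
})

test_that("threshold sweep recomputes nested hit sets per threshold", {
  set.seed(5)
  ids <- sprintf("c%03d", 1:200)
  rec <- data.frame(compound_id = ids, k_norm = runif(200, -10, 110))
  r <- ranking_result("m", ids, runif(200))
  sw <- threshold_sweep(r, rec, c(50, 80))
  expect_equal(sort(unique(sw$threshold)), c(50, 80))
  n50 <- unique(sw$n_hits[sw$threshold == 50])
  n80 <- unique(sw$n_hits[sw$threshold == 80])
  expect_gt(n50, n80)
  # nesting: the stricter hit set is a subset of the looser one
  expect_true(all(call_hits(rec, 80) %in% call_hits(rec, 50)))
  expect_warning(threshold_sweep(r, rec, c(50, 200)), "no hits")
})

test_that("scaffold discovery counts clusters by their best-ranked member", {
  ids <- sprintf("c%02d", 1:20)
  r <- ranking_result("m", ids, 20:1)   # c01 ranked first
  cl <- data.frame(compound_id = c("c01", "c15", "c20", "c10"),
                   cluster_id = c(1L, 1L, 2L, 3L))
  class(cl) <- c("cluster_set", class(cl))
  cv <- scaffold_discovery_curve(r, cl, fractions = c(0.05, 0.5, 1))
  # cluster 1 discovered from the very top; all three by f = 1
  expect_equal(cv$value, c(1, 2, 3))
  expect_true(all(diff(cv$value) >= 0))
  expect_equal(cv$value[cv$fraction == 1], length(unique(cl$cluster_id)))
  # label filter restricts the denominator
  lab <- data.frame(cluster_id = 1:3,
                    label = c("nanomolar", "micromolar", "nanomolar"))
  cvn <- scaffold_discovery_curve(r, cl, labels = lab,
                                  label_filter = "nanomolar",
                                  fractions = c(0.05, 1))
  expect_equal(cvn$value, c(1, 2))
})

test_that("method comparison reports fold-ratios and a random baseline", {
  set.seed(9)
  ids <- sprintf("c%03d", 1:300)
  act <- c(rep(1, 15), rep(0, 285))
  hits <- ids[act == 1]
  cfg <- sim_config(n_compounds = 300,
                    score_enrichment = c(good = 1, bad = 0), seed = 2)
  sc <- simulate_method_scores(
    data.frame(compound_id = ids, true_inhibition = act * 100), cfg)
  rk <- rankings_from_scores(sc)
  cmp <- compare_methods(rk, hits, fractions = c(0.01, 0.05, 0.1, 1))
  expect_true("random_baseline" %in% cmp$table$method)
  expect_equal(cmp$table$value[cmp$table$method == "random_baseline"],
               c(0.01, 0.05, 0.1, 1))
  # a perfectly enriched method crushes an unenriched one early on
  r01 <- cmp$ratios[cmp$ratios$fraction == 0.05 &
                      cmp$ratios$method_a == "good" &
                      cmp$ratios$method_b == "bad", "ratio"]
  expect_gt(r01, 3)
  # identical rankings: ratio exactly 1 everywhere
  cmp2 <- compare_methods(list(a = transform(rk$good, method = "a"),
                               b = transform(rk$good, method = "b")),
                          hits, fractions = c(0.01, 0.5, 1))
  expect_true(all(cmp2$ratios$ratio[cmp2$ratios$method_a %in% c("a", "b") &
                                      cmp2$ratios$method_b %in% c("a", "b")] == 1))
  # universe mismatch is an error listing missing ids
  rbad <- ranking_result("c", ids[-1], seq_len(299))
  expect_error(compare_methods(list(rk$good, rbad), hits), "universes differ")
})

test_that("random rankings average to the diagonal", {
  set.seed(17)
  ids <- sprintf("c%04d", 1:400)
  hits <- sample(ids, 30)
  fr <- c(0.05, 0.1, 0.2, 0.5, 1)
  vals <- replicate(300, {
    r <- ranking_result("r", ids, runif(400))
    hit_discovery_curve(r, hits, fr)$value
  })
  expect_lt(max(abs(rowMeans(vals) - fr)), 0.05)
})
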