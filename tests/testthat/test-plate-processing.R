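# Plate statistics, Z-prime QC, normalization and hit confirmation.

test_that("Z-prime matches direct substitution on constructed plates", {
  # zero-variance controls: Z' = 1 exactly
  p0 <- make_plate(mu_neg = 0, sigma_neg = 0, mu_pos = 100, sigma_pos = 0)
  expect_equal(compute_plate_stats(p0)$zprime, 1)
  # 100 +/- 5 vs 0 +/- 5: Z' = 1 - 3*10/100 = 0.7
  p7 <- make_plate(mu_neg = 0, sigma_neg = 5, mu_pos = 100, sigma_pos = 5)
  s7 <- compute_plate_stats(p7)
  expect_equal(s7$zprime, 0.7)
  expect_true(s7$passed_qc)
  # 100 +/- 10 vs 0 +/- 10: Z' = 0.4, fails QC at the 0.5 minimum
  p4 <- make_plate(sigma_neg = 10, sigma_pos = 10)
  s4 <- compute_plate_stats(p4)
  expect_equal(s4$zprime, 0.4)
  expect_false(s4$passed_qc)
})

test_that("degenerate and malformed plates are rejected", {
  pd <- make_plate(mu_neg = 50, sigma_neg = 0, mu_pos = 50, sigma_pos = 0)
  expect_error(compute_plate_stats(pd), "degenerate")
  p <- make_plate()
  expect_error(compute_plate_stats(p[p$role == "neg", ]), "layout")
})

test_that("Z-prime is invariant under common affine transforms of the signal", {
  p <- make_plate(mu_neg = 10000, sigma_neg = 400, mu_pos = 2000, sigma_pos = 350)
  z0 <- compute_plate_stats(p)$zprime
  for (ab in list(c(2, 0), c(1, 500), c(0.3, -100))) {
    q <- p
    q$raw_value <- ab[1] * p$raw_value + ab[2]
    expect_equal(compute_plate_stats(q)$zprime, z0)
  }
  # and strictly decreases as control SDs grow, means fixed
  zs <- vapply(c(2, 5, 8, 12), function(s)
    compute_plate_stats(make_plate(sigma_neg = s, sigma_pos = s))$zprime,
    numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("normalization anchors controls at 0%/100% and is invertible", {
  p <- make_plate(mu_neg = 1000, sigma_neg = 20, mu_pos = 200, sigma_pos = 20)
  p <- rbind(p, data.frame(plate_id = "P001", well = "S01", role = "sample",
                           compound_id = "cpd1", raw_value = 600))
  st <- compute_plate_stats(p)
  nr <- normalize_plate(p, st)
  expect_equal(mean(nr$k_norm[nr$role == "neg"]), 0, tolerance = 1e-12)
  expect_equal(mean(nr$k_norm[nr$role == "pos"]), 100, tolerance = 1e-12)
  # signal decreases with inhibition; halfway raw value -> 50%
  expect_equal(nr$k_norm[nr$role == "sample"], 50)
  # affine and invertible
  back <- st$mu_neg + nr$k_norm / 100 * (st$mu_pos - st$mu_neg)
  expect_equal(back, p$raw_value, tolerance = 1e-9)
  expect_error(normalize_plate(transform(p, plate_id = "P999"), st), "mismatch")
})

test_that("qc_filter partitions plates exhaustively and disjointly", {
  plates <- do.call(rbind, lapply(1:153, function(i)
    make_plate(plate_id = sprintf("P%03d", i),
               sigma_neg = if (i <= 3) 10 else 4,
               sigma_pos = if (i <= 3) 10 else 4, seed = i)))
  st <- compute_plate_stats(plates)
  qc <- qc_filter(st, 0.5)
  expect_equal(length(qc$failed_ids), 3)
  expect_setequal(qc$failed_ids, sprintf("P%03d", 1:3))
  expect_equal(nrow(qc$passed) + length(qc$failed_ids), 153)
  expect_length(intersect(qc$passed$plate_id, qc$failed_ids), 0)
  # a bound above the attainable maximum fails everything
  expect_equal(length(qc_filter(st, 1.1)$failed_ids), 153)
  expect_equal(length(qc_filter(st, -10)$failed_ids), 0)
})

test_that("noiseless synthetic screens pass QC on every plate", {
  cfg <- sim_config(n_compounds = 640, well_sigma = 1e-9, seed = 9)
  scr <- simulate_primary_screen(generate_library(cfg), cfg)
  st <- compute_plate_stats(scr)
  expect_true(all(st$passed_qc))
  expect_true(all(st$zprime > 1 - 1e-9))
})

test_that("confirmation metrics follow their set-based definitions", {
  prim <- sprintf("h%02d", 1:94)
  # identity: everything confirmed
  m <- confirmation_metrics(prim, list(prim, prim, prim))
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
  # 88 of 94 confirmed, none new: precision 88/94, recall 100
  conf88 <- prim[1:88]
  m2 <- confirmation_metrics(prim, list(prim[1:90], conf88, c(conf88, prim[91])))
  expect_equal(length(m2$confirmed), 88)
  expect_equal(m2$precision, 100 * 88 / 94, tolerance = 1e-12)
  expect_equal(m2$recall, 100)
  # a consensus hit absent from the primary screen lowers recall below 100
  m3 <- confirmation_metrics(prim, list(c(prim, "new1"), c(prim, "new1")))
  expect_lt(m3$recall, 100)
  expect_equal(m3$precision, 100)
  expect_error(confirmation_metrics(character(0), list(prim)), "precision undefined")
})

test_that("replicate correlation is reported per plate and pair", {
  set.seed(1)
  base <- rnorm(40, 50, 30)
  vals <- do.call(rbind, lapply(1:3, function(r)
    data.frame(plate_id = rep(c("P1", "P2"), each = 20),
               compound_id = sprintf("c%02d", 1:40),
               replicate = r, k_norm = base + rnorm(40, 0, 5))))
  rc <- replicate_correlation(vals)
  expect_equal(nrow(rc), 6)  # 2 plates x 3 replicate pairs
  expect_true(all(rc$correlation > 0.8))
})
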