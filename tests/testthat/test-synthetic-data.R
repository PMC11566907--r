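# The synthetic-data generator: determinism, layout arithmetic, ground
# truth statistics, and its noiseless limits.

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_compounds = 0), "n_compounds")
  expect_error(sim_config(active_fraction = 1.5), "active_fraction")
  expect_error(sim_config(well_sigma = 0), "well_sigma")
  expect_error(sim_config(dose_series = c(1, 2, 3)), "dose_series")
  expect_error(sim_config(dose_series = c(3, 2, -1)), "dose_series")
  expect_error(sim_config(score_enrichment = c(0.5, 0.2)), "score_enrichment")
  expect_error(sim_config(score_enrichment = c(a = 1.2)), "score_enrichment")
})

test_that("library generation is unique, valid and seed-deterministic", {
  cfg <- sim_config(n_compounds = 100, seed = 7)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 100)
  expect_false(anyDuplicated(lib$compound_id) > 0)
  expect_false(anyDuplicated(lib$smiles) > 0)
  expect_true(all(lib$mw > 0))
  expect_true(all(lib$n_undefined_stereocenters %in% 0:6))
  # every structure parses
  expect_silent(lapply(lib$smiles, parse_smiles))
  expect_identical(lib, generate_library(sim_config(n_compounds = 100, seed = 7)))
  # different seed, different draw
  expect_false(identical(lib$smiles,
                         generate_library(sim_config(n_compounds = 100, seed = 8))$smiles))
})

test_that("stereocenter counts span the expected range at n = 1000", {
  lib <- generate_library(sim_config(n_compounds = 1000, seed = 7))
  expect_true(all(c(0, 1, 2, 5) %in% unique(lib$n_undefined_stereocenters)))
})

test_that("plate layout has 32 + 32 controls and samples in columns 3-22", {
  cfg <- sim_config(n_compounds = 320, seed = 1)
  lib <- generate_library(cfg)
  scr <- simulate_primary_screen(lib, cfg)
  expect_equal(nrow(scr), 384)
  expect_equal(sum(scr$role == "sample"), 320)
  expect_equal(sum(scr$role == "neg"), 32)
  expect_equal(sum(scr$role == "pos"), 32)
  col <- as.integer(substring(scr$well, 2))
  expect_true(all(col[scr$role == "neg"] %in% 1:2))
  expect_true(all(col[scr$role == "pos"] %in% 23:24))
  expect_true(all(col[scr$role == "sample"] %in% 3:22))
  expect_true(all(scr$compound_id[scr$role == "sample"] %in% lib$compound_id))
  # capacity error names the required plate count
  cfg2 <- sim_config(n_compounds = 321, n_plates = 1, seed = 1)
  expect_error(simulate_primary_screen(generate_library(cfg2), cfg2),
               "2 plates required")
})

test_that("noiseless actives at 100% inhibition read exactly pos_mu", {
  cfg <- sim_config(n_compounds = 10, active_fraction = 1,
                    active_inhibition_mean = 100, active_inhibition_sd = 1e-9,
                    well_sigma = 1e-9, seed = 2)
  scr <- simulate_primary_screen(generate_library(cfg), cfg)
  samp <- scr[scr$role == "sample", ]
  expect_equal(samp$raw_value, rep(cfg$pos_mu, 10), tolerance = 1e-6)
})

test_that("realized active count is binomial around the configured rate", {
  cfg <- sim_config(seed = 1)  # study-scale defaults: n = 46743, p = 0.0076
  scr <- simulate_primary_screen(generate_library(cfg), cfg)
  n_active <- sum(scr$is_active, na.rm = TRUE)
  expected <- cfg$n_compounds * cfg$active_fraction
  band <- 3 * sqrt(expected * (1 - cfg$active_fraction))
  expect_gt(n_active, expected - band)
  expect_lt(n_active, expected + band)
  # regeneration with the same config is bitwise identical
  expect_identical(scr, simulate_primary_screen(generate_library(cfg), cfg))
})

test_that("dose-response simulation follows the 4PL at the configured doses", {
  cfg <- sim_config(n_compounds = 10, dr_noise_sd = 0, seed = 5)
  tf <- data.frame(compound_id = c("a", "b"), A = 100, B = 1.3,
                   C = c(0.469, 2), D = 0)
  dr <- simulate_dose_response(tf, cfg)
  # 8 concentrations x 3 replicates per compound
  expect_equal(nrow(dr), 2 * 8 * 3)
  expect_equal(sort(unique(dr$conc_uM)), sort(cfg$dose_series))
  # at x = C the noiseless response is the midpoint (A + D) / 2
  mid <- dr$response[dr$compound_id == "a" & dr$conc_uM == 0.469]
  expect_equal(mid, rep(50, 3))
  # as x -> 0 the response approaches D
  lo <- dr$response[dr$compound_id == "b" & dr$conc_uM == 0.002]
  expect_lt(max(abs(lo - 0)), 0.2)
  expect_error(simulate_dose_response(tf, sim_config(dose_series = c(3, 0))),
               "dose_series")
})

test_that("method scores interpolate between random and activity-sorted", {
  truth <- data.frame(compound_id = sprintf("c%02d", 1:50),
                      true_inhibition = seq(99, 1, length.out = 50))
  cfg <- sim_config(n_compounds = 50,
                    score_enrichment = c(perfect = 1, none = 0), seed = 3)
  sc <- simulate_method_scores(truth, cfg)
  r <- rankings_from_scores(sc)
  # enrichment 1: ranking sorted exactly by true activity
  expect_identical(r$perfect$compound_id, truth$compound_id)
  # determinism
  expect_identical(sc, simulate_method_scores(truth, cfg))
  expect_error(simulate_method_scores(truth, cfg, methods = "nope"),
               "unknown method")
})

test_that("hit recovery is monotone non-increasing in the calling threshold", {
  thresholds <- c(30, 50, 70, 90)
  recov <- matrix(NA_real_, nrow = 100, ncol = length(thresholds))
  for (s in 1:100) {
    cfg <- sim_config(n_compounds = 1000, active_fraction = 0.02, seed = s)
    scr <- simulate_primary_screen(generate_library(cfg), cfg)
    ns <- normalize_screen(scr)
    samp <- ns$readings[ns$readings$role == "sample", ]
    actives <- samp$compound_id[samp$is_active]
    if (length(actives) == 0) next
    recov[s, ] <- vapply(thresholds, function(t)
      length(intersect(call_hits(samp, t), actives)) / length(actives),
      numeric(1))
  }
  avg <- colMeans(recov, na.rm = TRUE)
  expect_true(all(diff(avg) <= 0))
})

test_that("rescreening preserves layout and truth, redraws only the noise", {
  cfg <- sim_config(n_compounds = 320, seed = 6)
  scr <- simulate_primary_screen(generate_library(cfg), cfg)
  r1 <- rescreen(scr, cfg, noise_seed = 42)
  expect_identical(r1[, c("plate_id", "well", "role", "compound_id",
                          "true_inhibition", "is_active")],
                   scr[, c("plate_id", "well", "role", "compound_id",
                           "true_inhibition", "is_active")])
  expect_false(identical(r1$raw_value, scr$raw_value))
  expect_identical(r1, rescreen(scr, cfg, noise_seed = 42))
  # replicate screens confirm nearly all strong hits
  ns0 <- normalize_screen(scr); ns1 <- normalize_screen(r1)
  h0 <- call_hits(ns0$readings[ns0$readings$role == "sample", ], 50)
  h1 <- call_hits(ns1$readings[ns1$readings$role == "sample", ], 50)
  strong <- scr$compound_id[!is.na(scr$is_active) & scr$is_active &
                              scr$true_inhibition > 70]
  if (length(strong)) {
    expect_true(all(strong %in% h0))
    expect_true(all(strong %in% h1))
  }
})

test_that("simulation CSVs round-trip through the exchange schema", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_compounds = 50, seed = 4)
  lib <- generate_library(cfg)
  scr <- simulate_primary_screen(lib, cfg)
  write_simulation(dir, library = lib, readings = scr)
  lib2 <- read.csv(file.path(dir, "library.csv"))
  expect_equal(lib2$smiles, lib$smiles)
  plates <- read.csv(file.path(dir, "plates.csv"), colClasses = "character")
  expect_equal(nrow(plates), nrow(scr))
})
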