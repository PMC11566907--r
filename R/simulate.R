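# Synthetic-data generator emulating a 46,743-compound single-point kinase
# screen on 384-well plates, plus its secondary dose-response assay and
# virtual-screening method scores. Every downstream module consumes only
# these outputs, so the full pipeline runs without external data.

.stage_seed <- function(seed, stage) {
  offsets <- c(library = 101L, screen = 202L, dr = 303L, scores = 404L,
               truefits = 505L, conformers = 606L)
  as.integer((as.numeric(seed) * 1000003 + offsets[[stage]]) %% 2147483647)
}

#' Simulation configuration for the synthetic screen
#'
#' Defaults reproduce the study conditions the pipeline is designed around:
#' a 46,743-compound diversity library screened at single point on 16 x 24
#' plates (columns 1-2 negative/DMSO controls, 23-24 positive/staurosporine
#' controls, samples in columns 3-22), ~0.76% true actives with strong
#' inhibition, Gaussian plate noise calibrated to Z' ~ 0.7, an 8-point
#' ~4-fold dilution dose series from 30 uM in triplicate, and per-method
#' rank enrichment of actives.
#'
#' @param n_compounds library size.
#' @param active_fraction probability a compound is a true active.
#' @param n_plates number of plates; `NULL` derives the minimum needed.
#' @param plate_rows,plate_cols plate geometry (16 x 24 = 384 wells).
#' @param neg_mu,pos_mu mean raw ratio-channel fluorescence (arbitrary
#'   units) of negative (no inhibition, high signal) and positive (full
#'   inhibition, low signal) control wells.
#' @param well_sigma per-well Gaussian noise SD, same units.
#' @param active_inhibition_mean,active_inhibition_sd true-inhibition
#'   distribution (percent) of actives, truncated to `[0, 120]`.
#' @param dose_series dose-response concentrations (uM), strictly
#'   decreasing.
#' @param n_replicates dose-response replicates per concentration.
#' @param dr_noise_sd dose-response response noise SD (percent).
#' @param class_probs named probabilities of micromolar / high-nanomolar /
#'   nanomolar true potency among assayed actives.
#' @param score_enrichment named vector in `[0, 1]`: per virtual-screening
#'   method, how strongly scores track true activity (0 = random,
#'   1 = perfect).
#' @param seed integer master seed; each generator stage draws from its own
#'   derived substream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 46743L,
                       active_fraction = 0.0076,
                       n_plates = NULL,
                       plate_rows = 16L,
                       plate_cols = 24L,
                       neg_mu = 10000,
                       pos_mu = 2000,
                       well_sigma = 400,
                       active_inhibition_mean = 85,
                       active_inhibition_sd = 15,
                       dose_series = c(30, 7.5, 1.875, 0.469, 0.117,
                                       0.029, 0.007, 0.002),
                       n_replicates = 3L,
                       dr_noise_sd = 2,
                       class_probs = c(micromolar = 0.894,
                                       high_nanomolar = 0.088,
                                       nanomolar = 0.018),
                       score_enrichment = c(deeplearn = 0.30,
                                            docking = 0.10,
                                            qsar = 0.12,
                                            pharmacophore = 0.01),
                       seed = 1L) {
  bad <- function(field, why) stop("invalid configuration: '", field, "' ", why,
                                   call. = FALSE)
  if (!is.numeric(n_compounds) || length(n_compounds) != 1L || n_compounds < 1)
    bad("n_compounds", "must be a single count >= 1")
  if (!is.numeric(active_fraction) || active_fraction < 0 || active_fraction > 1)
    bad("active_fraction", "must lie in [0, 1]")
  if (!is.numeric(well_sigma) || well_sigma <= 0)
    bad("well_sigma", "must be > 0")
  if (plate_rows < 1 || plate_cols < 5)
    bad("plate_rows/plate_cols", "leave no sample columns")
  if (length(dose_series) < 1 || any(dose_series <= 0))
    bad("dose_series", "must be positive concentrations")
  if (any(diff(dose_series) >= 0))
    bad("dose_series", "must be strictly decreasing")
  if (n_replicates < 1) bad("n_replicates", "must be >= 1")
  if (dr_noise_sd < 0) bad("dr_noise_sd", "must be >= 0")
  if (is.null(names(score_enrichment)) || any(!nzchar(names(score_enrichment))))
    bad("score_enrichment", "must be a named vector of method strengths")
  if (any(score_enrichment < 0 | score_enrichment > 1))
    bad("score_enrichment", "entries must lie in [0, 1]")
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0))
    bad("class_probs", "must be probabilities summing to 1")
  if (!is.numeric(seed) || length(seed) != 1L) bad("seed", "must be an integer")

  cfg <- list(n_compounds = as.integer(n_compounds),
              active_fraction = active_fraction,
              n_plates = if (is.null(n_plates)) NULL else as.integer(n_plates),
              plate_rows = as.integer(plate_rows),
              plate_cols = as.integer(plate_cols),
              neg_mu = neg_mu, pos_mu = pos_mu, well_sigma = well_sigma,
              active_inhibition_mean = active_inhibition_mean,
              active_inhibition_sd = active_inhibition_sd,
              dose_series = dose_series, n_replicates = as.integer(n_replicates),
              dr_noise_sd = dr_noise_sd, class_probs = class_probs,
              score_enrichment = score_enrichment, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_compounds, "compounds,",
      sprintf("%.2f%%", 100 * x$active_fraction), "active fraction,",
      x$plate_rows, "x", x$plate_cols, "plates, seed", x$seed, "\n")
  invisible(x)
}

#' Generate the synthetic compound library
#'
#' Draws `n_compounds` unique structures (without replacement) from the
#' built-in template grid: 14 chemotype cores x combinatorial substituents
#' at two slots. Each record carries an identifier, SMILES, molecular
#' weight, and the number of undefined stereocenters contributed by its
#' substituents.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `compound_id`, `smiles`, `core`, `mw`,
#'   `n_undefined_stereocenters`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_core <- length(.st_cores)
  n_sub <- nrow(.st_substituents)
  grid <- n_core * n_sub * n_sub
  if (config$n_compounds > grid)
    stop("invalid configuration: 'n_compounds' exceeds the template grid (",
         grid, " unique structures)", call. = FALSE)
  set.seed(.stage_seed(config$seed, "library"))
  idx <- sample.int(grid, config$n_compounds) - 1L
  core <- idx %% n_core + 1L
  a <- (idx %/% n_core) %% n_sub + 1L
  b <- idx %/% (n_core * n_sub) + 1L
  data.frame(
    compound_id = sprintf("CPD%06d", seq_len(config$n_compounds)),
    smiles = .assemble_smiles(core, a, b),
    core = names(.st_cores)[core],
    mw = unname(.assembled_mw(core, a, b)),
    n_undefined_stereocenters = .st_substituents$n_stereo[a] +
      .st_substituents$n_stereo[b],
    stringsAsFactors = FALSE)
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate the single-point primary screen
#'
#' Lays the library out on 384-well plates (samples column-major in columns
#' 3 to 22; 32 negative-control wells in columns 1-2 and 32 positive in
#' 23-24) and draws raw ratio-channel fluorescence per well:
#' `neg_mu + (pos_mu - neg_mu) * inhibition/100 + N(0, well_sigma)`.
#' True actives (probability `active_fraction`) get inhibition
#' `N(active_inhibition_mean, active_inhibition_sd)` truncated to
#' `[0, 120]`; inactives have zero true inhibition, so their realized
#' normalized values are pure well noise. Ground truth (`is_active`,
#' `true_inhibition`) is stored alongside.
#'
#' @param library data frame from [generate_library()].
#' @param config a [sim_config()].
#' @return data frame of well readings: `plate_id`, `well`, `role`
#'   (`sample`/`neg`/`pos`), `compound_id`, `raw_value`, `is_active`,
#'   `true_inhibition`.
#' @export
simulate_primary_screen <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(library) == 0L) stop("library is empty", call. = FALSE)
  rows <- config$plate_rows; cols <- config$plate_cols
  sample_cols <- 3:(cols - 2L)
  per_plate <- rows * length(sample_cols)
  need <- ceiling(nrow(library) / per_plate)
  n_plates <- if (is.null(config$n_plates)) need else config$n_plates
  if (nrow(library) > n_plates * per_plate)
    stop("library of ", nrow(library), " compounds exceeds capacity of ",
         n_plates, " plates (", n_plates * per_plate, " sample wells); ",
         need, " plates required", call. = FALSE)

  set.seed(.stage_seed(config$seed, "screen"))
  n <- nrow(library)
  is_active <- stats::runif(n) < config$active_fraction
  inh <- numeric(n)
  if (any(is_active))
    inh[is_active] <- .rnorm_trunc(sum(is_active), config$active_inhibition_mean,
                                   config$active_inhibition_sd, 0, 120)

  row_letters <- LETTERS[seq_len(rows)]
  plate_of <- (seq_len(n) - 1L) %/% per_plate + 1L
  slot <- (seq_len(n) - 1L) %% per_plate
  col_of <- sample_cols[slot %/% rows + 1L]
  row_of <- row_letters[slot %% rows + 1L]

  samples <- data.frame(
    plate_id = sprintf("P%03d", plate_of),
    well = sprintf("%s%02d", row_of, col_of),
    role = "sample",
    compound_id = library$compound_id,
    true_inhibition = inh,
    is_active = is_active,
    stringsAsFactors = FALSE)

  ctrl_cols <- c(1L, 2L, cols - 1L, cols)
  ctrl <- expand.grid(row = row_letters, col = ctrl_cols,
                      plate = seq_len(n_plates), stringsAsFactors = FALSE)
  controls <- data.frame(
    plate_id = sprintf("P%03d", ctrl$plate),
    well = sprintf("%s%02d", ctrl$row, ctrl$col),
    role = ifelse(ctrl$col <= 2L, "neg", "pos"),
    compound_id = "",
    true_inhibition = ifelse(ctrl$col <= 2L, 0, 100),
    is_active = NA,
    stringsAsFactors = FALSE)

  readings <- rbind(samples, controls)
  readings <- readings[order(readings$plate_id, readings$well), ]
  rownames(readings) <- NULL
  mu <- config$neg_mu + (config$pos_mu - config$neg_mu) * readings$true_inhibition / 100
  readings$raw_value <- mu + stats::rnorm(nrow(readings), 0, config$well_sigma)
  readings
}

#' Re-screen existing plates with fresh measurement noise
#'
#' Redraws every well's raw value around the same true means (same
#' compounds, layout and ground-truth inhibition) with a new noise stream:
#' the replicate experiment of a hit-confirmation run.
#'
#' @param readings output of [simulate_primary_screen()].
#' @param config the same [sim_config()].
#' @param noise_seed integer seed for the replicate's noise stream.
#' @return readings with `raw_value` redrawn.
#' @export
rescreen <- function(readings, config, noise_seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(noise_seed) %% 2147483647)
  mu <- config$neg_mu +
    (config$pos_mu - config$neg_mu) * readings$true_inhibition / 100
  readings$raw_value <- mu + stats::rnorm(nrow(readings), 0, config$well_sigma)
  readings
}

#' Draw true dose-response parameters for a set of compounds
#'
#' Assigns each compound a true four-parameter-logistic curve: potency
#' class drawn from `class_probs`, inflection `C` log-uniform within the
#' class's concentration band (micromolar 1-100 uM, high nanomolar
#' 0.1-1 uM, nanomolar 0.01-0.1 uM), asymptotes near 0/100 percent and a
#' Hill slope near 1.
#'
#' @param compound_ids character vector.
#' @param config a [sim_config()].
#' @return data frame `compound_id`, `A`, `B`, `C`, `D`, `true_pic50`.
#' @export
simulate_true_fits <- function(compound_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "truefits"))
  n <- length(compound_ids)
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  lo <- c(micromolar = 1, high_nanomolar = 0.1, nanomolar = 0.01)[cls]
  hi <- c(micromolar = 100, high_nanomolar = 1, nanomolar = 0.1)[cls]
  C <- 10^stats::runif(n, log10(lo), log10(hi))
  data.frame(
    compound_id = compound_ids,
    A = stats::rnorm(n, 100, 3),                 # response as x -> Inf
    B = .rnorm_trunc(n, 1, 0.15, 0.4, 2.5),      # Hill slope
    C = C,
    D = stats::rnorm(n, 0, 2),                   # response as x -> 0
    true_pic50 = 6 - log10(C),
    stringsAsFactors = FALSE)
}

#' Simulate dose-response measurements
#'
#' Evaluates each compound's true 4PL curve on the configured dose series
#' and adds Gaussian response noise, replicate by replicate.
#'
#' @param true_fits data frame with `compound_id`, `A`, `B`, `C`, `D`
#'   (e.g. from [simulate_true_fits()]).
#' @param config a [sim_config()]; uses `dose_series`, `n_replicates`,
#'   `dr_noise_sd`.
#' @return data frame `compound_id`, `conc_uM`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(true_fits, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$dose_series <= 0))
    stop("non-positive concentrations in dose series", call. = FALSE)
  set.seed(.stage_seed(config$seed, "dr"))
  grid <- expand.grid(k = seq_len(nrow(true_fits)),
                      conc_uM = config$dose_series,
                      replicate = seq_len(config$n_replicates))
  mu <- four_pl(grid$conc_uM, true_fits$A[grid$k], true_fits$B[grid$k],
                true_fits$C[grid$k], true_fits$D[grid$k])
  out <- data.frame(
    compound_id = true_fits$compound_id[grid$k],
    conc_uM = grid$conc_uM,
    replicate = grid$replicate,
    response = mu + stats::rnorm(nrow(grid), 0, config$dr_noise_sd),
    stringsAsFactors = FALSE)
  out[order(out$compound_id, -out$conc_uM, out$replicate), , drop = FALSE]
}

#' Simulate virtual-screening method scores
#'
#' For each configured method with enrichment `e`, a compound's score is
#' `e * (true inhibition / 120) + (1 - e) * Uniform(0, 1)`: enrichment 0
#' gives exchangeable (random) ranks, enrichment 1 ranks exactly by true
#' activity.
#'
#' @param library_truth data frame with `compound_id` and
#'   `true_inhibition` (e.g. sample rows of [simulate_primary_screen()]
#'   output).
#' @param config a [sim_config()].
#' @param methods method names to generate; defaults to all configured.
#'   Unknown names are a configuration error.
#' @return data frame `method`, `compound_id`, `score`.
#' @export
simulate_method_scores <- function(library_truth, config,
                                   methods = names(config$score_enrichment)) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(methods, names(config$score_enrichment))
  if (length(unknown))
    stop("invalid configuration: unknown method name(s) in 'score_enrichment': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(.stage_seed(config$seed, "scores"))
  n <- nrow(library_truth)
  act <- library_truth$true_inhibition / 120
  out <- lapply(methods, function(m) {
    e <- config$score_enrichment[[m]]
    data.frame(method = m,
               compound_id = library_truth$compound_id,
               score = e * act + (1 - e) * stats::runif(n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write all simulation outputs as CSV files
#'
#' Emits the pipeline's exchange schema: `library.csv`, `plates.csv`,
#' `scores.csv`, `dose_response.csv` and `ground_truth.csv`.
#'
#' @param dir output directory (created if needed).
#' @param library,readings,scores,dose_response data frames from the
#'   corresponding generators (those not supplied are skipped).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, library = NULL, readings = NULL,
                             scores = NULL, dose_response = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  if (!is.null(library)) w(library, "library.csv")
  if (!is.null(readings)) {
    w(readings[, c("plate_id", "well", "role", "compound_id", "raw_value")],
      "plates.csv")
    w(readings[readings$role == "sample",
               c("compound_id", "is_active", "true_inhibition")],
      "ground_truth.csv")
  }
  if (!is.null(scores)) w(scores, "scores.csv")
  if (!is.null(dose_response)) w(dose_response, "dose_response.csv")
  invisible(dir)
}
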