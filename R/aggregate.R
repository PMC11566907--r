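# Collapsing per-pose and per-stereoisomer scores to one score per library
# compound: stereoisomer enumeration with seeded subsampling, racemic
# (arithmetic-mean) averaging, Boltzmann-like (softmax-weighted) pose
# aggregation and the best-pose docking-energy rule.

#' Stereoisomer enumeration policy
#'
#' Compounds with at most `enumerate_all_up_to` undefined stereocenters get
#' all `2^n` stereoisomers; beyond that, exactly `max_enumerated` are
#' sampled without replacement, deterministically per compound and seed.
#'
#' @param max_enumerated cap on sampled isomers (default 16).
#' @param enumerate_all_up_to full-enumeration limit (default 4, so the
#'   full set never exceeds `2^4 = 16`).
#' @param seed integer seed for the subsampling stream.
#' @return object of class `stereo_policy`.
#' @export
stereo_policy <- function(max_enumerated = 16L, enumerate_all_up_to = 4L,
                          seed = 1L) {
  stopifnot(max_enumerated >= 1, enumerate_all_up_to >= 0)
  structure(list(max_enumerated = as.integer(max_enumerated),
                 enumerate_all_up_to = as.integer(enumerate_all_up_to),
                 seed = as.integer(seed)),
            class = "stereo_policy")
}

#' Enumerate stereoisomer identifiers for a compound
#'
#' @param compound_id identifier.
#' @param n_undefined_stereocenters count of undefined stereocenters.
#' @param policy a [stereo_policy()].
#' @return character vector of stereoisomer ids (`<id>_S<k>` where `k`
#'   indexes the `2^n` stereo configurations); length `2^n` for
#'   `n <= enumerate_all_up_to`, else exactly `max_enumerated`.
#' @export
enumerate_stereoisomers <- function(compound_id, n_undefined_stereocenters,
                                    policy = stereo_policy()) {
  n <- n_undefined_stereocenters
  stopifnot(length(n) == 1L, n >= 0)
  total <- 2^n
  if (n <= policy$enumerate_all_up_to) {
    idx <- seq_len(total)
  } else {
    # per-compound substream so enumeration is order-independent
    set.seed((policy$seed + .st_hash(compound_id)) %% 2147483647)
    idx <- sort(sample.int(total, policy$max_enumerated))
  }
  sprintf("%s_S%d", compound_id, idx)
}

#' Racemic average of per-stereoisomer scores
#'
#' Assay measurements on racemic material correspond to the average over
#' stereoisomers, so in-silico per-isomer scores are collapsed by the
#' arithmetic mean.
#'
#' @param scores numeric vector (non-empty).
#' @return mean score.
#' @export
racemic_average <- function(scores) {
  if (length(scores) == 0L) stop("no stereoisomer scores supplied", call. = FALSE)
  mean(scores)
}

#' Boltzmann-like aggregation of per-pose scores
#'
#' Softmax-weighted mean: `sum(s_i * w_i)` with `w_i` proportional to
#' `exp(s_i / temperature)` (higher score = stronger predicted binding).
#' The maximum is subtracted before exponentiation, so the result is
#' invariant to adding a constant to all scores and never overflows. The
#' aggregate always lies in `[min(s), max(s)]`; the temperature limits are
#' the arithmetic mean (`temperature -> Inf`) and the maximum
#' (`temperature -> 0+`).
#'
#' @param scores numeric vector of pose scores (non-empty).
#' @param temperature positive scalar on the score scale (default 1).
#' @return aggregate score.
#' @export
boltzmann_aggregate <- function(scores, temperature = 1) {
  if (length(scores) == 0L) stop("no pose scores supplied", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  z <- (scores - max(scores)) / temperature
  w <- exp(z)
  sum(scores * w) / sum(w)
}

#' Ensemble score from per-pose docking free energies
#'
#' Takes the most favorable (most negative) binding free energy over the
#' pose ensemble and negates it, so that higher = better predicted binding
#' across all methods.
#'
#' @param energies numeric vector of docking free energies, kcal/mol
#'   (non-empty; more negative = more favorable).
#' @return compound score (positive for favorable binding).
#' @export
docking_ensemble_score <- function(energies) {
  if (length(energies) == 0L) stop("no pose energies supplied", call. = FALSE)
  -min(energies)
}

#' Aggregate a per-pose score table to one score per compound
#'
#' Poses within a stereoisomer are collapsed by the pose rule
#' (`boltzmann_like` softmax mean or `best_pose` maximum); stereoisomers
#' are then collapsed by the racemic arithmetic mean. The output has
#' exactly one row per compound present in the input.
#'
#' @param poses data frame `compound_id`, `stereoisomer_id`, `pose_id`,
#'   `score` (higher = better; sign-flip docking energies first, e.g. via
#'   [docking_ensemble_score()] conventions).
#' @param pose_rule `"boltzmann_like"` or `"best_pose"`.
#' @param temperature softmax temperature for `boltzmann_like`.
#' @return data frame `compound_id`, `score`.
#' @export
aggregate_scores <- function(poses, pose_rule = c("boltzmann_like", "best_pose"),
                             temperature = 1) {
  pose_rule <- match.arg(pose_rule)
  per_iso <- function(s) switch(pose_rule,
                                boltzmann_like = boltzmann_aggregate(s, temperature),
                                best_pose = max(s))
  rows <- lapply(split(poses, poses$compound_id), function(df) {
    iso <- vapply(split(df$score, df$stereoisomer_id), per_iso, numeric(1))
    data.frame(compound_id = df$compound_id[1], score = racemic_average(iso),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
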