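# Plate-level processing of the primary screen: control statistics and
# Z-prime quality control, control-anchored normalization to relative
# inhibition (percent), and triplicate hit-confirmation metrics.

#' Per-plate control statistics and Z-prime
#'
#' Computes mean and sample SD (n-1 denominator) of the negative and
#' positive control wells of each plate and the Z-prime statistic
#' `Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`. `Z' = 1` exactly when
#' both control SDs are zero; plates pass QC when `Z' >= z_min`.
#'
#' @param readings well readings for one or more plates (`plate_id`,
#'   `role`, `raw_value`).
#' @param z_min minimum acceptable Z-prime (default 0.5).
#' @return data frame, one row per plate: `plate_id`, `mu_neg`, `mu_pos`,
#'   `sigma_neg`, `sigma_pos`, `n_neg`, `n_pos`, `zprime`, `passed_qc`.
#' @export
compute_plate_stats <- function(readings, z_min = 0.5) {
  one <- function(df) {
    neg <- df$raw_value[df$role == "neg"]
    pos <- df$raw_value[df$role == "pos"]
    if (length(neg) < 2L || length(pos) < 2L)
      stop("plate ", df$plate_id[1],
           ": need >= 2 wells of each control role (layout error)", call. = FALSE)
    mu_n <- mean(neg); mu_p <- mean(pos)
    if (mu_p == mu_n)
      stop("plate ", df$plate_id[1],
           ": degenerate plate, positive and negative control means equal",
           call. = FALSE)
    s_n <- stats::sd(neg); s_p <- stats::sd(pos)
    z <- 1 - 3 * (s_p + s_n) / abs(mu_p - mu_n)
    data.frame(plate_id = df$plate_id[1], mu_neg = mu_n, mu_pos = mu_p,
               sigma_neg = s_n, sigma_pos = s_p,
               n_neg = length(neg), n_pos = length(pos),
               zprime = z, passed_qc = z >= z_min,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(readings, readings$plate_id), one))
  rownames(out) <- NULL
  out
}

#' Normalize one plate's readings against its control statistics
#'
#' Adds `k_norm`, the relative inhibition in percent:
#' `100 * (k_raw - mu_neg) / (mu_pos - mu_neg)`. Negative-control signal
#' maps to 0%, positive-control (full inhibition) to 100%; values outside
#' `[0, 100]` are preserved, not clipped. Control wells are normalized too.
#'
#' @param readings well readings of a single plate.
#' @param stats the matching row of [compute_plate_stats()] output.
#' @return `readings` with a `k_norm` column appended.
#' @export
normalize_plate <- function(readings, stats) {
  if (nrow(stats) != 1L)
    stop("'stats' must be a single plate's statistics row", call. = FALSE)
  if (!all(readings$plate_id == stats$plate_id))
    stop("plate_id mismatch between readings and stats", call. = FALSE)
  if (stats$mu_pos == stats$mu_neg)
    stop("degenerate plate statistics: control means equal", call. = FALSE)
  readings$k_norm <- 100 * (readings$raw_value - stats$mu_neg) /
    (stats$mu_pos - stats$mu_neg)
  readings
}

#' Normalize a whole screen plate by plate
#'
#' Convenience wrapper: computes per-plate control statistics and applies
#' [normalize_plate()] to every plate.
#'
#' @inheritParams compute_plate_stats
#' @return list with `readings` (normalized) and `stats` (per-plate table).
#' @export
normalize_screen <- function(readings, z_min = 0.5) {
  stats <- compute_plate_stats(readings, z_min = z_min)
  parts <- lapply(split(readings, readings$plate_id), function(df)
    normalize_plate(df, stats[stats$plate_id == df$plate_id[1], , drop = FALSE]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  list(readings = out, stats = stats)
}

#' Partition plates by Z-prime quality control
#'
#' @param stats per-plate statistics from [compute_plate_stats()].
#' @param z_min minimum acceptable Z-prime.
#' @return list with `passed` (rows of `stats`) and `failed_ids` (plate
#'   identifiers to re-run). The partition is exhaustive and disjoint.
#' @export
qc_filter <- function(stats, z_min = 0.5) {
  ok <- stats$zprime >= z_min
  list(passed = stats[ok, , drop = FALSE], failed_ids = stats$plate_id[!ok])
}

#' Replicate hit-confirmation metrics
#'
#' Confirmed hits are primary hits present in every replicate hit set.
#' Precision is `confirmed / |primary|` (percent); recall is
#' `confirmed / |confirmed + hits new in the replicate consensus|`
#' (percent), where "new" hits appear in every replicate but not in the
#' primary set.
#'
#' @param primary_hits character vector of primary-screen hit ids.
#' @param replicate_hit_sets list of character vectors, one per replicate.
#' @return list with `confirmed` (ids), `precision`, `recall` (percent),
#'   `n_primary`, `n_new`.
#' @export
confirmation_metrics <- function(primary_hits, replicate_hit_sets) {
  if (length(primary_hits) == 0L)
    stop("empty primary hit set: precision undefined", call. = FALSE)
  if (length(replicate_hit_sets) == 0L)
    stop("no replicate hit sets supplied", call. = FALSE)
  consensus <- Reduce(intersect, replicate_hit_sets)
  confirmed <- intersect(primary_hits, consensus)
  new_hits <- setdiff(consensus, primary_hits)
  denom <- length(confirmed) + length(new_hits)
  list(confirmed = confirmed,
       precision = 100 * length(confirmed) / length(primary_hits),
       recall = if (denom == 0) NA_real_ else 100 * length(confirmed) / denom,
       n_primary = length(primary_hits),
       n_new = length(new_hits))
}

#' Per-plate correlation between replicate normalized values
#'
#' Pearson correlation of `k_norm` between every pair of replicates,
#' reported per plate.
#'
#' @param values data frame with `plate_id`, `compound_id`, `replicate`,
#'   `k_norm`.
#' @return data frame `plate_id`, `rep_a`, `rep_b`, `correlation`.
#' @export
replicate_correlation <- function(values) {
  out <- lapply(split(values, values$plate_id), function(df) {
    reps <- sort(unique(df$replicate))
    if (length(reps) < 2L) return(NULL)
    prs <- utils::combn(reps, 2)
    rows <- lapply(seq_len(ncol(prs)), function(j) {
      a <- df[df$replicate == prs[1, j], c("compound_id", "k_norm")]
      b <- df[df$replicate == prs[2, j], c("compound_id", "k_norm")]
      m <- merge(a, b, by = "compound_id")
      data.frame(plate_id = df$plate_id[1], rep_a = prs[1, j], rep_b = prs[2, j],
                 correlation = stats::cor(m$k_norm.x, m$k_norm.y),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
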