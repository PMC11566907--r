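#!/usr/bin/env Rscript
# Stage 2 -- plate quality control and normalization.
# Computes per-plate control statistics and Z', partitions plates at the
# Z' >= 0.5 acceptance bound, normalizes every well to relative inhibition
# (0% = DMSO, 100% = staurosporine), and runs a triplicate hit-confirmation
# experiment on the ten plates with the most primary hits.

suppressMessages(library(screentriage))

cfg <- sim_config(seed = 1)
scr <- simulate_primary_screen(generate_library(cfg), cfg)

ns <- normalize_screen(scr)
qc <- qc_filter(ns$stats, 0.5)
cat(sprintf("Z' mean %.3f (range %.3f-%.3f); %d of %d plates failed QC\n",
            mean(ns$stats$zprime), min(ns$stats$zprime), max(ns$stats$zprime),
            length(qc$failed_ids), nrow(ns$stats)))

samp <- ns$readings[ns$readings$role == "sample", ]
h50 <- call_hits(samp, 50)
cat(sprintf("primary hits at the 50%% threshold: %d (%.2f%% hit rate)\n",
            length(h50), 100 * length(h50) / nrow(samp)))

# triplicate confirmation on the top-10 hit plates: two replicate
# re-screens with fresh noise, consensus against the primary call
hit_plate <- sort(table(samp$plate_id[samp$compound_id %in% h50]),
                  decreasing = TRUE)
top10 <- names(hit_plate)[1:10]
sub <- scr[scr$plate_id %in% top10, ]
reps <- lapply(1:2, function(r) {
  rs <- normalize_screen(rescreen(sub, cfg, noise_seed = 7000 + r))
  call_hits(rs$readings[rs$readings$role == "sample", ], 50)
})
cm <- confirmation_metrics(intersect(h50, sub$compound_id), reps)
cat(sprintf("confirmation on %d primary hits: precision %.1f%%, recall %.1f%% (%d new)\n",
            cm$n_primary, cm$precision, cm$recall, cm$n_new))

dir.create("results", showWarnings = FALSE)
write.csv(ns$stats, "results/plate_qc.csv", row.names = FALSE)
write.csv(ns$readings, "results/normalized.csv", row.names = FALSE)
cat("wrote results/plate_qc.csv, results/normalized.csv\n")
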