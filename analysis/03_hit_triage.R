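#!/usr/bin/env Rscript
# Stage 3 -- cluster the hits and pick the diversified set.
# Fingerprints the primary hits, builds the Tanimoto graph, extracts
# Louvain communities, computes per-cluster MCS scaffolds, selects the
# top-5 ligand-efficiency representatives per cluster, and counts novelty
# against a synthetic "public actives" reference set. Also runs the
# edge-threshold calibration sweep (the cluster/singleton counts are a
# calibration experiment, not a validated quantity: they depend on an
# unreported similarity threshold and on the generator's scaffold
# diversity).

suppressMessages(library(screentriage))

cfg <- sim_config(seed = 1)
lib <- generate_library(cfg)
ns <- normalize_screen(simulate_primary_screen(lib, cfg))
samp <- ns$readings[ns$readings$role == "sample", ]
h50 <- call_hits(samp, 50)

hit_rec <- merge(samp[samp$compound_id %in% h50, c("compound_id", "k_norm")],
                 lib, by = "compound_id")
fps <- fingerprint_matrix(stats::setNames(hit_rec$smiles, hit_rec$compound_id))

# calibration sweep over the (unreported) graph edge threshold
for (thr in c(0.3, 0.4, 0.5, 0.6)) {
  cl_t <- louvain_cluster(build_similarity_graph(fps, thr), seed = 1)
  sizes <- table(cl_t$cluster_id)
  cat(sprintf("edge threshold %.1f: %3d clusters, %3d singletons\n",
              thr, length(sizes), sum(sizes == 1)))
}

cl <- louvain_cluster(build_similarity_graph(fps, 0.4), seed = 1)
div <- diversify(cl, hit_rec, 5)
cat(sprintf("working threshold 0.4: %d clusters -> %d diversified hits\n",
            length(unique(cl$cluster_id)), nrow(div)))

sc <- cluster_scaffolds(cl, lib, timeout = 0.5)
cat(sprintf("MCS scaffolds: %d non-empty, median %d heavy atoms\n",
            sum(nzchar(sc$scaffold_smiles)),
            stats::median(vapply(sc$scaffold_smiles[nzchar(sc$scaffold_smiles)],
                                 function(s) length(parse_smiles(s)$element),
                                 integer(1)))))

# novelty vs a synthetic reference of previously known actives
ref_lib <- generate_library(sim_config(n_compounds = 689, seed = 4242))
ref_fps <- fingerprint_matrix(stats::setNames(ref_lib$smiles, ref_lib$compound_id))
nv <- novelty_counts(fps, ref_fps, c(0.4, 0.6, 0.8, 0.9), clusters = cl)
print(nv, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
out <- merge(merge(div, cl), sc[, c("cluster_id", "scaffold_smiles")])
write.csv(out, "results/clusters.csv", row.names = FALSE)
write.csv(nv, "results/novelty.csv", row.names = FALSE)
cat("wrote results/clusters.csv, results/novelty.csv\n")
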