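#!/usr/bin/env Rscript
# Stage 1 -- simulate the screening campaign.
# Generates the 46,743-compound template library, lays it out on 147
# 384-well plates (32 DMSO + 32 staurosporine control wells each, samples
# in columns 3-22) and draws single-point raw fluorescence readings, plus
# the virtual-screening score tables. All downstream stages read the CSVs
# written here.

suppressMessages(library(screentriage))

cfg <- sim_config(seed = 1)
dir.create("results", showWarnings = FALSE)

lib <- generate_library(cfg)
cat(sprintf("library: %d unique compounds from %d chemotype cores, MW %.0f-%.0f g/mol\n",
            nrow(lib), length(unique(lib$core)), min(lib$mw), max(lib$mw)))
cat(sprintf("undefined stereocenters: %s\n",
            paste(names(table(lib$n_undefined_stereocenters)),
                  table(lib$n_undefined_stereocenters),
                  sep = ":", collapse = "  ")))

scr <- simulate_primary_screen(lib, cfg)
cat(sprintf("screen: %d wells on %d plates, %d true actives (%.2f%%)\n",
            nrow(scr), length(unique(scr$plate_id)),
            sum(scr$is_active, na.rm = TRUE),
            100 * mean(scr$is_active, na.rm = TRUE)))

scores <- simulate_method_scores(scr[scr$role == "sample", ], cfg)
cat(sprintf("scores: %d methods x %d compounds\n",
            length(unique(scores$method)), nrow(lib)))

write_simulation("results", library = lib, readings = scr, scores = scores)
cat("wrote results/{library,plates,scores,ground_truth}.csv\n")
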