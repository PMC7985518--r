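#!/usr/bin/env Rscript
# Step 1: generate the synthetic regulatory landscape used by the whole
# workflow: a two-chromosome genome, 300 genes on a 60 kb grid, root-TF
# (VDR) ChIP-seq peaks, gene-linked REMs, per-condition open chromatin
# with embedded motif instances, and early/late DEG tables with a planted
# driver-TF cascade. Everything is deterministic for the seed below.

suppressPackageStartupMessages(library(tfcascade))

seed <- 1
out <- "results/sim"
cfg <- sim_config(seed = seed)
bundle <- generate_synthetic_bundle(cfg, out)

tr <- bundle$truth
cat("synthetic landscape written to", out, "\n")
cat(sprintf("genes: %d (%d chromosomes x %.1f Mb)\n", cfg$n_genes,
            cfg$n_chromosomes, cfg$chrom_length / 1e6))
cat("ground-truth classes:\n")
print(table(tr$class))
cat("evidence channels among primary genes:\n")
print(table(tr$channel))
cat(sprintf("driver TF of the secondary response: %s\n", tr$driver_tf))
cat(sprintf("planted regulatory edges: %d (early TF -> TF gene)\n",
            nrow(tr$planted_edges)))
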