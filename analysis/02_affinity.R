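#!/usr/bin/env Rscript
# Step 2: TRAP affinity scanning. Converts the motif count matrices to
# position-specific energy matrices, calibrates a per-motif affinity
# threshold on dinucleotide-shuffled copies of the treated open-chromatin
# sequences, and aggregates region affinities into distance-decayed
# TF-gene score matrices for the control and treated conditions.

suppressPackageStartupMessages(library(tfcascade))

seed <- 1
sim <- "results/sim"
dir.create("results", showWarnings = FALSE)

genes <- read_gene_annotation(file.path(sim, "genes.gtf"))
genome <- Biostrings::readDNAStringSet(file.path(sim, "genome.fa"))
names(genome) <- sub(" .*$", "", names(genome))
motifs <- read_motifs(file.path(sim, "motifs.jaspar"))
open_ctl <- read_bed(file.path(sim, "open_control.bed"))
open_trt <- read_bed(file.path(sim, "open_treated.bed"))

ems <- lapply(motifs, pwm_to_energy_matrix)
seqs_trt <- vapply(seq_along(open_trt), function(i)
  extract_sequence(genome, open_trt[i]), character(1))
random_seqs <- shuffle_dinucleotides(seqs_trt, n = 1000, seed = seed + 101)
thresholds <- vapply(ems, function(em)
  calibrate_threshold(em, random_seqs, p_value = 0.05), numeric(1))
cat("calibrated per-motif affinity thresholds (p = 0.05):\n")
print(signif(thresholds, 3))

for (cond in c("control", "treated")) {
  regions <- if (cond == "control") open_ctl else open_trt
  A <- region_affinities(ems, regions, genome)
  sc <- compute_gene_tf_scores(regions, A, genes,
                               threshold_per_motif = thresholds,
                               condition = cond)
  write_tf_gene_scores(sc, sprintf("results/scores_%s.tsv", cond))
  cat(sprintf("%s: %d regions -> %d x %d gene-TF score matrix (%.1f%% nonzero)\n",
              cond, length(regions), nrow(sc), ncol(sc),
              100 * mean(sc > 0)))
}
write.table(data.frame(motif = names(thresholds),
                       threshold = unname(thresholds)),
            "results/thresholds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
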