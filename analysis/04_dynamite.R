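#!/usr/bin/env Rscript
# Step 4: driver-TF ranking. Builds the log2 score contrast
# (treated vs control) for the late secondary DEGs, fits the sparse
# elastic-net logistic regression that discriminates up- from
# down-regulated genes, and ranks TFs by their normalized coefficients.

suppressPackageStartupMessages(library(tfcascade))

seed <- 1
cl <- read.table("results/classification.tsv", sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
scores_ctl <- read_tf_gene_scores("results/scores_control.tsv")
scores_trt <- read_tf_gene_scores("results/scores_treated.tsv")

sub <- cl[cl$timing == "late" & !cl$is_primary & cl$log2fc_late != 0, ]
cat(sprintf("regression set: %d late secondary DEGs (%d up, %d down)\n",
            nrow(sub), sum(sub$log2fc_late > 0), sum(sub$log2fc_late < 0)))

fm <- build_feature_matrix(scores_ctl, scores_trt,
                           data.frame(gene_id = sub$gene_id,
                                      log2fc = sub$log2fc_late))
fit <- suppressWarnings(fit_sparse_classifier(fm$features, fm$labels,
                                              seed = seed + 202))
rk <- normalize_and_rank(fit)
write.table(rk, "results/tf_importance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("mean held-out fold accuracy: %.2f\n",
            mean(attr(fit, "fold_accuracy"), na.rm = TRUE)))
cat("TF importance ranking (normalized |coefficient|):\n")
print(rk, row.names = FALSE)
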