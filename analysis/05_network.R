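#!/usr/bin/env Rscript
# Step 5: the root-centred directed TF network. The root TF points to
# every primary-target TF gene; an early-responding TF gains a
# predicted_binding edge to another TF when its decayed affinity score at
# that TF's gene locus exceeds the calibrated threshold.

suppressPackageStartupMessages(library(tfcascade))

sim <- "results/sim"
genes <- read_gene_annotation(file.path(sim, "genes.gtf"))
cl <- read.table("results/classification.tsv", sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
scores_trt <- read_tf_gene_scores("results/scores_treated.tsv")
thr <- read.table("results/thresholds.tsv", sep = "\t", header = TRUE)
motifs <- read_motifs(file.path(sim, "motifs.jaspar"))
tf_of_motif <- vapply(motifs, `[[`, "", "tf_name")

sym_of <- setNames(genes$symbol, genes$gene_id)
prim <- cl[cl$is_primary, ]
is_tf <- sym_of[prim$gene_id] %in% setdiff(unique(tf_of_motif), "VDR")
primary_tfs <- data.frame(tf_name = unname(sym_of[prim$gene_id[is_tf]]),
                          timing = prim$timing[is_tf],
                          stringsAsFactors = FALSE)
cat(sprintf("primary target genes coding for TFs: %d (%s)\n",
            nrow(primary_tfs), paste(primary_tfs$tf_name, collapse = ", ")))

scm <- scores_trt[prim$gene_id[is_tf], , drop = FALSE]
rownames(scm) <- primary_tfs$tf_name
thr_tf <- tapply(setNames(thr$threshold, thr$motif), tf_of_motif[thr$motif],
                 min)
net <- build_tf_network(primary_tfs, scm, edge_threshold = thr_tf,
                        root = "VDR")
export_network(net, "results/network_edges.tsv", format = "edgelist")
export_network(net, "results/network.graphml", format = "graphml")

ed <- igraph::as_data_frame(net)
cat(sprintf("network: %d nodes, %d edges (%d root, %d predicted binding)\n",
            igraph::vcount(net), igraph::ecount(net),
            sum(ed$evidence == "root_primary"),
            sum(ed$evidence == "predicted_binding")))
print(ed[ed$evidence == "predicted_binding", ], row.names = FALSE)
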