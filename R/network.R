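# Root-centred directed TF regulatory network. The root TF (e.g. VDR) gets
# a typed edge to every primary-target TF; an early-responding primary TF
# gains a predicted_binding edge to any other primary TF whose gene-level
# decayed affinity score for the early TF's motif exceeds a threshold.

#' Build the directed TF regulatory network
#'
#' @param primary_tfs data.frame with columns `tf_name` (gene symbol, must
#'   match a row of `score_matrix` for binding edges) and `timing`
#'   (`"early"` or `"late"`).
#' @param score_matrix `tf_gene_scores` matrix whose rows are named by gene
#'   symbol (or a matrix whose rownames cover the primary TFs) and whose
#'   columns are TF motifs; used to score early-TF binding at TF gene loci.
#' @param edge_threshold named numeric vector of per-TF score thresholds
#'   (names = early TF names), or a single number applied to all; an edge
#'   requires score strictly greater than the threshold.
#' @param root name of the root TF (default `"VDR"`).
#' @return an `igraph` directed graph; vertices carry `timing` and
#'   `is_root`, edges carry `evidence` (`root_primary` /
#'   `predicted_binding`) and `affinity_score` (NA for root edges).
#' @export
build_tf_network <- function(primary_tfs, score_matrix = NULL,
                             edge_threshold = 0, root = "VDR") {
  stopifnot(all(c("tf_name", "timing") %in% names(primary_tfs)))
  if (any(primary_tfs$tf_name == root)) {
    primary_tfs <- primary_tfs[primary_tfs$tf_name != root, , drop = FALSE]
  }
  nodes <- data.frame(
    name = c(root, primary_tfs$tf_name),
    timing = c("early", primary_tfs$timing),
    is_root = c(TRUE, rep(FALSE, nrow(primary_tfs))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = root, to = primary_tfs$tf_name,
                      evidence = "root_primary",
                      affinity_score = NA_real_,
                      stringsAsFactors = FALSE)
  early_tfs <- primary_tfs$tf_name[primary_tfs$timing == "early"]
  if (!is.null(score_matrix) && length(early_tfs) > 0L) {
    thr_of <- function(tf) {
      if (length(edge_threshold) == 1L && is.null(names(edge_threshold))) {
        return(as.numeric(edge_threshold))
      }
      if (!tf %in% names(edge_threshold)) return(NA_real_)
      as.numeric(edge_threshold[[tf]])
    }
    for (e in early_tfs) {
      if (!(e %in% colnames(score_matrix))) {
        warning("early TF without a motif column in score matrix: ", e)
        next
      }
      thr <- thr_of(e)
      if (is.na(thr)) {
        warning("no edge threshold for early TF ", e, "; no binding edges")
        next
      }
      for (t in primary_tfs$tf_name) {
        if (t == e || !(t %in% rownames(score_matrix))) next
        sc <- score_matrix[t, e]
        if (sc > thr) {
          edges <- rbind(edges, data.frame(
            from = e, to = t, evidence = "predicted_binding",
            affinity_score = sc, stringsAsFactors = FALSE))
        }
      }
    }
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Export a TF network
#'
#' Formats: `"edgelist"` (tab-separated edge table `source, target,
#' evidence, affinity_score` plus a companion node table
#' `<path>.nodes.tsv` with `tf_name, timing, is_root`; lossless round
#' trip), `"graphml"`, `"dot"`.
#'
#' @param network `igraph` graph from [build_tf_network()].
#' @param path output file path.
#' @param format one of `"edgelist"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edgelist", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    ed <- igraph::as_data_frame(network, what = "edges")
    names(ed)[1:2] <- c("source", "target")
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nd <- igraph::as_data_frame(network, what = "vertices")
    names(nd)[1] <- "tf_name"
    utils::write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(network, path, format = format)
  }
  invisible(path)
}

#' Read a TF network exported as an edge list
#'
#' @param path path given to [export_network()] with `format = "edgelist"`.
#' @return an `igraph` graph equivalent to the exported one.
#' @export
read_network_edgelist <- function(path) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  nd <- utils::read.table(paste0(path, ".nodes.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  names(ed)[1:2] <- c("from", "to")
  names(nd)[1] <- "name"
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
}
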