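# End-to-end orchestration: affinity -> evidence flags -> classification ->
# upset summary -> driver-TF regression (secondary subset) -> TF network.
# Every stage is a pure function of (inputs, config, seed); rerunning with
# the same config produces byte-identical output tables.

#' Default pipeline configuration
#'
#' @param ... named overrides.
#' @return config list with defaults filled in.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    genome_fasta = NULL, genes_gtf = NULL, peaks_bed = NULL,
    open_control_bed = NULL, open_treated_bed = NULL, rem_tsv = NULL,
    motifs = NULL, deg_tables = NULL,  # named list/vector: timepoint -> path
    early_timepoints = c("2.5h", "4h"),
    late_timepoints = "24h",
    half_width = 25000,
    decay_constant = 5000,
    lambda_param = 0.7,
    r0_slope = 0.584,
    r0_intercept = -5.66,
    pseudocount = 1,
    threshold_p_value = 0.05,
    n_random_sequences = 1000,
    motif_aggregate = "max",
    k_methods = 1,
    padj_cutoff = 0.05,
    root_tf = "VDR",
    alpha = 0.1,
    epsilon = 1e-3,
    contrast = "ratio",
    n_outer_folds = 6,
    n_inner_folds = 6,
    restrict_to_secondary = TRUE,
    seed = 1,
    out_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config keys: ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_pipeline_config(cfg)
  cfg
}

.validate_pipeline_config <- function(cfg) {
  if (cfg$half_width <= 0) stop("half_width must be > 0")
  if (cfg$decay_constant <= 0) stop("decay_constant must be > 0")
  if (cfg$lambda_param <= 0) stop("lambda_param must be > 0")
  if (cfg$threshold_p_value <= 0 || cfg$threshold_p_value >= 1) {
    stop("threshold_p_value must be in (0, 1)")
  }
  if (!cfg$k_methods %in% 1:3) stop("k_methods must be 1, 2 or 3")
  if (cfg$epsilon <= 0) stop("epsilon must be > 0")
  if (cfg$padj_cutoff <= 0 || cfg$padj_cutoff > 1) {
    stop("padj_cutoff must be in (0, 1]")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_pipeline_config()]. The resolved configuration round-trips
#' through save/load unchanged.
#'
#' @param path YAML (or JSON) file.
#' @return validated config list.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$deg_tables)) raw$deg_tables <- unlist(raw$deg_tables)
  do.call(default_pipeline_config, raw)
}

#' Save a resolved pipeline configuration
#'
#' @param config config list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; TRAP energies and region affinities for both
#' open-chromatin conditions; per-motif threshold calibration on
#' dinucleotide-shuffled copies of the treated open-chromatin sequences;
#' decayed TF-gene scores per condition; three evidence-channel flags;
#' early/late primary/secondary classification and upset summary; sparse
#' logistic regression ranking driver TFs on the secondary subset; and the
#' root-centred TF network. Intermediate tables are written to
#' `config$out_dir` when set.
#'
#' @param config list from [default_pipeline_config()] / [load_config()].
#' @return list with elements `thresholds`, `scores_control`,
#'   `scores_treated`, `flags`, `classification`, `upset`, `importance`
#'   (NULL if no two-class secondary set), `network`, `counts` (per-stage
#'   log counts) and `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  inputs <- stage("read_inputs", {
    genes <- read_gene_annotation(cfg$genes_gtf)
    genome <- Biostrings::readDNAStringSet(cfg$genome_fasta)
    names(genome) <- sub(" .*$", "", names(genome))
    peaks <- read_bed(cfg$peaks_bed)
    rems <- if (!is.null(cfg$rem_tsv)) read_rem_table(cfg$rem_tsv, genes)
            else GenomicRanges::GRanges()
    open_ctl <- read_bed(cfg$open_control_bed)
    open_trt <- read_bed(cfg$open_treated_bed)
    motifs <- read_motifs(cfg$motifs)
    degs <- do.call(rbind, lapply(names(cfg$deg_tables), function(tp)
      read_deg_table(cfg$deg_tables[[tp]], tp)))
    list(genes = genes, genome = genome, peaks = peaks, rems = rems,
         open_ctl = open_ctl, open_trt = open_trt, motifs = motifs,
         degs = degs)
  })
  counts$n_genes <- length(inputs$genes)
  counts$n_peaks <- length(inputs$peaks)
  message("read ", counts$n_genes, " genes, ", counts$n_peaks, " peaks, ",
          length(inputs$open_trt), " treated open regions")

  aff <- stage("affinity", {
    ems <- lapply(inputs$motifs, function(p)
      pwm_to_energy_matrix(p, lambda_param = cfg$lambda_param,
                           r0_slope = cfg$r0_slope,
                           r0_intercept = cfg$r0_intercept,
                           pseudocount = cfg$pseudocount))
    seqs_trt <- vapply(seq_along(inputs$open_trt), function(i)
      extract_sequence(inputs$genome, inputs$open_trt[i]), character(1))
    random_seqs <- shuffle_dinucleotides(seqs_trt,
                                         n = cfg$n_random_sequences,
                                         seed = cfg$seed + 101)
    thresholds <- vapply(ems, function(em)
      calibrate_threshold(em, random_seqs, cfg$threshold_p_value),
      numeric(1))
    A_ctl <- region_affinities(ems, inputs$open_ctl, inputs$genome)
    A_trt <- region_affinities(ems, inputs$open_trt, inputs$genome)
    sc_ctl <- compute_gene_tf_scores(
      inputs$open_ctl, A_ctl, inputs$genes, half_width = cfg$half_width,
      decay_constant = cfg$decay_constant, threshold_per_motif = thresholds,
      aggregate = cfg$motif_aggregate, condition = "control")
    sc_trt <- compute_gene_tf_scores(
      inputs$open_trt, A_trt, inputs$genes, half_width = cfg$half_width,
      decay_constant = cfg$decay_constant, threshold_per_motif = thresholds,
      aggregate = cfg$motif_aggregate, condition = "treated")
    list(thresholds = thresholds, scores_control = sc_ctl,
         scores_treated = sc_trt,
         tf_of_motif = vapply(inputs$motifs, `[[`, "", "tf_name"))
  })
  message("calibrated thresholds for ", length(aff$thresholds), " motifs")

  flags <- stage("flags", {
    method_flags(
      window_peak = flag_window_targets(inputs$peaks, inputs$genes,
                                        cfg$half_width),
      rem_overlap = flag_rem_targets(inputs$peaks, inputs$rems,
                                     inputs$genes),
      motif_open_chromatin = flag_motif_targets(aff$scores_treated,
                                                cfg$root_tf))
  })
  counts$n_flagged_any <- sum(flags$n_methods > 0)

  classification <- stage("classify", {
    classify_degs(inputs$degs, flags,
                  early_timepoints = cfg$early_timepoints,
                  late_timepoints = cfg$late_timepoints,
                  k_methods = cfg$k_methods, padj_cutoff = cfg$padj_cutoff)
  })
  upset <- summarize_upset(classification)
  counts$n_degs <- nrow(classification)
  counts$n_primary <- sum(classification$is_primary)
  for (tm in c("early", "late")) {
    tot <- upset$totals[upset$totals$timing == tm, ]
    message(tm, " DEGs: ", tot$n_degs, "; predicted primary: ",
            tot$n_primary, " (", tot$pct_primary, "%)")
  }

  importance <- stage("dynamite", {
    sub <- classification[classification$timing == "late" &
                          !is.na(classification$log2fc_late) &
                          classification$log2fc_late != 0, , drop = FALSE]
    if (cfg$restrict_to_secondary) {
      sub <- sub[!sub$is_primary, , drop = FALSE]
    }
    counts$n_regression_genes <- nrow(sub)
    if (nrow(sub) < 10L || length(unique(sub$log2fc_late > 0)) < 2L) {
      warning("too few (or single-class) secondary DEGs; regression skipped")
      NULL
    } else {
      fm <- build_feature_matrix(aff$scores_control, aff$scores_treated,
                                 data.frame(gene_id = sub$gene_id,
                                            log2fc = sub$log2fc_late),
                                 epsilon = cfg$epsilon,
                                 contrast = cfg$contrast)
      raw <- fit_sparse_classifier(fm$features, fm$labels,
                                   alpha = cfg$alpha,
                                   n_outer_folds = cfg$n_outer_folds,
                                   n_inner_folds = cfg$n_inner_folds,
                                   seed = cfg$seed + 202)
      normalize_and_rank(raw)
    }
  })

  network <- stage("network", {
    sym_of <- stats::setNames(inputs$genes$symbol, inputs$genes$gene_id)
    prim <- classification[classification$is_primary, , drop = FALSE]
    prim_sym <- sym_of[prim$gene_id]
    tf_names <- unique(aff$tf_of_motif)
    is_tf_gene <- prim_sym %in% setdiff(tf_names, cfg$root_tf)
    if (!any(is_tf_gene)) {
      NULL
    } else {
      primary_tfs <- data.frame(tf_name = unname(prim_sym[is_tf_gene]),
                                timing = prim$timing[is_tf_gene],
                                stringsAsFactors = FALSE)
      primary_tfs <- primary_tfs[!duplicated(primary_tfs$tf_name), ]
      sc <- aff$scores_treated
      tf_rows <- prim$gene_id[is_tf_gene]
      scm <- sc[tf_rows, , drop = FALSE]
      rownames(scm) <- unname(prim_sym[is_tf_gene])
      scm <- scm[!duplicated(rownames(scm)), , drop = FALSE]
      # per-TF edge threshold: the calibrated per-motif affinity threshold
      # (minimum over a TF's motif variants)
      thr_tf <- tapply(aff$thresholds, aff$tf_of_motif, min)
      build_tf_network(primary_tfs, scm,
                       edge_threshold = thr_tf[names(thr_tf)],
                       root = cfg$root_tf)
    }
  })
  counts$n_network_edges <- if (is.null(network)) 0L
                            else igraph::ecount(network)
  message("network: ",
          if (is.null(network)) "no primary TF genes"
          else paste0(igraph::vcount(network), " nodes, ",
                      igraph::ecount(network), " edges"))

  result <- list(thresholds = aff$thresholds,
                 scores_control = aff$scores_control,
                 scores_treated = aff$scores_treated,
                 flags = flags, classification = classification,
                 upset = upset, importance = importance, network = network,
                 counts = counts, config = cfg)
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result, cfg$out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$flags, "method_flags.tsv")
  wt(result$classification, "classification.tsv")
  wt(result$upset$combos, "upset_combinations.tsv")
  wt(result$upset$totals, "upset_totals.tsv")
  wt(result$upset$confirmed, "upset_confirmed.tsv")
  wt(data.frame(motif = names(result$thresholds),
                threshold = unname(result$thresholds)), "thresholds.tsv")
  write_tf_gene_scores(result$scores_control,
                       file.path(out_dir, "scores_control.tsv"))
  write_tf_gene_scores(result$scores_treated,
                       file.path(out_dir, "scores_treated.tsv"))
  if (!is.null(result$importance)) wt(result$importance, "tf_importance.tsv")
  if (!is.null(result$network)) {
    export_network(result$network, file.path(out_dir, "network_edges.tsv"),
                   format = "edgelist")
  }
  save_config(result$config, file.path(out_dir, "resolved_config.yaml"))
  jsonlite::write_json(result$counts,
                       file.path(out_dir, "stage_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
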