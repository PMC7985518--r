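# Deterministic generator of a miniature regulatory landscape with known
# ground truth. It emulates the structure of the real study inputs: a root
# TF's ChIP-seq peaks near TSSs, gene-linked regulatory elements (REMs)
# overlapped by peaks, consensus motif instances embedded in open
# chromatin, per-condition open-chromatin BED files, and early/late
# differential-expression tables with a planted TF cascade (secondary genes
# driven by an early-responding TF).
#
# Layout guarantees (all deterministic given the seed):
#   * genes sit on a 60 kb grid, so adjacent 50 kb TSS windows never
#     overlap and planted evidence cannot leak between genes;
#   * REM-channel evidence (REM + overlapping peak) is placed in the
#     inter-window dead zone ~27-33 kb downstream of the TSS, outside every
#     window, so it fires only the REM channel of its linked gene;
#   * every open-chromatin region that is NOT supposed to carry evidence
#     for a motif is rejection-sampled until its TRAP affinity stays below
#     half the generator-calibrated threshold for every planted motif
#     (enforcing the ground-truth invariant that non-evidenced windows are
#     clean), and every planted consensus region is verified to exceed the
#     threshold.

#' Default simulation configuration
#'
#' @param ... named overrides of the defaults.
#' @return validated config list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_chromosomes = 2,
    chrom_length = 9.2e6,
    n_genes = 300,
    n_tfs = 6,
    fraction_responsive = 0.8,
    fraction_primary = 0.5,   # of DEGs
    fraction_early = 0.4,     # of primary DEGs
    motif_length = 10,
    peak_noise_rate = 0,
    label_noise_rate = 0,
    gc = 0.41,
    half_width = 25000,
    decay_constant = 5000,
    threshold_p_value = 0.05,
    region_width = 300,
    peak_width = 400,
    rem_width = 500,
    n_calibration = 300,      # generator-internal threshold calibration
    max_rejection_tries = 60,
    root_tf = "VDR",
    channel_probs = c(window = 0.25, rem = 0.10, motif = 0.15,
                      window_rem = 0.10, window_motif = 0.20,
                      rem_motif = 0.05, all = 0.15),
    planted_edge_prob = 0.6,
    timepoints_early = c("2.5h", "4h"),
    timepoint_late = "24h"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown sim config keys: ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c(cfg$fraction_responsive, cfg$fraction_primary, cfg$fraction_early,
          cfg$peak_noise_rate, cfg$label_noise_rate, cfg$gc)
  if (any(fr < 0 | fr > 1)) stop("fractions/rates must lie in [0,1]")
  if (cfg$chrom_length < cfg$n_genes * 60000 / cfg$n_chromosomes) {
    stop("chrom_length too small: genes (with their windows) must fit; ",
         "need >= n_genes * 60000 / n_chromosomes")
  }
  if (cfg$n_tfs < 2) stop("need the root TF plus at least one more TF")
  if (cfg$motif_length >= cfg$region_width) {
    stop("motif_length must be smaller than region_width")
  }
  cfg
}

.sim_tf_names <- function(cfg) {
  n_other <- cfg$n_tfs - 1L
  n_early <- min(2L, n_other)
  early <- c("CEBPA", "ETS1")[seq_len(n_early)]
  n_late <- n_other - n_early
  late_pool <- c("PPARG", "IRF5", "NFIA", "KLF4", "CUX1", "NFE2", "BCL6")
  late <- if (n_late <= length(late_pool)) late_pool[seq_len(n_late)] else
    c(late_pool, sprintf("LTF%02d", seq_len(n_late - length(late_pool))))
  list(root = cfg$root_tf, early = early, late = late,
       all = c(cfg$root_tf, early, late))
}

.random_seq <- function(width, gc) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the motif collection for a simulation
#'
#' One informative count matrix per TF: a random consensus of
#' `motif_length` bases with 85/5/5/5 column counts.
#'
#' @param config from [sim_config()].
#' @return named list of `pwm` objects (one per TF, motif id `<TF>.sim`).
#' @export
sim_motifs <- function(config) {
  tfs <- .sim_tf_names(config)$all
  set.seed(config$seed + 11)
  out <- list()
  for (tf in tfs) {
    cons <- sample(1:4, config$motif_length, replace = TRUE)
    counts <- matrix(5, nrow = 4, ncol = config$motif_length)
    counts[cbind(cons, seq_len(config$motif_length))] <- 85
    id <- paste0(tf, ".sim")
    out[[id]] <- new_pwm(tf, id, counts, source = "sim")
  }
  out
}

#' Generate the genome scaffold and gene annotation
#'
#' I.i.d. background sequence at the configured GC content; genes placed
#' non-overlapping on a 60 kb grid with both strands represented.
#' Deterministic given the config seed.
#'
#' @param config from [sim_config()].
#' @return list with `chrom_bases` (per-chromosome character vectors of
#'   bases, modifiable before FASTA export) and `genes` (a `GRanges` as
#'   produced by [read_gene_annotation()]).
#' @export
generate_genome_and_genes <- function(config) {
  cfg <- config
  set.seed(cfg$seed + 1)
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chromosomes))
  chrom_bases <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE,
           prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2,
                    (1 - cfg$gc) / 2)))
  names(chrom_bases) <- chroms
  slots_per_chrom <- floor((cfg$chrom_length - 90000) / 60000) + 1L
  if (slots_per_chrom * cfg$n_chromosomes < cfg$n_genes) {
    stop("genes cannot fit on the 60 kb grid with the given chrom_length")
  }
  idx <- seq_len(cfg$n_genes) - 1L
  chrom_of <- chroms[(idx %% cfg$n_chromosomes) + 1L]
  slot_of <- idx %/% cfg$n_chromosomes
  tss0 <- 50000 + slot_of * 60000      # 0-based TSS position
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  len <- sample(2000:20000, cfg$n_genes, replace = TRUE)
  start0 <- ifelse(strand == "+", tss0, tss0 - len + 1)
  end0 <- ifelse(strand == "+", tss0 + len, tss0 + 1)
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  genes <- GenomicRanges::GRanges(
    seqnames = chrom_of,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand)
  genes$gene_id <- gene_id
  genes$symbol <- gene_id
  genes$tss <- tss0 + 1
  names(genes) <- gene_id
  list(chrom_bases = chrom_bases, genes = genes)
}

# Draw a region sequence: optionally embed a consensus at the centre;
# redraw the random part until the region is below `ceiling_of` for every
# listed motif and (if required) above `floor_req` for the embedded motif.
.draw_region <- function(cfg, ems, ceiling_of, embed_consensus = NULL,
                         required_motif = NULL, floor_req = NULL) {
  w <- cfg$region_width
  for (try in seq_len(cfg$max_rejection_tries)) {
    s <- .random_seq(w, cfg$gc)
    if (!is.null(embed_consensus)) {
      at <- (w - nchar(embed_consensus)) %/% 2
      substr(s, at + 1, at + nchar(embed_consensus)) <- embed_consensus
    }
    ok <- TRUE
    for (mo in names(ceiling_of)) {
      if (!is.null(required_motif) && mo == required_motif) next
      if (trap_affinity(ems[[mo]], s) >= ceiling_of[[mo]]) { ok <- FALSE; break }
    }
    if (ok && !is.null(required_motif)) {
      ok <- trap_affinity(ems[[required_motif]], s) >= floor_req
    }
    if (ok) return(s)
  }
  warning("rejection sampling did not converge for one region; using last draw")
  s
}

#' Plant the regulatory landscape
#'
#' Assigns each gene a ground-truth class, plants evidence for primary
#' genes per the channel distribution, driver-TF motif instances for
#' secondary genes, and early-TF motif instances at planted network-edge
#' target loci; writes the planted sequences into the genome scaffold.
#'
#' @param config from [sim_config()].
#' @param scaffold list from [generate_genome_and_genes()].
#' @param motifs list from [sim_motifs()].
#' @return list with `chrom_bases` (updated), `peaks`, `open_control`,
#'   `open_treated` (`GRanges`), `rems` (`GRanges` with `rem_id`,
#'   `gene_id`), `genes` (symbols updated for TF genes) and `truth`
#'   (ground-truth list).
#' @export
plant_regulatory_landscape <- function(config, scaffold, motifs) {
  cfg <- config
  tfn <- .sim_tf_names(cfg)
  genes <- scaffold$genes
  chrom_bases <- scaffold$chrom_bases
  n <- length(genes)
  ems <- lapply(motifs, pwm_to_energy_matrix)
  consensus <- vapply(motifs, pwm_consensus, character(1))
  tf_of_motif <- vapply(motifs, `[[`, "", "tf_name")
  motif_of_tf <- stats::setNames(names(motifs), tf_of_motif)

  set.seed(cfg$seed + 2)
  # generator-internal thresholds from random background sequences
  bg <- vapply(seq_len(cfg$n_calibration), function(i)
    .random_seq(cfg$region_width, cfg$gc), character(1))
  thr_gen <- vapply(names(ems), function(mo)
    calibrate_threshold(ems[[mo]], bg, cfg$threshold_p_value), numeric(1))
  ceiling_of <- thr_gen / 2

  # ---- class assignment -------------------------------------------------
  n_deg <- round(cfg$fraction_responsive * n)
  n_primary <- round(cfg$fraction_primary * n_deg)
  n_early <- round(cfg$fraction_early * n_primary)
  n_secondary <- n_deg - n_primary
  ord <- sample.int(n)
  class <- rep("unresponsive", n)
  class[ord[seq_len(n_early)]] <- "early-primary"
  if (n_primary > n_early) {
    class[ord[(n_early + 1):n_primary]] <- "late-primary"
  }
  if (n_secondary > 0) {
    class[ord[(n_primary + 1):n_deg]] <- "late-secondary"
  }

  # evidence channels for primary genes
  cells <- list(window = c(TRUE, FALSE, FALSE), rem = c(FALSE, TRUE, FALSE),
                motif = c(FALSE, FALSE, TRUE), window_rem = c(TRUE, TRUE, FALSE),
                window_motif = c(TRUE, FALSE, TRUE),
                rem_motif = c(FALSE, TRUE, TRUE), all = c(TRUE, TRUE, TRUE))
  is_primary <- class %in% c("early-primary", "late-primary")
  channel <- rep(NA_character_, n)
  channel[is_primary] <- sample(names(cells), sum(is_primary), replace = TRUE,
                                prob = cfg$channel_probs[names(cells)])

  # TF gene assignment: early TFs on early-primary genes, late TFs on
  # late-primary genes
  early_idx <- which(class == "early-primary")
  late_idx <- which(class == "late-primary")
  if (length(early_idx) < length(tfn$early) ||
      length(late_idx) < length(tfn$late)) {
    stop("not enough primary genes to host the TF genes; increase n_genes")
  }
  tf_gene_idx <- c(early_idx[seq_along(tfn$early)],
                   late_idx[seq_along(tfn$late)])
  tf_gene_names <- c(tfn$early, tfn$late)
  genes$symbol[tf_gene_idx] <- tf_gene_names

  # planted directed edges early TF -> other TF gene
  other_of <- function(e) setdiff(tf_gene_names, e)
  planted_edges <- do.call(rbind, lapply(tfn$early, function(e) {
    cand <- other_of(e)
    keep <- stats::runif(length(cand)) < cfg$planted_edge_prob
    if (!any(keep)) keep[sample.int(length(cand), 1L)] <- TRUE
    data.frame(from = e, to = cand[keep], stringsAsFactors = FALSE)
  }))

  # driver TF for secondary genes (single planted driver: first early TF)
  driver_tf <- tfn$early[1L]
  direction <- rep(NA_character_, n)
  sec_idx <- which(class == "late-secondary")
  direction[sec_idx] <- sample(c("up", "down"), length(sec_idx),
                               replace = TRUE)

  # ---- evidence planting ------------------------------------------------
  peaks <- list(); open_ctl <- list(); open_trt <- list(); rems <- list()
  add_iv <- function(lst, chrom, s0, w, name) {
    lst[[length(lst) + 1L]] <- data.frame(chrom = chrom, start = s0,
                                          end = s0 + w, name = name,
                                          stringsAsFactors = FALSE)
    lst
  }
  write_seq <- function(chrom, s0, s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    chrom_bases[[chrom]][(s0 + 1):(s0 + length(v))] <<- v
    invisible(NULL)
  }
  chrom_of <- as.character(GenomicRanges::seqnames(genes))
  tss0 <- genes$tss - 1L
  root_motif <- motif_of_tf[[cfg$root_tf]]
  # fixed centre slots near the TSS for consensus-bearing regions; slot 1
  # is the root-motif region, further slots host planted-edge regions
  core_slots <- c(1500, -2400, 3300, -4200)
  rw <- cfg$region_width

  edge_targets <- split(planted_edges$from, planted_edges$to)

  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    t0 <- tss0[i]
    # background open region (both conditions), clean for every motif
    off <- sample(c(-1, 1), 1) * sample(8000:20000, 1)
    s0 <- t0 + off - rw %/% 2
    write_seq(ch, s0, .draw_region(cfg, ems, ceiling_of))
    open_ctl <- add_iv(open_ctl, ch, s0, rw, sprintf("bg_%s", genes$gene_id[i]))
    open_trt <- add_iv(open_trt, ch, s0, rw, sprintf("bg_%s", genes$gene_id[i]))

    if (is_primary[i]) {
      chan <- cells[[channel[i]]]
      if (chan[1]) {  # window channel: peak inside the TSS window
        p0 <- t0 + sample(c(-1, 1), 1) * sample(5000:20000, 1) -
          cfg$peak_width %/% 2
        peaks <- add_iv(peaks, ch, p0, cfg$peak_width,
                        sprintf("pk_w_%s", genes$gene_id[i]))
      } else {
        sample(c(-1, 1), 1); sample(5000:20000, 1)  # keep RNG stream aligned
      }
      if (chan[2]) {  # REM channel: REM + overlapping peak in the dead zone
        r0 <- t0 + 27000
        rems[[length(rems) + 1L]] <- data.frame(
          chrom = ch, start = r0, end = r0 + cfg$rem_width,
          rem_id = sprintf("REM_%s", genes$gene_id[i]),
          gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
        peaks <- add_iv(peaks, ch, r0 - 100, cfg$peak_width,
                        sprintf("pk_r_%s", genes$gene_id[i]))
      }
      if (chan[3]) {  # motif channel: root consensus in treated open chromatin
        s0 <- t0 + core_slots[1] - rw %/% 2
        write_seq(ch, s0, .draw_region(cfg, ems, ceiling_of,
                                       embed_consensus = consensus[[root_motif]],
                                       required_motif = root_motif,
                                       floor_req = 4 * thr_gen[[root_motif]]))
        open_trt <- add_iv(open_trt, ch, s0, rw,
                           sprintf("mo_%s", genes$gene_id[i]))
      }
      # planted-edge regions at TF gene loci (treated condition)
      sym <- genes$symbol[i]
      if (sym %in% names(edge_targets)) {
        froms <- edge_targets[[sym]]
        for (k in seq_along(froms)) {
          mo <- motif_of_tf[[froms[k]]]
          s0 <- t0 + core_slots[1 + k] - rw %/% 2
          write_seq(ch, s0, .draw_region(cfg, ems, ceiling_of,
                                         embed_consensus = consensus[[mo]],
                                         required_motif = mo,
                                         floor_req = 4 * thr_gen[[mo]]))
          open_trt <- add_iv(open_trt, ch, s0, rw,
                             sprintf("edge_%s_%s", froms[k], sym))
        }
      }
    } else if (class[i] == "late-secondary") {
      # driver motif instance: treated-only if up, control-only if down
      mo <- motif_of_tf[[driver_tf]]
      s0 <- t0 + core_slots[1] - rw %/% 2
      write_seq(ch, s0, .draw_region(cfg, ems, ceiling_of,
                                     embed_consensus = consensus[[mo]],
                                     required_motif = mo,
                                     floor_req = 4 * thr_gen[[mo]]))
      if (direction[i] == "up") {
        open_trt <- add_iv(open_trt, ch, s0, rw,
                           sprintf("drv_%s", genes$gene_id[i]))
      } else {
        open_ctl <- add_iv(open_ctl, ch, s0, rw,
                           sprintf("drv_%s", genes$gene_id[i]))
      }
    }
  }

  # decoy peaks
  n_planted_peaks <- length(peaks)
  n_decoy <- round(cfg$peak_noise_rate * n_planted_peaks)
  if (n_decoy > 0) {
    for (k in seq_len(n_decoy)) {
      ch <- sample(names(chrom_bases), 1)
      p0 <- sample.int(cfg$chrom_length - cfg$peak_width, 1)
      peaks <- add_iv(peaks, ch, p0, cfg$peak_width, sprintf("pk_decoy_%d", k))
    }
  }

  to_gr <- function(lst, with_name = TRUE) {
    if (length(lst) == 0L) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    genomic_intervals(df$chrom, df$start, df$end,
                      name = if (with_name) df$name else NULL)
  }
  rem_gr <- if (length(rems) > 0L) {
    df <- do.call(rbind, rems)
    g <- genomic_intervals(df$chrom, df$start, df$end)
    g$rem_id <- df$rem_id; g$gene_id <- df$gene_id
    g
  } else GenomicRanges::GRanges()

  truth <- list(
    gene_id = genes$gene_id,
    symbol = genes$symbol,
    class = class,
    channel = channel,
    direction = direction,
    driver_tf = driver_tf,
    tf_genes = data.frame(tf_name = tf_gene_names,
                          gene_id = genes$gene_id[tf_gene_idx],
                          timing = c(rep("early", length(tfn$early)),
                                     rep("late", length(tfn$late))),
                          stringsAsFactors = FALSE),
    planted_edges = planted_edges,
    thresholds_generator = thr_gen)

  list(chrom_bases = chrom_bases, genes = genes, peaks = to_gr(peaks),
       open_control = to_gr(open_ctl), open_treated = to_gr(open_trt),
       rems = rem_gr, truth = truth)
}

#' Simulate per-time-point differential-expression tables
#'
#' Early-primary genes are significant at the early and late time points;
#' late-primary and secondary genes only at the late time point; secondary
#' genes' fold-change sign follows their driver TF's planted direction
#' (flipped with probability `label_noise_rate`); unresponsive genes are
#' never significant. No gene is significant early but not late.
#'
#' @param config from [sim_config()].
#' @param truth ground-truth list from [plant_regulatory_landscape()].
#' @return named list of data.frames (gene_id, log2fc, padj), one per time
#'   point label.
#' @export
simulate_deg_tables <- function(config, truth) {
  cfg <- config
  set.seed(cfg$seed + 3)
  n <- length(truth$gene_id)
  cls <- truth$class
  mag <- stats::runif(n, 1, 3)
  sign <- sample(c(1, -1), n, replace = TRUE)
  sec <- cls == "late-secondary"
  sign[sec] <- ifelse(truth$direction[sec] == "up", 1, -1)
  flip <- stats::runif(n) < cfg$label_noise_rate
  sign[sec & flip] <- -sign[sec & flip]
  sig_p <- function(k) stats::runif(k, 1e-8, 0.01)
  ns_p <- function(k) stats::runif(k, 0.2, 0.95)
  tps <- c(cfg$timepoints_early, cfg$timepoint_late)
  out <- list()
  for (tp in tps) {
    is_late_tp <- tp == cfg$timepoint_late
    signif <- (cls == "early-primary") |
      (is_late_tp & cls %in% c("late-primary", "late-secondary"))
    padj <- numeric(n)
    padj[signif] <- sig_p(sum(signif))
    padj[!signif] <- ns_p(sum(!signif))
    l2fc <- ifelse(signif, sign * mag, stats::rnorm(n, 0, 0.1))
    out[[tp]] <- data.frame(gene_id = truth$gene_id, log2fc = l2fc,
                            padj = padj, stringsAsFactors = FALSE)
  }
  out
}

.write_gtf <- function(genes, path) {
  strand <- as.character(GenomicRanges::strand(genes))
  attrs <- sprintf('gene_id "%s"; gene_name "%s";',
                   genes$gene_id, genes$symbol)
  lines <- paste(as.character(GenomicRanges::seqnames(genes)), "sim", "gene",
                 GenomicRanges::start(genes), GenomicRanges::end(genes),
                 ".", strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Runs the genome/gene generator, the evidence planting and the DEG
#' simulation, and writes every pipeline input format (FASTA, GTF, BED,
#' REM TSV, per-time-point DEG TSVs, JASPAR motifs) plus a ground-truth
#' JSON. Byte-identical for a fixed config.
#'
#' @param config from [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisible list with `paths` (named file paths), `genes`,
#'   `genome` (`DNAStringSet`), `truth` and `config`.
#' @export
generate_synthetic_bundle <- function(config = sim_config(), out_dir) {
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  motifs <- sim_motifs(cfg)
  scaffold <- generate_genome_and_genes(cfg)
  planted <- plant_regulatory_landscape(cfg, scaffold, motifs)
  degs <- simulate_deg_tables(cfg, planted$truth)

  genome <- Biostrings::DNAStringSet(
    vapply(planted$chrom_bases, paste, character(1), collapse = ""))
  names(genome) <- names(planted$chrom_bases)

  p <- list(
    genome_fasta = file.path(out_dir, "genome.fa"),
    genes_gtf = file.path(out_dir, "genes.gtf"),
    peaks_bed = file.path(out_dir, "root_peaks.bed"),
    open_control_bed = file.path(out_dir, "open_control.bed"),
    open_treated_bed = file.path(out_dir, "open_treated.bed"),
    rem_tsv = file.path(out_dir, "rems.tsv"),
    motifs = file.path(out_dir, "motifs.jaspar"),
    truth_json = file.path(out_dir, "ground_truth.json"))
  Biostrings::writeXStringSet(genome, p$genome_fasta)
  .write_gtf(planted$genes, p$genes_gtf)
  write_bed(planted$peaks, p$peaks_bed)
  write_bed(planted$open_control, p$open_control_bed)
  write_bed(planted$open_treated, p$open_treated_bed)
  rem_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(planted$rems)),
    start = GenomicRanges::start(planted$rems) - 1L,
    end = GenomicRanges::end(planted$rems),
    rem_id = planted$rems$rem_id, gene_id = planted$rems$gene_id,
    stringsAsFactors = FALSE)
  utils::write.table(rem_df, p$rem_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_motifs_jaspar(motifs, p$motifs)
  deg_paths <- character(0)
  for (tp in names(degs)) {
    fp <- file.path(out_dir, sprintf("deg_%s.tsv", gsub("[^0-9A-Za-z.]", "_", tp)))
    utils::write.table(degs[[tp]], fp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    deg_paths[tp] <- fp
  }
  p$deg_tables <- deg_paths
  jsonlite::write_json(planted$truth, p$truth_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = p, genes = planted$genes, genome = genome,
                 peaks = planted$peaks, open_control = planted$open_control,
                 open_treated = planted$open_treated, rems = planted$rems,
                 degs = degs, truth = planted$truth, motifs = motifs,
                 config = cfg))
}
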