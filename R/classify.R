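# Hierarchical primary/secondary target classification. Three independent
# evidence channels link a root transcription factor to genes:
#   i.  window_peak        - a root-TF ChIP-seq peak overlapping the 50 kb
#                            TSS-centred window;
#   ii. rem_overlap        - a root-TF peak overlapping a regulatory element
#                            (REM) linked to the gene;
#   iii.motif_open_chromatin - an above-threshold root-TF motif affinity in
#                            open chromatin inside the window.
# A differentially expressed gene is a primary target when at least
# k_methods channels fire; response timing is early (significant at any
# early time point) or late (significant only at the late time point).

#' Flag genes with a peak in their TSS window
#'
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param genes `GRanges` from [read_gene_annotation()].
#' @param half_width window half width in bp (default 25000).
#' @return named logical vector over `genes$gene_id`.
#' @export
flag_window_targets <- function(peaks, genes, half_width = 25000) {
  win <- tss_window(genes, half_width)
  hit <- GenomicRanges::countOverlaps(win, peaks, minoverlap = 1L,
                                      ignore.strand = TRUE) > 0
  stats::setNames(hit, genes$gene_id)
}

#' Flag genes linked to a peak-overlapping REM
#'
#' A gene is flagged iff at least one REM linked to it overlaps (>= 1 bp)
#' at least one peak.
#'
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param rems `GRanges` from [read_rem_table()] (metadata column `gene_id`).
#' @param genes `GRanges` of genes (defines the flag universe).
#' @return named logical vector over `genes$gene_id`.
#' @export
flag_rem_targets <- function(peaks, rems, genes) {
  unresolved <- !(rems$gene_id %in% genes$gene_id)
  if (any(unresolved)) {
    warning(sum(unresolved), " REM link(s) to unresolvable gene ids excluded")
    rems <- rems[!unresolved]
  }
  ov <- GenomicRanges::countOverlaps(rems, peaks, minoverlap = 1L,
                                     ignore.strand = TRUE) > 0
  hit_genes <- unique(rems$gene_id[ov])
  stats::setNames(genes$gene_id %in% hit_genes, genes$gene_id)
}

#' Flag genes with an above-threshold motif score for one TF
#'
#' Operates on a score matrix built with per-motif thresholding enabled, so
#' a positive score means at least one qualifying (above-threshold) region
#' in the gene's window.
#'
#' @param score_matrix a `tf_gene_scores` matrix.
#' @param tf_name TF column to use.
#' @return named logical vector over the matrix's genes.
#' @export
flag_motif_targets <- function(score_matrix, tf_name) {
  if (!(tf_name %in% colnames(score_matrix))) {
    stop("TF not in score matrix: ", tf_name)
  }
  stats::setNames(score_matrix[, tf_name] > 0, rownames(score_matrix))
}

#' Combine channel flags into one table
#'
#' @param window_peak,rem_overlap,motif_open_chromatin named logical
#'   vectors over the same gene universe (missing genes count as FALSE).
#' @return data.frame with columns `gene_id`, the three channel flags and
#'   `n_methods`.
#' @export
method_flags <- function(window_peak, rem_overlap, motif_open_chromatin) {
  ids <- sort(unique(c(names(window_peak), names(rem_overlap),
                       names(motif_open_chromatin))))
  at <- function(v) {
    out <- stats::setNames(rep(FALSE, length(ids)), ids)
    out[names(v)[v]] <- TRUE
    out
  }
  df <- data.frame(gene_id = ids,
                   window_peak = at(window_peak),
                   rem_overlap = at(rem_overlap),
                   motif_open_chromatin = at(motif_open_chromatin),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$n_methods <- rowSums(df[, c("window_peak", "rem_overlap",
                                 "motif_open_chromatin")])
  df
}

#' Classify differentially expressed genes as early/late primary/secondary
#'
#' A gene is significant at a time point when `padj < padj_cutoff`. Timing
#' is `early` if significant at any early time point (regardless of late
#' significance), else `late` if significant at a late time point. Genes
#' never significant are excluded. A gene is a primary target when at least
#' `k_methods` evidence channels fire.
#'
#' @param deg_tables data.frame with columns `gene_id`, `timepoint`,
#'   `log2fc`, `padj` (rows from all time points; see [read_deg_table()]).
#' @param flags data.frame from [method_flags()].
#' @param early_timepoints,late_timepoints character vectors of time point
#'   labels (defaults `c("2.5h", "4h")` and `"24h"`).
#' @param k_methods stringency: channels required for a primary call
#'   (1, 2 or 3; default 1).
#' @param padj_cutoff significance cutoff (default 0.05, strict `<`).
#' @return data.frame with columns `gene_id`, `timing`, `n_methods`,
#'   `is_primary`, the three channel flags, and `log2fc_late` (fold change
#'   at the first late time point, NA if absent).
#' @export
classify_degs <- function(deg_tables, flags,
                          early_timepoints = c("2.5h", "4h"),
                          late_timepoints = "24h",
                          k_methods = 1, padj_cutoff = 0.05) {
  if (!k_methods %in% 1:3) stop("k_methods must be 1, 2 or 3")
  sig <- deg_tables[!is.na(deg_tables$padj) &
                    deg_tables$padj < padj_cutoff, , drop = FALSE]
  ids <- unique(sig$gene_id)
  if (length(ids) == 0L) {
    return(data.frame(gene_id = character(), timing = character(),
                      n_methods = integer(), is_primary = logical(),
                      window_peak = logical(), rem_overlap = logical(),
                      motif_open_chromatin = logical(),
                      log2fc_late = numeric(), stringsAsFactors = FALSE))
  }
  early <- unique(sig$gene_id[sig$timepoint %in% early_timepoints])
  late_only <- setdiff(unique(sig$gene_id[sig$timepoint %in% late_timepoints]),
                       early)
  ids <- c(early, late_only)
  timing <- c(rep("early", length(early)), rep("late", length(late_only)))
  i <- match(ids, flags$gene_id)
  nm <- ifelse(is.na(i), 0L, flags$n_methods[i])
  pick_flag <- function(col) ifelse(is.na(i), FALSE, flags[[col]][i])
  late_rows <- deg_tables[deg_tables$timepoint %in% late_timepoints, ]
  l2fc <- late_rows$log2fc[match(ids, late_rows$gene_id)]
  out <- data.frame(gene_id = ids, timing = timing,
                    n_methods = as.integer(nm),
                    is_primary = nm >= k_methods,
                    window_peak = pick_flag("window_peak"),
                    rem_overlap = pick_flag("rem_overlap"),
                    motif_open_chromatin = pick_flag("motif_open_chromatin"),
                    log2fc_late = l2fc,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}

#' Percentage of a count, one decimal
#'
#' `100 * count / total`, rounded to one decimal (round-half-even). The
#' package never stores percentages independently of the counts they are
#' derived from.
#'
#' @param count,total nonnegative counts (`total > 0`).
#' @return numeric percentage with one decimal.
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, 1)
}

#' Upset-style summary of evidence-channel combinations
#'
#' Exclusive counts of predicted primary genes per non-empty combination of
#' the three channels, split by response timing, with derived percentages
#' (per timing class, of the predicted primary total).
#'
#' @param classifications data.frame from [classify_degs()].
#' @return list with `combos` (data.frame: timing, combination label,
#'   count, pct), `totals` (per timing: n DEGs, n primary, pct primary),
#'   and `confirmed` (per timing: counts and pct predicted by >= 2 and by
#'   all 3 channels).
#' @export
summarize_upset <- function(classifications) {
  cl <- classifications
  combo_label <- function(w, r, m) {
    paste(c("window", "rem", "motif")[c(w, r, m)], collapse = "+")
  }
  combos <- expand.grid(w = c(TRUE, FALSE), r = c(TRUE, FALSE),
                        m = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  out <- list()
  totals <- list()
  confirmed <- list()
  for (tm in c("early", "late")) {
    sub <- cl[cl$timing == tm, , drop = FALSE]
    prim <- sub[sub$is_primary, , drop = FALSE]
    n_prim <- nrow(prim)
    cnt <- apply(combos, 1, function(co) {
      sum(prim$window_peak == co[["w"]] & prim$rem_overlap == co[["r"]] &
          prim$motif_open_chromatin == co[["m"]])
    })
    out[[tm]] <- data.frame(
      timing = tm,
      combination = apply(combos, 1, function(co)
        combo_label(co[["w"]], co[["r"]], co[["m"]])),
      count = as.integer(cnt),
      pct = if (n_prim > 0) percent_of(cnt, n_prim) else NA_real_,
      stringsAsFactors = FALSE, row.names = NULL)
    totals[[tm]] <- data.frame(
      timing = tm, n_degs = nrow(sub), n_primary = n_prim,
      pct_primary = if (nrow(sub) > 0) percent_of(n_prim, nrow(sub))
                    else NA_real_,
      stringsAsFactors = FALSE)
    n_ge2 <- sum(prim$n_methods >= 2)
    n_all3 <- sum(prim$n_methods == 3)
    confirmed[[tm]] <- data.frame(
      timing = tm, n_ge2 = n_ge2, n_all3 = n_all3,
      pct_ge2 = if (n_prim > 0) percent_of(n_ge2, n_prim) else NA_real_,
      pct_all3 = if (n_prim > 0) percent_of(n_all3, n_prim) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(combos = do.call(rbind, out),
       totals = do.call(rbind, totals),
       confirmed = do.call(rbind, confirmed))
}

#' Partition two or three gene sets
#'
#' For two sets: sizes of a-only, b-only and the intersection. For three:
#' the full 7-cell partition.
#'
#' @param set_a,set_b,set_c character vectors of gene ids (`set_c` optional).
#' @return named integer vector of partition sizes.
#' @export
compare_deg_sets <- function(set_a, set_b, set_c = NULL) {
  a <- unique(set_a); b <- unique(set_b)
  if (is.null(set_c)) {
    c(a_only = length(setdiff(a, b)),
      b_only = length(setdiff(b, a)),
      both = length(intersect(a, b)))
  } else {
    cc <- unique(set_c)
    u <- unique(c(a, b, cc))
    ina <- u %in% a; inb <- u %in% b; inc <- u %in% cc
    key <- paste0(ifelse(ina, "a", ""), ifelse(inb, "b", ""),
                  ifelse(inc, "c", ""))
    cells <- c("a", "b", "c", "ab", "ac", "bc", "abc")
    stats::setNames(vapply(cells, function(k) sum(key == k), integer(1)),
                    c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc"))
  }
}
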