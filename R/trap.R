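# TRAP biophysical motif-affinity model. A PWM is converted to a
# position-specific mismatch-energy matrix
#     E(b, i) = (1/lambda) * ln(p_max,i / p_b,i)
# so the per-column consensus base has energy zero. A sequence window of
# motif length with total energy E contributes the equilibrium occupancy
#     p = R0 * exp(-E) / (1 + R0 * exp(-E)),   ln R0 = slope * m + intercept,
# and the affinity of a sequence is the sum of occupancies over all windows
# on both strands: the expected number of bound sites.

.SEQ_CODE <- stats::setNames(c(1L, 2L, 3L, 4L), c("A", "C", "G", "T"))

encode_sequence <- function(sequence) {
  v <- .SEQ_CODE[strsplit(toupper(sequence), "", fixed = TRUE)[[1]]]
  unname(v)  # non-ACGT (e.g. N) -> NA
}

revcomp <- function(sequence) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(sequence, "",
    fixed = TRUE)[[1]]), collapse = ""))
}

#' Convert a PWM to a TRAP energy matrix
#'
#' Counts are pseudocount-regularized, normalized to probabilities and
#' floored, then transformed to mismatch energies relative to the per-column
#' maximum. The TRAP equilibrium constant is length-dependent:
#' `ln R0 = r0_slope * m + r0_intercept`.
#'
#' @param pwm a `pwm` object (count or probability columns).
#' @param lambda_param energy scale (> 0); default 0.7, the published TRAP
#'   value.
#' @param r0_slope,r0_intercept linear model for `ln R0` in the motif
#'   length; defaults 0.584 and -5.66, the published TRAP values.
#' @param pseudocount added to every count before normalization.
#' @param prob_floor lower bound applied to probabilities (guards the log).
#' @return an `energy_matrix` object with fields `tf_name`, `motif_id`,
#'   `energies` (4 x m, consensus base zero per column), `lambda_param`,
#'   `ln_r0`.
#' @export
pwm_to_energy_matrix <- function(pwm, lambda_param = 0.7,
                                 r0_slope = 0.584, r0_intercept = -5.66,
                                 pseudocount = 1, prob_floor = 0.001) {
  if (lambda_param <= 0) stop("lambda_param must be > 0")
  cnt <- pwm$counts + pseudocount
  p <- sweep(cnt, 2, colSums(cnt), "/")
  p <- pmax(p, prob_floor)
  p <- sweep(p, 2, colSums(p), "/")
  pmaxcol <- apply(p, 2, max)
  E <- log(sweep(1 / p, 2, pmaxcol, "*")) / lambda_param
  E <- pmax(E, 0)  # clip tiny negative rounding noise
  m <- ncol(E)
  structure(list(tf_name = pwm$tf_name, motif_id = pwm$motif_id,
                 energies = E, lambda_param = lambda_param,
                 ln_r0 = r0_slope * m + r0_intercept),
            class = "energy_matrix")
}

# Summed mismatch energies of all windows of a coded sequence (one strand).
# Windows containing NA (ambiguous base) return NA.
.window_energies <- function(code, E) {
  m <- ncol(E)
  nw <- length(code) - m + 1L
  if (nw < 1L) return(numeric(0))
  tot <- numeric(nw)
  has_na <- logical(nw)
  for (j in seq_len(m)) {
    cj <- code[j:(j + nw - 1L)]
    naj <- is.na(cj)
    has_na <- has_na | naj
    cj[naj] <- 1L
    tot <- tot + E[cj + 4L * (j - 1L)]
  }
  tot[has_na] <- NA_real_
  tot
}

#' TRAP affinity of a sequence
#'
#' Expected number of bound sites: the sum of equilibrium occupancies over
#' every motif-length window on both strands. Windows containing ambiguous
#' bases (N) contribute zero. A sequence shorter than the motif yields 0
#' with a warning.
#'
#' @param energy_matrix an `energy_matrix`.
#' @param sequence DNA string (A,C,G,T,N; case-insensitive).
#' @return nonnegative scalar affinity.
#' @export
trap_affinity <- function(energy_matrix, sequence) {
  m <- ncol(energy_matrix$energies)
  if (nchar(sequence) < m) {
    warning("sequence shorter than motif; affinity defined as 0")
    return(0)
  }
  code <- encode_sequence(sequence)
  code_rc <- 5L - rev(code)
  R0 <- exp(energy_matrix$ln_r0)
  occ <- function(E_win) {
    x <- R0 * exp(-E_win)
    sum(x / (1 + x), na.rm = TRUE)
  }
  occ(.window_energies(code, energy_matrix$energies)) +
    occ(.window_energies(code_rc, energy_matrix$energies))
}

#' Calibrate an affinity threshold from random sequences
#'
#' Scans a set of user-supplied random (background) sequences and returns
#' the empirical upper quantile of their TRAP affinities so that at most a
#' fraction `p_value` of random sequences meet or exceed the threshold.
#' With `n` sequences the threshold is the order statistic of rank
#' `floor((1 - p_value) * n) + 1` (so `p_value = 1/n` yields the maximum
#' observed affinity, and the threshold is monotone non-increasing in
#' `p_value`). Deterministic given the sequence set.
#'
#' @param energy_matrix an `energy_matrix`.
#' @param random_sequences character vector of background sequences.
#' @param p_value exceedance probability in (0, 1); default 0.05.
#' @return scalar affinity threshold.
#' @export
calibrate_threshold <- function(energy_matrix, random_sequences,
                                p_value = 0.05) {
  n <- length(random_sequences)
  if (n == 0L) stop("random_sequences must be non-empty")
  if (p_value <= 0 || p_value >= 1) stop("p_value must be in (0, 1)")
  aff <- vapply(random_sequences, function(s)
    trap_affinity(energy_matrix, s), numeric(1), USE.NAMES = FALSE)
  srt <- sort(aff)
  k <- min(n, floor((1 - p_value) * n + 1e-9) + 1L)
  srt[k]
}

#' Dinucleotide-preserving shuffle of sequences
#'
#' Produces `n` shuffled background copies by permuting the non-overlapping
#' doublets of input sequences (cycled as needed), preserving doublet
#' composition at even phase. Deterministic given `seed`.
#'
#' @param sequences character vector of template sequences.
#' @param n number of shuffled sequences to produce.
#' @param seed RNG seed.
#' @return character vector of length `n`.
#' @export
shuffle_dinucleotides <- function(sequences, n = 1000, seed = 1) {
  if (length(sequences) == 0L) stop("no template sequences")
  out <- character(n)
  rng <- local({ set.seed(seed); function(k) sample.int(k) })
  for (i in seq_len(n)) {
    s <- sequences[[(i - 1L) %% length(sequences) + 1L]]
    L <- nchar(s)
    L2 <- L - (L %% 2L)
    doublets <- substring(s, seq(1L, L2 - 1L, by = 2L), seq(2L, L2, by = 2L))
    tail_base <- if (L %% 2L == 1L) substr(s, L, L) else ""
    out[i] <- paste0(paste(doublets[rng(length(doublets))], collapse = ""),
                     tail_base)
  }
  out
}

#' TRAP affinities of regions against a motif collection
#'
#' @param energy_matrices named list of `energy_matrix` objects.
#' @param regions `GRanges` of (open-chromatin) regions.
#' @param genome named `DNAStringSet` or FASTA path.
#' @return numeric matrix, regions x motifs; attribute `tf_name` gives the
#'   TF of each motif column.
#' @export
region_affinities <- function(energy_matrices, regions, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  seqs <- vapply(seq_along(regions), function(i)
    extract_sequence(genome, regions[i]), character(1))
  A <- vapply(energy_matrices, function(em)
    vapply(seqs, function(s) trap_affinity(em, s), numeric(1),
           USE.NAMES = FALSE),
    numeric(length(regions)))
  A <- matrix(A, nrow = length(regions),
              dimnames = list(NULL, names(energy_matrices)))
  attr(A, "tf_name") <- vapply(energy_matrices, `[[`, "", "tf_name")
  A
}

#' Decayed TF-gene scores from region affinities
#'
#' For each gene, sums the affinities of qualifying regions (>= 1 bp overlap
#' with the TSS window), each weighted by `exp(-d / decay_constant)` where
#' `d` is the distance from the region centre to the TSS. Region affinities
#' below the per-motif threshold are zeroed before decay weighting (they do
#' not contribute). Motif variants of the same TF are aggregated per gene.
#'
#' @param regions `GRanges` of regions (same set/order as `affinities` rows).
#' @param affinities regions x motifs matrix from [region_affinities()].
#' @param genes `GRanges` from [read_gene_annotation()].
#' @param half_width TSS window half width in bp (default 25000).
#' @param decay_constant exponential decay scale in bp (default 5000); must
#'   be > 0.
#' @param threshold_per_motif optional named numeric vector of per-motif
#'   affinity thresholds (names matching `colnames(affinities)`); an
#'   affinity qualifies when it meets (`>=`) its threshold.
#' @param aggregate how to combine motif variants of one TF: `"max"`
#'   (default), `"sum"` or `"mean"`.
#' @param condition label stored on the result.
#' @return genes x TFs numeric matrix of class `tf_gene_scores` with
#'   attributes `condition`, `half_width`, `decay_constant`.
#' @export
compute_gene_tf_scores <- function(regions, affinities, genes,
                                   half_width = 25000, decay_constant = 5000,
                                   threshold_per_motif = NULL,
                                   aggregate = c("max", "sum", "mean"),
                                   condition = "condition") {
  if (decay_constant <= 0) stop("decay_constant must be > 0")
  aggregate <- match.arg(aggregate)
  A <- affinities
  tf_of <- attr(affinities, "tf_name")
  if (is.null(tf_of)) tf_of <- colnames(A)
  if (!is.null(threshold_per_motif)) {
    for (mo in colnames(A)) {
      thr <- threshold_per_motif[[mo]]
      if (!is.null(thr) && !is.na(thr)) A[A[, mo] < thr, mo] <- 0
    }
  }
  win <- tss_window(genes, half_width)
  hits <- GenomicRanges::findOverlaps(win, regions, minoverlap = 1L,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  # distances: 0-based region centre to 0-based TSS
  centre0 <- floor((GenomicRanges::start(regions)[s] - 1 +
                    GenomicRanges::end(regions)[s]) / 2)
  d <- abs(centre0 - (genes$tss[q] - 1))
  w <- exp(-d / decay_constant)
  per_motif <- matrix(0, nrow = length(genes), ncol = ncol(A),
                      dimnames = list(genes$gene_id, colnames(A)))
  if (length(q) > 0L) {
    contrib <- A[s, , drop = FALSE] * w
    agg <- rowsum(contrib, group = q)
    per_motif[as.integer(rownames(agg)), ] <- agg
  }
  tfs <- unique(tf_of)
  scores <- vapply(tfs, function(tf) {
    cols <- per_motif[, tf_of == tf, drop = FALSE]
    switch(aggregate,
           max = apply(cols, 1, max),
           sum = rowSums(cols),
           mean = rowMeans(cols))
  }, numeric(length(genes)))
  scores <- matrix(scores, nrow = length(genes),
                   dimnames = list(genes$gene_id, tfs))
  structure(scores, condition = condition, half_width = half_width,
            decay_constant = decay_constant, class = "tf_gene_scores")
}

#' Write a TF-gene score matrix
#'
#' Tab-separated genes x TFs table preceded by `#`-prefixed metadata lines
#' (condition and the window/decay parameters).
#'
#' @param scores a `tf_gene_scores` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tf_gene_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condition=%s", attr(scores, "condition")),
    sprintf("# half_width=%s", attr(scores, "half_width")),
    sprintf("# decay_constant=%s", attr(scores, "decay_constant")),
    paste(c("gene_id", colnames(scores)), collapse = "\t")), con)
  utils::write.table(
    data.frame(gene_id = rownames(scores), unclass(scores)[, , drop = FALSE],
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TF-gene score matrix written by [write_tf_gene_scores()]
#'
#' @param path file path.
#' @return a `tf_gene_scores` matrix.
#' @export
read_tf_gene_scores <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, condition = meta$condition,
            half_width = as.numeric(meta$half_width),
            decay_constant = as.numeric(meta$decay_constant),
            class = "tf_gene_scores")
}
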