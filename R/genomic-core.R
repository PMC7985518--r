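# Interval conventions used throughout:
#   * in-memory intervals are GRanges (1-based closed, the Bioconductor norm)
#   * on disk, BED is 0-based half-open and GTF is 1-based closed; the
#     readers/writers convert so that round trips are lossless.

#' Construct a genomic interval set
#'
#' Thin validated constructor for the interval container used across the
#' package (a `GRanges`). BED-style 0-based half-open coordinates are
#' converted to the 1-based closed convention of `GRanges`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start (BED convention).
#' @param end integer vector, 0-based exclusive end; must satisfy `end > start`.
#' @param name optional label vector.
#' @param score optional numeric score vector.
#' @return A `GRanges` with optional `name` and `score` metadata columns.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  gr
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3+ (optionally with name and score columns). Coordinates in the
#' file are 0-based half-open; the returned `GRanges` is 1-based closed.
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path path to a BED file.
#' @return `GRanges`, one range per data line, in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", line_no[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    stop("BED parse error at line ", line_no[which(bad)[1L]],
         ": non-integer coordinates")
  }
  bad <- end <= start | start < 0
  if (any(bad)) {
    stop("BED parse error at line ", line_no[which(bad)[1L]],
         ": end <= start (or negative start)")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  NA_real_)
  gr <- genomic_intervals(chrom, start, end)
  if (any(nf >= 4L)) gr$name <- name
  if (any(nf >= 5L)) gr$score <- score
  gr
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates, with `name`
#' and `score` columns when present.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  cols <- list(
    as.character(GenomicRanges::seqnames(gr)),
    format(GenomicRanges::start(gr) - 1L, scientific = FALSE, trim = TRUE),
    format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE)
  )
  if (!is.null(gr$name)) {
    cols <- c(cols, list(gr$name))
    if (!is.null(gr$score)) cols <- c(cols, list(as.character(gr$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Imports `gene` feature lines, validates them, and derives the
#' strand-aware transcription start site: for `+` genes the TSS is the
#' leftmost base, for `-` genes the rightmost. GTF coordinates are 1-based
#' closed and kept that way in the returned `GRanges`.
#'
#' @param path path to a GTF file containing `gene` feature lines with a
#'   `gene_id` attribute (and optionally `gene_name`).
#' @return `GRanges` with metadata columns `gene_id`, `symbol` and `tss`
#'   (1-based position of the TSS).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no 'gene' feature lines in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("GTF parse error: gene feature without gene_id attribute in ", path)
  }
  unstranded <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " gene record(s) with unknown strand skipped")
    gr <- gr[!unstranded]
  }
  dup <- duplicated(gr$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene_id record(s) dropped (first kept)")
    gr <- gr[!dup]
  }
  gr$symbol <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  gr$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("gene_id", "symbol", "tss")]
  names(gr) <- gr$gene_id
  gr
}

#' TSS-centred windows for a set of genes
#'
#' Builds the window `[tss - half_width, tss + half_width)` (0-based
#' half-open semantics; returned as 1-based closed `GRanges`) for each gene,
#' clamped at the chromosome start.
#'
#' @param genes `GRanges` from [read_gene_annotation()] (needs a `tss`
#'   metadata column).
#' @param half_width window half width in bp (default 25000, i.e. the
#'   classical 50 kb window centred at the TSS).
#' @return `GRanges` of windows, named by `gene_id`.
#' @export
tss_window <- function(genes, half_width = 25000) {
  if (half_width <= 0) stop("half_width must be > 0")
  tss0 <- genes$tss - 1L  # 0-based TSS
  start0 <- pmax(0, tss0 - half_width)
  end0 <- tss0 + half_width
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  names(win) <- genes$gene_id
  win$gene_id <- genes$gene_id
  win
}

#' All overlapping pairs between two interval sets
#'
#' A pair is reported iff the two ranges are on the same chromosome and
#' share at least 1 bp (half-open semantics on the underlying 0-based
#' coordinates, i.e. touching intervals do not overlap).
#'
#' @param a,b `GRanges`.
#' @return two-column integer matrix of (index in `a`, index in `b`) pairs.
#' @export
overlaps <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L,
                                      ignore.strand = TRUE)
  cbind(index_a = S4Vectors::queryHits(hits),
        index_b = S4Vectors::subjectHits(hits))
}

#' Extract an interval's DNA sequence from a genome
#'
#' @param genome a named `DNAStringSet` (as returned by
#'   `Biostrings::readDNAStringSet`) or the path to a FASTA file.
#' @param interval a length-one `GRanges`.
#' @return uppercase character sequence of length `width(interval)`;
#'   soft-masked lowercase bases are promoted to uppercase.
#' @export
extract_sequence <- function(genome, interval) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  chrom <- as.character(GenomicRanges::seqnames(interval))
  nm <- sub(" .*$", "", names(genome))
  i <- match(chrom, nm)
  if (is.na(i)) stop("chromosome not in FASTA: ", chrom)
  s <- GenomicRanges::start(interval)
  e <- GenomicRanges::end(interval)
  if (s < 1L || e > Biostrings::width(genome)[i]) {
    stop("interval out of chromosome bounds: ", chrom, ":", s, "-", e)
  }
  toupper(as.character(Biostrings::subseq(genome[[i]], start = s, end = e)))
}

#' Read a REM (regulatory element) table
#'
#' Tab-separated file with columns chrom, start, end (0-based half-open),
#' rem_id, gene_id linking each regulatory element to its target gene.
#'
#' @param path path to the table (a header line starting with `chrom` or
#'   `#` is tolerated).
#' @param genes optional `GRanges` of genes; links whose `gene_id` is not
#'   present are flagged unresolved (dropped with a warning).
#' @return `GRanges` with metadata columns `rem_id` and `gene_id`.
#' @export
read_rem_table <- function(path, genes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!is.numeric(df[[2]])) {  # header row present
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
  }
  names(df)[1:5] <- c("chrom", "start", "end", "rem_id", "gene_id")
  gr <- genomic_intervals(df$chrom, df$start, df$end)
  gr$rem_id <- as.character(df$rem_id)
  gr$gene_id <- as.character(df$gene_id)
  if (!is.null(genes)) {
    unresolved <- !(gr$gene_id %in% genes$gene_id)
    if (any(unresolved)) {
      warning(sum(unresolved), " REM link(s) to unknown gene ids dropped")
      gr <- gr[!unresolved]
    }
  }
  gr
}

#' Read a differential-expression table for one time point
#'
#' Tab-separated columns: gene_id, log2fc, padj (header tolerated).
#'
#' @param path file path.
#' @param timepoint label attached to the records (e.g. `"2.5h"`).
#' @return data.frame with columns `gene_id`, `timepoint`, `log2fc`, `padj`.
#' @export
read_deg_table <- function(path, timepoint) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!is.numeric(df[[2]])) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
  }
  names(df)[1:3] <- c("gene_id", "log2fc", "padj")
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0,1] in ", path)
  }
  data.frame(gene_id = as.character(df$gene_id), timepoint = timepoint,
             log2fc = df$log2fc, padj = df$padj,
             stringsAsFactors = FALSE)
}
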