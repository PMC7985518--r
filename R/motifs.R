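# Motif input. Two dialects are auto-detected:
#   * JASPAR count matrices: ">ID NAME" header, then four rows (A,C,G,T),
#     optionally "A [ 1 2 3 ]"-style brackets;
#   * a TRANSFAC-like dialect: "ID <name>" records with a "P0 A C G T"
#     column header and one row per motif position, terminated by "//".

.BASES <- c("A", "C", "G", "T")

#' Construct a position count/weight matrix object
#'
#' @param tf_name transcription factor name.
#' @param motif_id motif identifier.
#' @param counts 4 x m nonnegative matrix (rows A, C, G, T).
#' @param source motif-set provenance label.
#' @return a `pwm` object.
#' @export
new_pwm <- function(tf_name, motif_id, counts, source = "motifs") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4L) stop("PWM '", motif_id, "' has fewer than 4 columns")
  if (any(counts < 0)) stop("PWM counts must be nonnegative")
  rownames(counts) <- .BASES
  structure(list(tf_name = tf_name, motif_id = motif_id,
                 counts = counts, source = source),
            class = "pwm")
}

#' Read a motif collection
#'
#' Parses JASPAR-format count matrices or a TRANSFAC-like dialect
#' (auto-detected from the file content).
#'
#' @param path path to the motif file.
#' @param source label recorded on every motif (motif-set provenance).
#' @return named list of `pwm` objects (names are motif ids).
#' @export
read_motifs <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl("^P[O0]\\b", lines))) {
    .parse_transfac(lines, source)
  } else if (any(grepl("^>", lines))) {
    .parse_jaspar(lines, source)
  } else {
    stop("unrecognized motif format in ", path)
  }
}

.parse_jaspar <- function(lines, source) {
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR '>' headers found")
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) >= 2) toks[2] else toks[1]
    body <- lines[(heads[k] + 1L):ends[k]]
    if (length(body) < 4L) stop("motif ", motif_id, ": fewer than 4 matrix rows")
    body <- body[1:4]
    row_base <- toupper(substr(trimws(body), 1, 1))
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      l <- sub("^\\s*[ACGTacgt]\\s+", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("motif ", motif_id, ": ragged matrix rows")
    }
    counts <- do.call(rbind, rows)
    if (all(row_base %in% .BASES)) counts <- counts[match(.BASES, row_base), ]
    out[[motif_id]] <- new_pwm(tf_name, motif_id, counts, source)
  }
  out
}

.parse_transfac <- function(lines, source) {
  out <- list()
  i <- 1L
  tf_name <- motif_id <- NA_character_
  rows <- list()
  col_order <- .BASES
  flush <- function() {
    if (length(rows) > 0L) {
      counts <- t(do.call(rbind, rows))
      counts <- counts[match(.BASES, col_order), , drop = FALSE]
      id <- if (is.na(motif_id)) tf_name else motif_id
      out[[id]] <<- new_pwm(tf_name, id, counts, source)
    }
    rows <<- list(); tf_name <<- motif_id <<- NA_character_
  }
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (grepl("^ID\\b", l)) {
      motif_id <- strsplit(l, "\\s+")[[1]][2]
      if (is.na(tf_name)) tf_name <- motif_id
    } else if (grepl("^NA\\b", l)) {
      tf_name <- strsplit(l, "\\s+")[[1]][2]
    } else if (grepl("^P[O0]\\b", l)) {
      col_order <- toupper(strsplit(l, "\\s+")[[1]][-1])
      if (!setequal(col_order, .BASES)) {
        stop("TRANSFAC P0 header must name columns A C G T")
      }
    } else if (grepl("^[0-9]+\\s", l)) {
      v <- strsplit(l, "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(v[2:5])
    } else if (identical(l, "//")) {
      flush()
    }
    i <- i + 1L
  }
  flush()
  out
}

#' Write motifs in JASPAR count-matrix format
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$tf_name), con)
    for (b in .BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Consensus sequence of a motif
#'
#' The highest-count base per column (ties broken in A,C,G,T order).
#'
#' @param pwm a `pwm` object.
#' @return character string of length `ncol(pwm$counts)`.
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$counts, 2, which.max)], collapse = "")
}
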