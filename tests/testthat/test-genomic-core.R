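test_that("read_bed maps fields, skips non-data lines, reports bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "# comment",
               "chr1\t100\t200\tpk1", "chr2\t0\t50\tpk2\t7.5"), f)
  gr <- read_bed(f)
  expect_equal(length(gr), 2L)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr), c(101L, 1L))  # 0-based -> 1-based
  expect_equal(GenomicRanges::end(gr), c(200L, 50L))
  expect_equal(gr$name, c("pk1", "pk2"))

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2.*end <= start")
  writeLines("chr1\tx\t200", f)
  expect_error(read_bed(f), "non-integer")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("BED round trip is lossless on generated fixtures", {
  set.seed(11)
  n <- 200
  start <- sample.int(1e6, n)
  gr <- genomic_intervals(chrom = sample(c("chr1", "chr2", "chr3"), n, TRUE),
                          start = start,
                          end = start + sample.int(5000, n),
                          name = sprintf("iv%03d", seq_len(n)),
                          score = round(stats::runif(n), 3))
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f1)
  back <- read_bed(f1)
  write_bed(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$name, gr$name)
})

test_that("gene annotation reader converts coordinates and derives the TSS", {
  f <- withr::local_tempfile(fileext = ".gtf")
  # GTF line 1001..2000 is 0-based half-open [1000, 2000)
  write_gtf_fixture(f, list(
    list(chrom = "chr1", start = 1001, end = 2000, strand = "+",
         gene_id = "gplus"),
    list(chrom = "chr1", start = 1001, end = 2000, strand = "-",
         gene_id = "gminus")))
  g <- read_gene_annotation(f)
  expect_equal(g["gplus"]$tss, 1001)   # 0-based 1000
  expect_equal(g["gminus"]$tss, 2000)  # 0-based 1999 (end - 1)
  expect_equal(GenomicRanges::start(g["gplus"]), 1001L)
  expect_equal(GenomicRanges::end(g["gplus"]), 2000L)
})

test_that("gene annotation reader: count oracle, strand and duplicates", {
  f <- withr::local_tempfile(fileext = ".gtf")
  set.seed(3)
  rows <- lapply(seq_len(25), function(i) {
    s <- sample.int(1e5, 1)
    list(chrom = sample(c("chr1", "chr2"), 1), start = s, end = s + 500,
         strand = sample(c("+", "-"), 1), gene_id = sprintf("g%02d", i))
  })
  write_gtf_fixture(f, rows)
  g <- read_gene_annotation(f)
  # independent text scan of 'gene' feature lines
  n_lines <- sum(vapply(strsplit(readLines(f), "\t"), function(x)
    x[3] == "gene", logical(1)))
  expect_equal(length(g), n_lines)

  rows[[26]] <- list(chrom = "chr1", start = 10, end = 20, strand = ".",
                     gene_id = "gdot")
  write_gtf_fixture(f, rows)
  expect_warning(g2 <- read_gene_annotation(f), "unknown strand")
  expect_false("gdot" %in% g2$gene_id)

  rows[[26]] <- rows[[1]]
  write_gtf_fixture(f, rows)
  expect_warning(g3 <- read_gene_annotation(f), "duplicate")
  expect_equal(length(g3), 25L)
})

test_that("tss_window arithmetic, clamping and translation equivariance", {
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(f, list(
    list(chrom = "chr1", start = 30001, end = 31000, strand = "+",
         gene_id = "a"),                                   # 0-based tss 30000
    list(chrom = "chr1", start = 10001, end = 11000, strand = "+",
         gene_id = "b")))                                  # 0-based tss 10000
  g <- read_gene_annotation(f)
  w <- tss_window(g, 25000)
  # [5000, 55000) 0-based == 5001..55000 1-based
  expect_equal(GenomicRanges::start(w["a"]), 5001L)
  expect_equal(GenomicRanges::end(w["a"]), 55000L)
  # clamped at chromosome start: [0, 35000)
  expect_equal(GenomicRanges::start(w["b"]), 1L)
  expect_equal(GenomicRanges::end(w["b"]), 35000L)
  expect_equal(GenomicRanges::width(w["a"]), 50000L)
  # translation equivariance away from the clamp
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(f2, list(list(chrom = "chr1", start = 30001 + 777,
                                  end = 31000 + 777, strand = "+",
                                  gene_id = "a")))
  w2 <- tss_window(read_gene_annotation(f2), 25000)
  expect_equal(GenomicRanges::start(w2), GenomicRanges::start(w["a"]) + 777L)
  expect_error(tss_window(g, 0), "half_width")
})

test_that("overlaps uses half-open 1-bp semantics and matches brute force", {
  a <- genomic_intervals("chr1", 100, 200)
  b1 <- genomic_intervals("chr1", 199, 300)  # 1 bp intersection
  b2 <- genomic_intervals("chr1", 200, 300)  # touching: no overlap
  expect_equal(nrow(overlaps(a, b1)), 1L)
  expect_equal(nrow(overlaps(a, b2)), 0L)
  # shifting b so that b.start == a.end destroys a former 1-bp overlap
  expect_equal(nrow(overlaps(a, GenomicRanges::shift(b1, 1))), 0L)

  set.seed(21)
  n <- 500
  mk <- function() {
    s <- sample.int(10000, n)
    genomic_intervals(sample(c("c1", "c2"), n, TRUE), s,
                      s + sample.int(200, n, replace = TRUE))
  }
  A <- mk(); B <- mk()
  got <- overlaps(A, B)
  ca <- as.character(GenomicRanges::seqnames(A))
  cb <- as.character(GenomicRanges::seqnames(B))
  sa <- GenomicRanges::start(A); ea <- GenomicRanges::end(A)
  sb <- GenomicRanges::start(B); eb <- GenomicRanges::end(B)
  brute_list <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- which(ca[i] == cb & pmin(ea[i], eb) - pmax(sa[i], sb) + 1 >= 1)
    if (length(hit)) brute_list[[i]] <- cbind(i, hit)
  }
  brute <- do.call(rbind, brute_list)
  o1 <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  o2 <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
  expect_equal(unname(o1), unname(o2))
})

test_that("extract_sequence promotes case, checks bounds, honours strandless reverse", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "acgtACGTnn"), fa)
  iv <- genomic_intervals("chrT", 0, 4)
  expect_equal(extract_sequence(fa, iv), "ACGT")
  iv2 <- genomic_intervals("chrT", 2, 9)
  expect_equal(nchar(extract_sequence(fa, iv2)), 7L)
  expect_error(extract_sequence(fa, genomic_intervals("chrT", 5, 20)),
               "bounds")
  expect_error(extract_sequence(fa, genomic_intervals("chrX", 0, 4)),
               "chromosome")
  # reverse-complement oracle on a manually reversed fixture
  s <- random_dna(50, seed = 9)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">f", s, ">r", rc), fa2)
  fwd <- extract_sequence(fa2, genomic_intervals("f", 10, 30))
  rev_win <- extract_sequence(fa2, genomic_intervals("r", 50 - 30, 50 - 10))
  expect_equal(paste(rev(strsplit(chartr("ACGT", "TGCA", fwd), "")[[1]]),
                     collapse = ""), rev_win)
})

test_that("REM and DEG table readers validate their inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t600\tREM1\tgeneA", "chr1\t900\t1400\tREM2\tgeneB"),
             f)
  r <- read_rem_table(f)
  expect_equal(r$rem_id, c("REM1", "REM2"))
  expect_equal(GenomicRanges::start(r), c(101L, 901L))
  genes <- genomic_intervals("chr1", 0, 10)
  genes$gene_id <- "geneA"
  expect_warning(r2 <- read_rem_table(f, genes), "unknown gene")
  expect_equal(length(r2), 1L)

  d <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\t1.5\t0.01", "geneB\t-0.3\t0.8"), d)
  deg <- read_deg_table(d, "4h")
  expect_equal(deg$timepoint, c("4h", "4h"))
  expect_equal(deg$log2fc, c(1.5, -0.3))
  writeLines("geneA\t1.5\t1.4", d)
  expect_error(read_deg_table(d, "4h"), "padj")
})
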