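test_that("motif parsers read JASPAR and TRANSFAC dialects identically", {
  jas <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M0001 TFA",
               "A [ 10  0  5  2 ]",
               "C [  0 20  5  8 ]",
               "G [  5  0  5  0 ]",
               "T [  5  0  5 10 ]"), jas)
  tra <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID M0001", "NA TFA", "P0 A C G T",
               "01 10 0 5 5", "02 0 20 0 0", "03 5 5 5 5",
               "04 2 8 0 10", "//"), tra)
  expect_error(new_pwm("x", "toosmall", matrix(1, 4, 3)), "fewer than 4")
  pj <- read_motifs(jas)[[1]]
  pt <- read_motifs(tra)[[1]]
  expect_equal(pj$tf_name, "TFA")
  expect_equal(unname(pj$counts[, 4]), c(2, 8, 0, 10))
  expect_equal(unname(pj$counts[, 1:3]), unname(pt$counts[, 1:3]))
  # JASPAR writer round trip
  out <- withr::local_tempfile(fileext = ".jaspar")
  write_motifs_jaspar(list(pj), out)
  expect_equal(read_motifs(out)[[1]]$counts, pj$counts)
})

test_that("energy matrices zero the consensus and match the log-ratio form", {
  # uniform column: all four energies 0
  uni <- new_pwm("U", "U.1", matrix(0.25, 4, 4))
  em <- pwm_to_energy_matrix(uni, pseudocount = 0)
  expect_true(all(em$energies == 0))
  # (0.85, 0.05, 0.05, 0.05) at lambda = 0.7: non-consensus = ln(17)/0.7
  p <- matrix(c(0.85, 0.05, 0.05, 0.05), 4, 5)
  em2 <- pwm_to_energy_matrix(new_pwm("X", "X.1", p), lambda_param = 0.7,
                              pseudocount = 0)
  expect_equal(unname(em2$energies[1, ]), rep(0, 5))
  expect_equal(unname(em2$energies[2, ]), rep(log(17) / 0.7, 5),
               tolerance = 1e-12)
  # consensus base has energy zero in every column for arbitrary motifs
  em3 <- pwm_to_energy_matrix(random_pwm(seed = 4))
  expect_true(all(abs(apply(em3$energies, 2, min)) < 1e-12))
  expect_true(all(em3$energies >= 0))
  expect_equal(em3$ln_r0, 0.584 * 8 - 5.66)
  expect_error(pwm_to_energy_matrix(uni, lambda_param = 0), "lambda")
})

test_that("trap_affinity closed forms: all-N, zero-energy window, short input", {
  em <- pwm_to_energy_matrix(random_pwm(m = 6, seed = 2))
  expect_equal(trap_affinity(em, strrep("N", 30)), 0)
  # uniform motif: every window has energy 0; single-window sequence gives
  # occupancy R0/(1+R0) on each strand
  uni <- pwm_to_energy_matrix(new_pwm("U", "U.1", matrix(0.25, 4, 6)),
                              pseudocount = 0)
  R0 <- exp(uni$ln_r0)
  expect_equal(trap_affinity(uni, "ACGTAC"), 2 * R0 / (1 + R0),
               tolerance = 1e-12)
  expect_warning(a <- trap_affinity(em, "ACG"), "shorter")
  expect_equal(a, 0)
})

test_that("trap_affinity equals the naive loop oracle on random sequences", {
  em <- pwm_to_energy_matrix(random_pwm(m = 8, seed = 13))
  set.seed(99)
  for (i in 1:100) {
    s <- random_dna(60)
    if (i %% 7 == 0) substr(s, 20, 22) <- "NNN"  # exercise ambiguous bases
    expect_equal(trap_affinity(em, s), naive_trap(em, s), tolerance = 1e-9)
  }
})

test_that("trap_affinity is reverse-complement invariant and monotone in planted sites", {
  pwm <- random_pwm(m = 9, seed = 31)
  em <- pwm_to_energy_matrix(pwm)
  set.seed(42)
  for (i in 1:25) {
    s <- random_dna(80)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_equal(trap_affinity(em, s), trap_affinity(em, rc),
                 tolerance = 1e-9)
    # appending a consensus site never lowers the affinity
    expect_gte(trap_affinity(em, paste0(s, pwm_consensus(pwm))),
               trap_affinity(em, s))
  }
})

test_that("calibrate_threshold is a deterministic exceedance quantile", {
  em <- pwm_to_energy_matrix(random_pwm(m = 7, seed = 8))
  templates <- vapply(1:20, function(i) random_dna(60), character(1))
  shuf <- shuffle_dinucleotides(templates, n = 1000, seed = 77)
  expect_identical(shuf, shuffle_dinucleotides(templates, n = 1000, seed = 77))
  # doublet composition is preserved
  doublets <- function(s) {
    L <- nchar(s) - nchar(s) %% 2
    sort(substring(s, seq(1, L - 1, 2), seq(2, L, 2)))
  }
  expect_identical(doublets(shuf[1]), doublets(templates[1]))

  aff <- vapply(shuf, function(s) trap_affinity(em, s), numeric(1),
                USE.NAMES = FALSE)
  thr <- calibrate_threshold(em, shuf, p_value = 0.05)
  # independent sorted-array quantile: at most 5% of the random set may
  # meet or exceed the threshold
  expect_equal(thr, sort(aff)[floor(0.95 * 1000) + 1])
  expect_lte(mean(aff >= thr), 0.05)
  # monotone non-increasing in p_value; p = 1/n picks the maximum
  expect_lte(calibrate_threshold(em, shuf, 0.5), thr)
  expect_equal(calibrate_threshold(em, shuf, 1 / 1000), max(aff))
  expect_error(calibrate_threshold(em, character(0), 0.05), "non-empty")
})

test_that("gene-TF scores: decay closed forms, additivity, thresholding", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(gtf, list(list(chrom = "c1", start = 100001,
                                   end = 102000, strand = "+",
                                   gene_id = "g1")))
  genes <- read_gene_annotation(gtf)  # 0-based tss = 100000
  mk_aff <- function(vals) {
    A <- matrix(vals, ncol = 1, dimnames = list(NULL, "M1"))
    attr(A, "tf_name") <- c(M1 = "TF1")
    A
  }
  # region centred exactly at the TSS: weight exp(0) == 1
  r0 <- genomic_intervals("c1", 100000 - 150, 100000 + 150)
  sc <- compute_gene_tf_scores(r0, mk_aff(0.8), genes,
                               decay_constant = 5000)
  expect_equal(unname(sc["g1", "TF1"]), 0.8, tolerance = 1e-12)
  # region centred at distance d0: weight exp(-1)
  r1 <- GenomicRanges::shift(r0, 5000)
  sc1 <- compute_gene_tf_scores(r1, mk_aff(0.8), genes,
                                decay_constant = 5000)
  expect_equal(unname(sc1["g1", "TF1"]), 0.8 * exp(-1), tolerance = 1e-12)
  # two regions: contributions add
  both <- c(r0, r1)
  sc2 <- compute_gene_tf_scores(both, mk_aff(c(0.8, 0.8)), genes,
                                decay_constant = 5000)
  expect_equal(unname(sc2["g1", "TF1"]),
               unname(sc["g1", "TF1"]) + unname(sc1["g1", "TF1"]),
               tolerance = 1e-12)
  # sub-threshold affinities contribute nothing
  sc3 <- compute_gene_tf_scores(both, mk_aff(c(0.8, 0.3)), genes,
                                decay_constant = 5000,
                                threshold_per_motif = c(M1 = 0.5))
  expect_equal(unname(sc3["g1", "TF1"]), 0.8, tolerance = 1e-12)
  # a gene with no qualifying region scores 0
  far <- GenomicRanges::shift(r0, 3e5)
  sc4 <- compute_gene_tf_scores(far, mk_aff(0.9), genes)
  expect_equal(unname(sc4["g1", "TF1"]), 0)
  expect_error(compute_gene_tf_scores(r0, mk_aff(0.8), genes,
                                      decay_constant = 0), "decay_constant")
})

test_that("gene-TF scores decay monotonically with region distance", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(gtf, list(list(chrom = "c1", start = 100001,
                                   end = 102000, strand = "+",
                                   gene_id = "g1")))
  genes <- read_gene_annotation(gtf)
  A <- matrix(1, ncol = 1, dimnames = list(NULL, "M1"))
  attr(A, "tf_name") <- c(M1 = "TF1")
  dists <- seq(0, 24000, by = 1500)
  scores <- vapply(dists, function(d) {
    r <- genomic_intervals("c1", 100000 + d - 100, 100000 + d + 100)
    unname(compute_gene_tf_scores(r, A, genes)["g1", "TF1"])
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-15))
})

test_that("score matrices round trip through their TSV format", {
  m <- matrix(c(0.5, 0, 1.25, 3e-4), 2, 2,
              dimnames = list(c("g1", "g2"), c("TFA", "TFB")))
  sc <- structure(m, condition = "treated", half_width = 25000,
                  decay_constant = 5000, class = "tf_gene_scores")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tf_gene_scores(sc, f)
  back <- read_tf_gene_scores(f)
  expect_equal(unclass(back), unclass(sc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "condition"), "treated")
  expect_equal(attr(back, "decay_constant"), 5000)
})
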