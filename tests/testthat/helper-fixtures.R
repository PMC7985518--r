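# Shared fixtures. Bundles are generated once per test run and cached in a
# session-local environment; all fixture data is built in code.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# pipeline config pointing at a generated bundle
bundle_config <- function(bundle, ...) {
  default_pipeline_config(
    genome_fasta = bundle$paths$genome_fasta,
    genes_gtf = bundle$paths$genes_gtf,
    peaks_bed = bundle$paths$peaks_bed,
    open_control_bed = bundle$paths$open_control_bed,
    open_treated_bed = bundle$paths$open_treated_bed,
    rem_tsv = bundle$paths$rem_tsv,
    motifs = bundle$paths$motifs,
    deg_tables = as.list(bundle$paths$deg_tables),
    ...)
}

# default-scale bundle (300 genes) + pipeline result
default_bundle <- function() cached("default_bundle", {
  generate_synthetic_bundle(sim_config(seed = 20),
                            file.path(tempdir(), "tfc_default_bundle"))
})

default_pipeline_result <- function() cached("default_pipeline", {
  suppressWarnings(suppressMessages(
    run_pipeline(bundle_config(default_bundle(), seed = 20))))
})

# small bundle (40 genes) for cheap structural tests
small_sim_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_genes = 40, chrom_length = 1.4e6,
             n_calibration = 100, ...)
}

small_bundle <- function() cached("small_bundle", {
  generate_synthetic_bundle(small_sim_config(),
                            file.path(tempdir(), "tfc_small_bundle"))
})

small_pipeline_result <- function() cached("small_pipeline", {
  suppressWarnings(suppressMessages(
    run_pipeline(bundle_config(small_bundle(), n_random_sequences = 200,
                               seed = 5)))) })

# a toy PWM with a random but fixed consensus
random_pwm <- function(tf = "TFX", m = 8, seed = 1, strength = 85) {
  set.seed(seed)
  cons <- sample(1:4, m, replace = TRUE)
  counts <- matrix(5, nrow = 4, ncol = m)
  counts[cbind(cons, seq_len(m))] <- strength
  new_pwm(tf, paste0(tf, ".toy"), counts)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent TRAP oracle: explicit per-window, per-position loops.
naive_trap <- function(em, sequence) {
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- ncol(em$energies)
  R0 <- exp(em$ln_r0)
  total <- 0
  for (strand in 1:2) {
    bs <- if (strand == 1) bases else rev(unname(comp[bases]))
    nw <- length(bs) - m + 1
    if (nw < 1) next
    for (i in seq_len(nw)) {
      E <- 0
      skip <- FALSE
      for (j in seq_len(m)) {
        b <- bs[i + j - 1]
        if (is.na(b) || !(b %in% c("A", "C", "G", "T"))) {
          skip <- TRUE
          break
        }
        E <- E + em$energies[b, j]
      }
      if (!skip) total <- total + R0 * exp(-E) / (1 + R0 * exp(-E))
    }
  }
  unname(total)
}

# simple GTF fixture writer (1-based closed coordinates, as in the format)
write_gtf_fixture <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r$chrom, "test", "gene", r$start, r$end, ".", r$strand, ".",
          sprintf('gene_id "%s"; gene_name "%s";', r$gene_id,
                  if (is.null(r$symbol)) r$gene_id else r$symbol),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# ground-truth evaluation helpers
recovery_stats <- function(classification, truth) {
  truth_primary <- truth$gene_id[truth$class %in%
                                   c("early-primary", "late-primary")]
  truth_deg <- truth$gene_id[truth$class != "unresponsive"]
  truth_secondary <- setdiff(truth_deg, truth_primary)
  pred_primary <- classification$gene_id[classification$is_primary]
  truth_timing <- ifelse(grepl("^early", truth$class), "early", "late")
  names(truth_timing) <- truth$gene_id
  list(
    sensitivity = length(intersect(pred_primary, truth_primary)) /
      length(truth_primary),
    specificity = 1 - length(intersect(pred_primary, truth_secondary)) /
      length(truth_secondary),
    timing_accuracy = mean(classification$timing ==
                             truth_timing[classification$gene_id]),
    early_recall = {
      te <- truth$gene_id[truth$class == "early-primary"]
      pe <- classification$gene_id[classification$timing == "early"]
      length(intersect(pe, te)) / length(te)
    })
}
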