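---
title: "Classifying primary and secondary TF targets: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying primary and secondary TF targets: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tfcascade` separates the direct (primary) target genes of a
ligand-activated root transcription factor from indirect (secondary)
responders, ranks the TFs that drive the secondary response, and builds
the resulting directed regulatory network. This vignette explains the
models, the parameters that matter, and the design decisions taken where
the problem left genuine freedom. It states no empirical result beyond
what the package's tests and acceptance script themselves compute.

## The classification model

The unit of analysis is a differentially expressed gene (DEG): a gene
with `padj < 0.05` (strict inequality, the conventional DESeq2-style
cutoff; configurable) at one or more time points. Timing is a dichotomy:
*early* if significant at any early time point (defaults `2.5h`, `4h`),
otherwise *late* (default `24h`). A gene significant both early and late
counts as early — first significance wins. Genes never significant are
excluded entirely.

Three independent evidence channels connect the root TF to a gene:

* **window**: ≥ 1 ChIP-seq peak of the root TF overlaps the gene's
  TSS-centred window;
* **REM**: ≥ 1 root-TF peak overlaps a regulatory element that an
  external catalogue (EpiRegio-style, region → gene links) ties to the
  gene;
* **motif**: the gene's TF–gene score for the root TF is positive in the
  treated-condition open chromatin, where scores are built from
  affinities that passed a calibrated threshold.

A DEG is *primary* when at least `k_methods` channels fire. The default
`k_methods = 1` reflects the permissive published reading ("predicted by
any of the three methods"); `k_methods = 2` reproduces the stringent
variant. Raising `k` can only shrink the primary set — a monotonicity the
test suite asserts.

Coordinate conventions are fixed once: BED input is 0-based half-open,
GTF 1-based closed (converted on read), and all overlap logic requires
≥ 1 bp of intersection under half-open semantics, so touching intervals
do not overlap. The TSS window is `[tss − half_width, tss + half_width)`
with `half_width = 25000` bp, clamped at the chromosome start. Full peak
intervals (not summits) are used for window assignment: the most
permissive reading, and summits are not always available.

## TRAP affinities and decayed TF–gene scores

The motif channel is biophysical rather than hit-counting. A count matrix
becomes a position-specific energy matrix

$$E(b, i) = \frac{1}{\lambda}\,\ln\frac{p_{\max,i}}{p_{b,i}},$$

with pseudocount 1 on counts and probabilities floored at 0.001 (so zero
counts never produce infinite energies). A window of motif length $m$
with total energy $E$ contributes occupancy
$R_0 e^{-E}/(1 + R_0 e^{-E})$, $\ln R_0 = 0.584\,m - 5.66$; a region's
affinity is the occupancy sum over all windows on both strands. The
constants $\lambda = 0.7$ and the $\ln R_0$ line are the published TRAP
defaults and are exposed in the configuration. Windows containing
ambiguous bases (N) contribute zero rather than erroring — genomes
contain gaps; sequences shorter than the motif yield affinity 0 with a
warning.

**Threshold calibration.** Affinities are kept only if they meet a
per-motif threshold computed from background sequences: the package
shuffles the input open-chromatin sequences (non-overlapping doublet
permutation, which preserves dinucleotide composition at even phase — a
deliberate, documented approximation to an exact Euler-path dinucleotide
shuffle) and takes the empirical exceedance quantile at `p = 0.05`: the
order statistic of rank `floor((1 − p)·n) + 1`, so at most a fraction `p`
of background sequences meet the threshold, `p = 1/n` picks the observed
maximum, and the threshold is monotone non-increasing in `p`. The
calibration is deterministic given the shuffle seed, which is recorded in
the run configuration. Thresholding is applied to raw region affinities
*before* decay weighting (configurable): a weak site does not become
acceptable merely by sitting on the TSS.

**Gene scores.** Each qualifying region in a gene's window contributes
its affinity times $\exp(-d/d_0)$, with $d$ the distance from region
centre to TSS and $d_0 = 5000$ bp, following the TEPIC lineage; region
centre is the symmetric, convention-free choice of anchor. Motif variants
of one TF (several databases often model the same factor) are aggregated
per gene by maximum (configurable `max`/`sum`/`mean`); maximum is
conservative in the sense that one well-supported variant suffices and no
variant can dilute another.

## Driver-TF regression

For the late DEGs *not* classified primary (the secondary set — the
restriction is the default and can be disabled), the package builds the
feature matrix $x_{gt} = \log_2\!\big((s^{\text{trt}}_{gt} +
\varepsilon)/(s^{\text{ctl}}_{gt} + \varepsilon)\big)$ with
$\varepsilon = 10^{-3}$, labels up/down from the sign of the late fold
change (zero fold changes excluded), and fits an elastic-net logistic
regression with mixing $\alpha = 0.1$ — mostly ridge with enough lasso to
zero irrelevant TFs, the DYNAMITE-style default. The penalty is chosen by
inner cross-validation on misclassification error over a logarithmic
grid spanning six decades ($10^{1}$ to $10^{-5}$, 60 values); raw
coefficients are averaged over 6 outer folds; features are standardized
once to zero mean and unit variance (constant columns become zero and can
never be selected). Fold assignments derive from a mandatory seed, making
fits bit-identical across runs. Reported importances are
$|\beta_t|/\max_t |\beta_t| \in [0,1]$, ranked descending with ties
broken alphabetically; an all-zero fit stays all-zero rather than
dividing by zero.

Held-out fold accuracy is retained on the fit object: it is the honest
summary of whether the features carry signal at all, and the
permuted-label control in the acceptance script uses exactly this
quantity (planted labels ≈ 1.0, permuted ≈ 0.5 on the synthetic
landscape).

## The TF network

The network is a directed graph over the root TF and the primary-target
TF genes. The root points at every primary TF (`root_primary` edges, one
per node, so every non-root node has in-degree ≥ 1). An early-timing TF
`e` points at TF `t ≠ e` (`predicted_binding`) when the decayed gene
score of `e`'s motif at `t`'s locus exceeds a threshold — by default the
per-TF calibrated affinity threshold, overridable by a constant. Decayed
gene scores (not raw region affinities) are compared, consistent with
"binding at the gene locus"; late TFs never emit binding edges, matching
the construction's directionality; parallel root and binding evidence
yields two typed edges rather than a merged one. Edge sets shrink
monotonically in the threshold, which the tests assert.

## What the synthetic generator emulates — and what it does not

The generator builds a miniature landscape with known ground truth:
i.i.d. genome at GC 0.41 (the human-like default), genes on a 60 kb grid
with both strands, per-gene ground-truth classes (early-primary,
late-primary, late-secondary, unresponsive), evidence channels for
primary genes drawn from a configurable 7-cell distribution, driver-TF
motif instances whose open-chromatin presence is condition-specific
(treated-only for up-regulated secondary genes, control-only for
down-regulated), planted early-TF → TF-gene binding regions, and DEG
tables in which no gene is significant early but not late.

Geometry is chosen so evidence cannot leak: adjacent TSSs sit 60 kb
apart, so 50 kb windows never overlap, and REM evidence (a REM plus
overlapping peak, linked to the gene) is placed in the inter-window dead
zone ~27 kb downstream of the TSS — outside every window, so it fires
only the REM channel of its linked gene. This spacing requirement is also
why the default chromosome length is 9.2 Mb for 300 genes on two
chromosomes: the geometric invariant `chrom_length ≥
n_genes · 60 kb / n_chromosomes` is enforced at configuration time.

Two invariants are *actively enforced* during generation. Every
open-chromatin region that is not supposed to carry evidence for a motif
is rejection-sampled until its TRAP affinity stays below half the
generator-calibrated threshold for every planted motif; and every planted
consensus region is verified to exceed its motif's threshold (redrawn
flanks otherwise). Without the first enforcement, a p = 0.05 quantile
threshold would by construction let ~5% of background regions through,
and "clean" ground truth would not be clean. The factor-of-two safety
margin absorbs the difference between the generator's internal
calibration (generic random sequences) and the pipeline's calibration
(shuffles of the actual input regions).

What the generator does **not** emulate: read-level noise and peak-caller
artefacts, overlapping regulatory domains of neighbouring genes,
correlated TF binding (each motif is planted independently), repeat
structure or CpG islands, REM catalogues with wrong links, and expression
count matrices (the DEG summaries are drawn directly). Passing the
recovery tests therefore demonstrates the correctness of the pipeline's
logic under its own assumptions — not robustness to the full noise
spectrum of real ChIP-seq/FAIRE-seq data. The noise dials that do exist
(`peak_noise_rate` for decoy peaks, `label_noise_rate` for sign flips)
exercise degradation, not realism.

Default problem sizes — 300 genes, two chromosomes, six TFs, 1000
background sequences for calibration, 20 regression replicates — were
chosen as the smallest landscape on which all seven evidence-channel
combinations, both response timings, a driver cascade and a multi-edge
network coexist comfortably; the full workflow runs in well under a
minute on a laptop.

## Numerical choices and degenerate inputs

* Percentages are always derived from counts at the moment of reporting
  (one decimal, round-half-even) and counts are always emitted alongside;
  nothing stores a percentage independently of its counts.
* The exceedance-quantile definition above was chosen over R's
  interpolating `quantile()` types so the threshold is always an observed
  affinity and the `p = 1/n` extreme is exactly the sample maximum.
* Duplicate gene ids in the annotation keep the first record with a
  warning; unknown strands are skipped with a warning; unresolvable REM
  links are dropped with a warning and never silently flag anything.
* An all-constant feature matrix yields all-zero coefficients and a
  warning instead of an error; single-class labels are an error (there is
  nothing to discriminate).
* Ties in TF ranking break alphabetically, making output tables stable.
* Every stage is a pure function of (inputs, config, seed); byte-level
  determinism of output tables is asserted in the acceptance tests.

## Known limitations

* TRAP assumes independent positions and a single energy scale; complex
  dimeric binding profiles (exactly the motifs where the window channel
  outperforms the motif channel) are modelled imperfectly.
* The REM channel is only as good as the region → gene catalogue; the
  package validates links against the annotation but cannot detect wrong
  ones.
* The regression ranks TFs by discriminative importance for the up/down
  contrast; a TF driving both directions equally, or acting through
  unchanged chromatin, scores low by construction.
* The network threshold inherits the motif calibration; edges to TFs
  without a motif model cannot exist and are warned about.
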