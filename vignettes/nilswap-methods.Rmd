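---
title: "Models and design choices in nilswap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in nilswap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilswap)
```

## The experimental design the package models

`nilswap` analyzes reciprocal near-isogenic-line (NIL) allele-swap RNA-seq
experiments. Two recurrent parents differ at a locus of interest — in the
motivating application, the rice aluminum-resistance C2H2 zinc-finger
transcription factor ART1 — and the locus from each parent is introgressed
into the other's genetic background, giving four genotypes: `parentA`
(resistant allele, background A), `nilA` (background A carrying the
sensitive allele), `parentB` (sensitive allele, background B), and `nilB`
(background B carrying the resistant allele). Each genotype is profiled
under control and stress conditions with four biological replicates, so the
full design has 4 × 2 × 4 = 32 samples.

The question the comparative layer answers is *allele responsiveness*: for
a gene induced (or repressed) by stress, is the response stronger in the
line carrying the resistant-parent allele than in the otherwise-isogenic
line carrying the sensitive allele?

## The negative-binomial DE engine

The engine is a deliberately simple NB Wald pipeline, not a re-implementation
of any existing package's internals; downstream analyses consume only its
`(log2FoldChange, padj)` pairs, and its adequacy is demonstrated by
calibration and recovery on synthetic data (see the test suite and
`scripts/acceptance.R`).

**Size factors.** Median-of-ratios: \(s_j = \mathrm{median}_g\,
K_{gj}/(\prod_{j'} K_{gj'})^{1/n}\) over reference genes with all counts
positive. This is scaling-equivariant and robust to a minority of DE genes.

**Low-expression pre-filter.** A gene is retained iff its raw total across
samples is at least \(T = \overline{K^{norm}}/n\), the overall mean
normalized count divided by the number of samples. The comparison is
inclusive (`>= T`): the rule as stated eliminates genes *below* the
threshold. The raw/normalized asymmetry (raw totals against a
normalized-count threshold) is kept as stated.

**Dispersions.** With only four replicates per cell, gene-wise
method-of-moments estimates \(\hat\alpha_g = \max(0,(s^2-\bar\mu)/\bar\mu^2)\)
(within-cell variance pooled over genotype × treatment cells) are noisy, so
a mean-dispersion trend \(\alpha(\mu)=a_0+a_1/\mu\) is fitted by least
squares and the final value shrinks the log gene-wise estimate halfway
toward the log trend (`shrink_weight = 0.5`, configurable; the weight is a
design choice, since no prescription exists for this simplified engine).
Everything is floored at `1e-8`.

**Wald contrasts.** Per genotype, the model \(\log\mu_{gj} = \log s_j +
\beta_0 + \beta_1 x_j\) (x = stress indicator) is fitted by IRLS with the
dispersion fixed, vectorized across genes (the 2 × 2 normal equations are
solved in closed form, so ten thousand genes fit in well under a second).
`log2FoldChange` is \(\hat\beta_1/\ln 2\), the SE comes from the Fisher
information at the fit, p values are two-sided normal, and BH adjustment
runs over the tested genes only: all-zero and non-converged genes are
flagged `NA` and excluded from the BH denominator. Fitting contrasts
*within* each genotype (rather than a joint interaction model) mirrors how
per-genotype DE gene lists are compared downstream.

Calibration, measured by the acceptance script on a 10,000-gene null with
known dispersion (μ = 100, α = 0.05, 4 + 4 replicates): type-I error at
nominal 0.05 lands at 0.049–0.052 across seeds, and a planted log2FC of 2
(μ = 200, α = 0.05) is recovered with mean ≈ 2.00 over 1,000 genes.

**DE calling.** Three criteria: |log2FC| ≥ 1 (twofold), padj ≤ 0.05, and at
least eight counts in at least one sample. The count criterion is applied on
the *normalized*-count scale: the two plausible readings (raw vs normalized
log-transformed) conflict, and normalized counts are the interpretable,
depth-independent choice. It is configurable via `de_criteria()`.

## Allele-responsiveness ratio classification

For paired per-genotype fold changes, the classifier works on the linear
fold-change scale: a gene is "k-fold more responsive" under the reference
allele iff \(2^{lfc_{ref}-lfc_{alt}} \ge k\), i.e. \(\Delta\mathrm{log2FC}
\ge \log_2 k\), *inclusive*. The inclusive boundary is anchored by the
printed worked examples, where pairs with Δ exactly 1.00 (e.g. 2.65 vs
1.65) are members of the "2× or higher" set. `classify_table()` sorts by
descending Δ (ties keep input order — the within-class ordering of tied
rows is otherwise arbitrary) and reports nested pass counts per threshold,
so every ≥2× gene also counts as ≥1.5×.

`magnitude_test()` compares the global strength of two DE sets' fold
changes with Welch's t by default (the original comparison's test is
unnamed; Welch is the conventional unequal-variance choice), with a
Mann–Whitney alternative behind a flag. `venn_counts()` and
`pca_top_variance()` provide the set-overlap and ordination summaries; PCA
uses the 500 most variable genes of the \(\log_2(K/s+1)\) matrix, centered
per gene, unscaled. The log2-normalized transform stands in for a
regularized-log shrinkage transform: the latter is an internal model fit
with no public definition, the replacement is monotone, depth-corrected and
variance-compressing, and all PCA conclusions drawn in this package are
tested on synthetic data only. Samples flagged as outliers may be dropped
from PCA *display*, but never from DE analysis. `rrg()` is the phenotype
ratio (stress over control total root growth).

## The motif layer

Degenerate IUPAC motifs (e.g. the experimentally defined binding element
GGNVS, or its higher-affinity core GGYMS) are scanned over promoter
libraries with every overlapping offset counted; a sequence `N` never
matches any motif position. Scanning only the extracted upstream strand is
the default (`strand_mode = "given"`), since binding-site orientation
handling is unstated in the motivating analysis; `"both"` adds the reverse
complement. Counting overlaps (rather than greedily consuming matches)
treats the reported per-sequence averages as raw occurrence counts.

`extract_promoters()` anchors at the CDS start codon — not the transcript
start — because the library of putative regulatory regions is defined
upstream of start codons; genes lacking CDS features are skipped with a
warning rather than silently re-anchored. Intervals are clipped at contig
boundaries, and all reported coordinates are 1-based inclusive (internal
arithmetic is 0-based half-open only at the Biostrings boundary).

`expected_hits()` gives the analytic chance expectation
\(E=(L-m+1)\prod_k \sum_{b\in code_k} p_b\): for GGNVS on a uniform 2-kb
sequence, \(1996 \cdot 3/128 \approx 46.78\). This is the reason motif
*presence* is uninformative as regulatory evidence — at ~47 expected chance
hits per promoter, essentially every 2-kb sequence contains the element, a
behavior the acceptance checks reproduce on synthetic libraries.

## Sequence-allele analyses

`translate_cds()` is strict standard-code translation (ATG start warning,
frame check, internal-stop error) up to and excluding the first stop.
`apply_frameshift()` models a single-base deletion: the base at a given
1-based CDS position is removed, supplied downstream (3'UTR) sequence is
appended, and translation runs to the first stop in the shifted frame,
erroring — never silently truncating — if no stop is reached. The deletion
coordinate is always an explicit parameter because a reported "position"
may index nucleotides or codons; the caller decides.
`synthetic_frameshift_fixture()` constructs, purely in code, a synthetic
wild-type/frameshift pair with the same length signature as the motivating
natural allele (465-aa wild type lengthened to a 477-aa read-through
product), so this machinery is exercised end-to-end without shipping any
real genomic sequence.

`diff_proteins()` counts substitutions (aligned mismatch columns) and indel
*events* (maximal contiguous gap runs, so a 3-residue gap is one event —
matching how multi-residue indel blocks are conventionally counted) from a
global affine-gap alignment, BLOSUM62 with gap open 10 / extend 0.5 by
default. Curated alignments can differ from parameter-default optimal
alignments; the parameters are therefore exposed rather than hidden.

## The synthetic-data generator

`simulate_counts()` draws \(K_{gj}\sim NB(s_j\,\mu_g\,2^{x_j\beta_g},
\alpha_g)\) with five planted gene classes (fractions 0.80 null / 0.05
each): `allele_dependent` (stress log2FC 2.7 under the resistant allele vs
0.8 under the sensitive one — modeled on the column means of the printed
twofold tables, ≈2.66 vs ≈0.78), `allele_independent` (log2FC 2 in all
genotypes), `background_specific` (log2FC 2 only in background B, mimicking
genes responsive only in one genetic background), `introgression_effect`
(constitutive ±1.5 log2 baseline shift tracking the introgressed haplotype),
and null. Each non-null gene gets a random sign, so both induction and
repression occur. Baseline means are log-normal(meanlog 4, sdlog 1.5) —
a realistic dynamic range spanning the pre-filter boundary — dispersions
follow the trend \(0.01 + 2/\mu\) (≈0.05 at the median mean, a typical
bulk-RNA-seq scale), and depth factors are log-uniform on [0.5, 2] to
exercise size-factor estimation. All randomness flows from one seed;
identical configurations are bit-identical.

What the generator does *not* emulate: batch effects, gene–gene correlation,
length/GC biases, isoforms, and outlier samples. Recovery results on these
simulations therefore demonstrate the *internal* correctness and calibration
of the pipeline under its own model assumptions, not robustness to the
failure modes of real libraries.

`simulate_promoters()` draws i.i.d. bases at a chosen GC content and plants
non-overlapping concrete expansions of an IUPAC motif; with
`avoid_motif = TRUE` the background is rejection-sampled to be motif-free so
recovered counts can be compared against planted counts exactly.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10,000 genes for null
calibration, 1,000 for effect recovery, the default 2,000-gene / 32-sample
experiment for the end-to-end enrichment check, 100 × 10-kb sequences for
scanner/oracle equivalence, and 1,000–2,000 × 2-kb promoters for the
Monte-Carlo motif null — sizes at which every Monte-Carlo assertion has
comfortable margin while a full run stays in the tens of seconds. IRLS uses
a 1e-8 step tolerance with a 100-iteration cap; means are clamped to
[1e-10, 1e12] inside the solver; non-convergence is reported per gene, never
silently patched. The end-to-end enrichment check takes genes called
up-regulated in *at least one* line of a background (the ratio-sorted
heat-map population is the union of the background's DE genes; requiring
calls in both lines would condition away exactly the allele-dependent genes
whose sensitive-allele response sits below the twofold cutoff) and tests
planted `allele_dependent` vs `allele_independent` membership against the
≥2× ratio class with Fisher's exact test.

## Known limitations

* The DE engine's normal Wald p values are approximate at n = 4 per group;
  calibration is verified at the simulated settings, not guaranteed for
  extreme means or dispersions.
* The dispersion trend \(a_0 + a_1/\mu\) is a two-parameter convenience, not
  a flexible curve fit.
* `diff_proteins()` reports parameter-dependent alignment summaries; exact
  agreement with a hand-curated alignment may require adjusting the matrix
  or gap costs.
* Genome-scale motif prevalence on a real annotation depends on conventions
  (loci vs transcript models, strand handling) that the scanner exposes as
  options but cannot decide for you.
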