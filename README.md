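# nilswap

Analysis of **reciprocal near-isogenic-line (NIL) allele-swap RNA-seq
experiments**, built for the design used to dissect how the rice
aluminum-resistance transcription factor ART1 interacts with the genetic
background: two recurrent parents that differ at a mapped locus, the two
reciprocal NILs in which that locus has been swapped, and stress/control
profiling of all four genotypes (4 genotypes × 2 treatments × 4 replicates
= 32 samples).

The package is for quantitative geneticists and plant molecular biologists
who have such a design as a gene × sample count matrix and want to answer:
*which genes respond to stress, and how much of that response tracks the
swapped allele rather than the genetic background?*

## What it computes

**NB differential expression.** Counts are modeled as
K<sub>gj</sub> ~ NB(mean = s<sub>j</sub>·μ<sub>gj</sub>, Var = μ + αμ²) with
median-of-ratios size factors s<sub>j</sub>, a low-expression pre-filter
(gene kept iff its raw total ≥ overall mean normalized count / n samples),
method-of-moments dispersion estimation shrunk toward an a₀ + a₁/μ trend,
and per-genotype stress-vs-control Wald contrasts
(log μ = log s + β₀ + β₁·stress) with BH correction. DE calls require
|log2FC| ≥ 1, padj ≤ 0.05 and ≥ 8 normalized counts in at least one sample.

**Allele-responsiveness ratios.** For a gene with stress log2FC
`lfc_ref` in the line carrying the resistant-parent allele and `lfc_alt` in
the otherwise-isogenic line, it is *k-fold more allele-responsive* iff
2^(lfc_ref − lfc_alt) ≥ k (inclusive). `classify_table()` sorts genes by
Δlog2FC and counts the ≥2× and ≥1.5× classes; `venn_counts()`,
`magnitude_test()` (Welch t on fold-change sets) and `pca_top_variance()`
(top-500-variance genes of log₂(K/s+1)) give the set, magnitude and
ordination summaries; `rrg()` is the stress/control root-growth phenotype
ratio.

**Promoter motifs.** `extract_promoters()` builds the 2-kb-upstream-of-CDS
library from a genome FASTA + GFF3; `scan_counts()` counts overlapping
degenerate IUPAC motif hits (e.g. the ART1 element GGNVS; sequence `N`
never matches); `expected_hits()` is the analytic chance expectation
(L−m+1)·∏ₖ p(codeₖ) — 46.78 GGNVS hits per uniform 2-kb sequence, which is
why presence of such a short degenerate element is no regulatory evidence.

**Allele sequences.** `translate_cds()`, `apply_frameshift()` (single-base
deletion + 3'UTR read-through to the new stop; models a 465-aa factor
lengthened to 477 aa) and `diff_proteins()` (global BLOSUM62 alignment;
substitutions = mismatch columns, indel events = contiguous gap runs).

**Synthetic data.** `simulate_counts()` generates the full 32-sample design
with planted gene classes (null, allele-dependent, allele-independent,
background-specific, introgression-resident) and a ground-truth table;
`simulate_promoters()` plants motif instances in random backgrounds. Both
are seeded and bit-reproducible, and power every recovery test in the
package.

`run_full_pipeline()` chains everything (simulate/load → DE → comparisons →
PCA → motifs) from one YAML or list config into a directory of TSV/JSON
artifacts plus a manifest.

## Worked example

```r
library(nilswap)

sim  <- simulate_counts(sim_config(seed = 42))   # 2000 genes x 32 samples
sf   <- estimate_size_factors(sim$counts)
filt <- prefilter_low_expression(sim$counts, sf)
disp <- estimate_dispersions(filt$counts, sf, sim$design)
norm <- sweep(filt$counts, 2, sf, "/")

res_az  <- nb_wald_contrast(filt$counts, sf, disp, sim$design, "parentA")
res_nil <- nb_wald_contrast(filt$counts, sf, disp, sim$design, "nilA")
de_az   <- call_de_genes(res_az, norm)
de_nil  <- call_de_genes(res_nil, norm)
length(de_az$up); length(de_nil$up)
#> [1] 111
#> [1] 68

up_union <- union(de_az$up, de_nil$up)
ct <- classify_table(up_union,
                     res_az[up_union, "log2FoldChange"],
                     res_nil[up_union, "log2FoldChange"])
ct$counts
#> >=1.5x   >=2x
#>     58     54
head(ct$table, 3)
#>        gene  lfc_ref   lfc_alt    delta ratio_class
#> 1 gene01536 3.855947 0.3974355 3.458511        >=2x
#> 2 gene00354 5.227311 1.9949906 3.232321        >=2x
#> 3 gene01348 3.308420 0.2520004 3.056420        >=2x

magnitude_test(res_az[de_az$up, "log2FoldChange"],
               res_nil[de_nil$up, "log2FoldChange"])$p_value
#> [1] 7.56e-06
```

Read: in the parent carrying the resistant allele, 111 genes are
stress-induced versus 68 in the NIL carrying the sensitive allele; 54 of
the up-regulated genes respond at least twofold more strongly under the
resistant allele (the top rows show Δlog2FC ≈ 3, i.e. ~8-fold more
responsive), and the parent's up-set is globally more induced than the
NIL's (Welch p ≈ 8e-06) — the allele-swap signature the simulator plants
and the pipeline recovers.

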