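Package: nilswap
Title: Reciprocal NIL Allele-Swap Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reciprocal near-isogenic-line (NIL)
    allele-swap RNA-seq experiments, as used to dissect the contribution of
    the rice aluminum-resistance transcription factor ART1 to stress
    transcriptomes in two genetic backgrounds. Provides a negative-binomial
    differential-expression engine (median-of-ratios size factors, a
    normalized-mean low-expression pre-filter, method-of-moments dispersion
    estimation with a 1/mu trend and log-scale shrinkage, and vectorized
    Wald contrasts), allele-responsiveness ratio classification of paired
    parent/NIL fold changes, set overlap and fold-change magnitude
    summaries, top-variance PCA, degenerate IUPAC promoter-motif scanning
    with an analytic chance-expectation null, promoter extraction from
    genome FASTA plus GFF3 annotation, CDS translation with frameshift
    read-through reconstruction, protein substitution/indel counting, and a
    seeded synthetic-data generator that emulates the 4-genotype x
    2-treatment x 4-replicate design with planted gene classes for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
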