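#' @importFrom methods is
NULL

# IUPAC nucleotide code -> concrete base sets
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Validate an IUPAC motif pattern
#'
#' @param x character scalar over the 15 IUPAC nucleotide codes.
#' @return the validated upper-case pattern string.
#' @export
motif_pattern <- function(x) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop("motif must be a non-empty character scalar")
  x <- toupper(x)
  bad <- setdiff(strsplit(x, "")[[1]], names(.IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  x
}

#' Number of concrete words encoded by a degenerate motif
#'
#' The degeneracy is the product of per-position code-set sizes; e.g.
#' GGNVS encodes 1 x 1 x 4 x 3 x 2 = 24 concrete 5-mers.
#'
#' @param motif IUPAC motif string.
#' @return integer degeneracy.
#' @export
iupac_degeneracy <- function(motif) {
  motif <- motif_pattern(motif)
  prod(vapply(strsplit(motif, "")[[1]],
              function(ch) length(.IUPAC_SETS[[ch]]), numeric(1)))
}

#' Expand a degenerate motif to all concrete words
#'
#' @param motif IUPAC motif string.
#' @param max_words guard against combinatorial explosion.
#' @return character vector of all concrete expansions.
#' @export
expand_iupac <- function(motif, max_words = 1e6) {
  motif <- motif_pattern(motif)
  if (iupac_degeneracy(motif) > max_words)
    stop("motif expands to more than 'max_words' concrete words")
  sets <- lapply(strsplit(motif, "")[[1]], function(ch) .IUPAC_SETS[[ch]])
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)),
        1L, function(r) paste(rev(r), collapse = ""))
}

# promoter_library constructor shared by simulate_promoters / extract_promoters
new_promoter_library <- function(seq, info) {
  stopifnot(is(seq, "DNAStringSet"), nrow(info) == length(seq))
  structure(list(seq = seq, info = info), class = "promoter_library")
}

#' @export
print.promoter_library <- function(x, ...) {
  cat(sprintf("promoter_library with %d sequences (widths %s)\n",
              length(x$seq),
              if (length(x$seq)) paste(range(Biostrings::width(x$seq)),
                                       collapse = "-") else "NA"))
  invisible(x)
}

# 1-based start positions of degenerate-motif matches in one sequence string;
# hits whose window contains N are discarded (N never matches).
.match_iupac <- function(motif, seq) {
  subject <- Biostrings::DNAString(seq)
  if (nchar(motif) > length(subject)) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                   fixed = "subject")
  st <- BiocGenerics::start(hits)
  if (length(st) && grepl("N", seq, fixed = TRUE)) {
    win <- as.character(hits)
    st <- st[!grepl("N", win, fixed = TRUE)]
  }
  st
}

#' Scan a promoter library for a degenerate motif
#'
#' Counts every overlapping occurrence of an IUPAC motif at every offset of
#' each sequence. A sequence position containing \code{N} never matches any
#' motif position. With \code{strand_mode = "both"} the reverse complement of
#' each sequence is scanned as well and its hits added to the count.
#'
#' @param library a \code{promoter_library} (see [simulate_promoters()],
#'   [extract_promoters()]) or a [Biostrings::DNAStringSet].
#' @param motif IUPAC motif string.
#' @param strand_mode \code{"given"} (default: only the stored strand) or
#'   \code{"both"}.
#' @return data frame of class \code{"scan_result"} with one row per entry:
#'   \code{gene}, \code{n_hits}, and \code{positions} (list column of 1-based
#'   match start positions on the given strand).
#' @export
scan_counts <- function(library, motif, strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  motif <- motif_pattern(motif)
  if (is(library, "DNAStringSet"))
    library <- new_promoter_library(
      library, data.frame(gene = if (is.null(names(library)))
        sprintf("seq%04d", seq_along(library)) else names(library)))
  seqs <- as.character(library$seq)
  pos <- lapply(seqs, function(s) .match_iupac(motif, s))
  n <- lengths(pos)
  if (strand_mode == "both") {
    rc <- as.character(Biostrings::reverseComplement(library$seq))
    n <- n + lengths(lapply(rc, function(s) .match_iupac(motif, s)))
  }
  out <- data.frame(gene = library$info$gene, n_hits = as.integer(n),
                    stringsAsFactors = FALSE)
  out$positions <- pos
  class(out) <- c("scan_result", class(out))
  out
}

#' Summarize motif prevalence over a scanned library
#'
#' @param scan a \code{scan_result} from [scan_counts()].
#' @return list with \code{n_with_hit} (entries with at least one hit),
#'   \code{n_total}, and \code{mean_hits_per_sequence} (zero-hit entries
#'   included in the mean).
#' @export
prevalence_summary <- function(scan) {
  if (nrow(scan) == 0L) stop("empty scan result")
  list(n_with_hit = sum(scan$n_hits >= 1L),
       n_total = nrow(scan),
       mean_hits_per_sequence = mean(scan$n_hits))
}

#' Expected chance occurrences of a degenerate motif
#'
#' Analytic null expectation for a short degenerate motif in an i.i.d.
#' background: \eqn{E = (L - m + 1) \prod_k \sum_{b \in code_k} p_b},
#' doubled under both-strand scanning. Useful because short degenerate
#' elements occur by chance at high rates, which limits their value as
#' regulatory evidence.
#'
#' @param motif IUPAC motif string.
#' @param seq_length sequence length L; lengths below the motif length give 0.
#' @param base_freqs named frequencies for A, C, G, T summing to 1.
#' @param strand_mode \code{"given"} or \code{"both"}.
#' @return expected hit count (numeric).
#' @export
expected_hits <- function(motif, seq_length,
                          base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  motif <- motif_pattern(motif)
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base_freqs must sum to 1")
  if (!all(c("A", "C", "G", "T") %in% names(base_freqs)))
    stop("base_freqs must be named A, C, G, T")
  m <- nchar(motif)
  if (seq_length < m) return(0)
  p_match <- prod(vapply(strsplit(motif, "")[[1]],
                         function(ch) sum(base_freqs[.IUPAC_SETS[[ch]]]),
                         numeric(1)))
  e <- (seq_length - m + 1) * p_match
  if (strand_mode == "both") e <- 2 * e
  e
}

#' Extract putative regulatory regions upstream of CDS starts
#'
#' Builds a promoter library as the \code{length}-bp region immediately
#' upstream of the start codon (first CDS base) of each gene model: for a
#' plus-strand gene with 1-based CDS start p, the genomic interval
#' \code{[max(1, p - length), p - 1]}; for a minus-strand gene the reverse
#' complement of \code{[CDS end + 1, CDS end + length]}, clipped at contig
#' boundaries. Sequences are returned 5'->3' relative to the gene. Gene
#' models without CDS features are skipped with a warning.
#'
#' @param genome path to a FASTA file or a named [Biostrings::DNAStringSet].
#' @param annotation path to a GFF3 file or a [GenomicRanges::GRanges] of
#'   features including CDS rows with \code{Parent}/\code{ID} attributes.
#' @param length upstream window size in bp (default 2000).
#' @return A \code{promoter_library}; \code{info} records the 1-based
#'   inclusive genomic interval and the length actually extracted.
#' @export
extract_promoters <- function(genome, annotation, length = 2000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome))) stop("genome contigs must be named")
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  feats <- annotation
  type <- as.character(feats$type)
  cds <- feats[type == "CDS"]
  if (length(cds) == 0L) stop("annotation contains no CDS features")

  # map each CDS to its gene model: via Parent -> mRNA -> gene when present,
  # else the CDS Parent itself
  first_chr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  parent <- if (!is.null(cds$Parent)) first_chr(cds$Parent) else
    rep(NA_character_, length(cds))
  mrna <- feats[type %in% c("mRNA", "transcript")]
  mrna_parent <- if (length(mrna) && !is.null(mrna$Parent))
    stats::setNames(first_chr(mrna$Parent), as.character(mrna$ID)) else
    character(0)
  gene_of <- ifelse(!is.na(parent) & parent %in% names(mrna_parent),
                    unname(mrna_parent[parent]), parent)
  if (anyNA(gene_of)) stop("CDS features lack Parent attributes")

  genes <- feats[type == "gene"]
  gene_ids <- if (length(genes)) as.character(genes$ID) else unique(gene_of)
  skipped <- setdiff(gene_ids, gene_of)
  if (length(skipped))
    warning("skipping ", length(skipped),
            " gene model(s) without CDS: ", paste(skipped, collapse = ", "))
  gene_ids <- intersect(gene_ids, gene_of)

  rows <- lapply(gene_ids, function(g) {
    gc <- cds[gene_of == g]
    chr <- as.character(GenomicRanges::seqnames(gc))[1]
    if (!chr %in% names(genome))
      stop("contig '", chr, "' absent from genome FASTA")
    strand <- as.character(GenomicRanges::strand(gc))[1]
    clen <- length(genome[[chr]])
    if (strand == "-") {
      anchor <- max(BiocGenerics::end(gc))   # CDS start codon on - strand
      lo <- anchor + 1L
      hi <- min(clen, anchor + length)
    } else {
      anchor <- min(BiocGenerics::start(gc))
      lo <- max(1L, anchor - length)
      hi <- anchor - 1L
    }
    if (hi < lo) return(NULL)
    s <- Biostrings::subseq(genome[[chr]], lo, hi)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    list(gene = g, seq = as.character(s), seqname = chr,
         start = lo, end = hi, strand = strand, length = hi - lo + 1L)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no promoter sequences could be extracted")
  info <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r$gene, seqname = r$seqname, start = r$start,
               end = r$end, strand = r$strand, length = r$length,
               stringsAsFactors = FALSE)))
  ss <- Biostrings::DNAStringSet(vapply(rows, `[[`, character(1), "seq"))
  names(ss) <- info$gene
  new_promoter_library(ss, info)
}
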