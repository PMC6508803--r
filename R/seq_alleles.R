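#' Translate a coding sequence
#'
#' Standard-genetic-code translation of a CDS, up to and excluding the first
#' stop codon. In strict mode (default) the sequence must start with ATG,
#' have length divisible by 3, and contain no internal stop before the final
#' codon; a non-ATG start only warns.
#'
#' @param seq CDS as a character string or [Biostrings::DNAString].
#' @param strict enforce frame and internal-stop checks.
#' @return one-letter amino-acid string (no stop symbol).
#' @export
translate_cds <- function(seq, strict = TRUE) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (strict && n %% 3 != 0L)
    stop("CDS length is not divisible by 3")
  if (substr(seq, 1L, 3L) != "ATG")
    warning("CDS does not start with ATG")
  n_cod <- n %/% 3
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n_cod * 3L)),
    if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) return(aa)
  if (strict && stop_at < n_cod)
    stop("internal stop codon at codon ", stop_at)
  substr(aa, 1L, stop_at - 1L)
}

#' Reconstruct a frameshifted read-through protein
#'
#' Models a single-nucleotide deletion within a CDS: the base at
#' \code{del_pos} (1-based within the CDS) is removed, the downstream
#' genomic sequence (3'UTR) is appended so translation can read through the
#' original stop, and the result is translated from the start codon to the
#' first stop in the shifted frame. If no stop is reached an explicit error
#' is raised.
#'
#' @param cds wild-type CDS (character or [Biostrings::DNAString]).
#' @param del_pos 1-based position of the deleted nucleotide; must lie
#'   within the CDS.
#' @param downstream genomic sequence immediately 3' of the CDS.
#' @return the frameshifted protein as a one-letter amino-acid string.
#' @export
apply_frameshift <- function(cds, del_pos, downstream) {
  cds <- toupper(as.character(cds))
  downstream <- toupper(as.character(downstream))
  n <- nchar(cds)
  if (del_pos < 1 || del_pos > n)
    stop("deletion position ", del_pos, " lies outside the CDS (length ",
         n, ")")
  mutated <- paste0(substr(cds, 1L, del_pos - 1L),
                    substr(cds, del_pos + 1L, n), downstream)
  n_cod <- nchar(mutated) %/% 3
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mutated, 1L, n_cod * 3L)),
    if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L)
    stop("no stop codon reached in the shifted frame; ",
         "provide more downstream sequence")
  substr(aa, 1L, stop_at - 1L)
}

#' Count substitutions and indel events between two proteins
#'
#' Globally aligns two protein sequences (Needleman-Wunsch with affine gaps;
#' BLOSUM62 by default) and reports the number of aligned mismatch columns
#' and the number of indel events, where one event is a maximal contiguous
#' gap run in either sequence. Event counts are symmetric in the inputs.
#'
#' @param a,b protein sequences (character or [Biostrings::AAString]).
#' @param substitution_matrix matrix name (e.g. "BLOSUM62") or an actual
#'   scoring matrix.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return list with \code{n_substitutions}, \code{n_indel_events}, and the
#'   two aligned strings.
#' @export
diff_proteins <- function(a, b, substitution_matrix = "BLOSUM62",
                          gap_open = 10, gap_extend = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  if (is.character(substitution_matrix)) {
    env <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings",
                envir = env)
    substitution_matrix <- get(substitution_matrix, envir = env)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- al_a != "-" & al_b != "-"
  n_sub <- sum(both & al_a != al_b)
  gap_runs <- function(x) {
    r <- rle(x == "-")
    sum(r$values)
  }
  list(n_substitutions = n_sub,
       n_indel_events = gap_runs(al_a) + gap_runs(al_b),
       aligned_a = paste(al_a, collapse = ""),
       aligned_b = paste(al_b, collapse = ""))
}

#' Construct a synthetic wild-type / frameshift allele pair
#'
#' Builds a synthetic CDS of \code{n_aa} residues (ATG start, stop-free
#' body, terminal stop) together with a downstream 3'UTR engineered so that
#' deleting one nucleotide at \code{del_pos} shifts the frame and the
#' read-through protein terminates at exactly \code{target_aa} residues.
#' This mirrors the structure of a natural loss-of-function frameshift
#' allele (a 465-aa factor lengthened to 477 aa) without using any real
#' genomic sequence; it exists so the translation and frameshift machinery
#' can be exercised end-to-end on data generated in code.
#'
#' @param n_aa wild-type protein length (default 465).
#' @param target_aa frameshifted read-through protein length (default 477).
#' @param del_pos 1-based CDS position of the deleted base (default 317).
#' @return list with \code{cds}, \code{downstream}, \code{del_pos}, and the
#'   expected \code{wildtype_aa} / \code{frameshift_aa} lengths.
#' @export
synthetic_frameshift_fixture <- function(n_aa = 465, target_aa = 477,
                                         del_pos = 317) {
  if (target_aa * 3 + 3 <= n_aa * 3)
    stop("'target_aa' must extend beyond the wild-type CDS")
  # GCC repeats are stop-free in every reading frame (GCC/CCG/CGC)
  cds <- paste0("ATG", strrep("GCC", n_aa - 1), "TAA")
  if (del_pos < 1 || del_pos > nchar(cds))
    stop("'del_pos' outside the CDS")
  # after the 1-bp deletion the mutated CDS has 3*n_aa + 2 bases; the
  # read-through must consume target_aa codons before hitting a stop
  need_utr <- (target_aa + 1) * 3 - (nchar(cds) - 1)
  if (need_utr < 3) stop("'target_aa' too short for this CDS")
  downstream <- paste0(strrep("C", need_utr - 3), "TAA", strrep("C", 30))
  list(cds = cds, downstream = downstream, del_pos = del_pos,
       wildtype_aa = n_aa, frameshift_aa = target_aa)
}
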