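# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and libraries) they validate.

# naive O(m^2) Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, numeric(1))
    padj[i] <- min(1, min(cands))
  }
  padj
}

# exhaustive sliding-window IUPAC matcher built on plain character ops
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_match_positions <- function(motif, seq) {
  mchars <- strsplit(motif, "")[[1]]
  schars <- strsplit(seq, "")[[1]]
  m <- length(mchars); L <- length(schars)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (i in seq_len(m)) {
    allowed <- iupac_sets[[mchars[i]]]  # N in the sequence matches nothing
    ok <- ok & schars[seq_len(L - m + 1L) + i - 1L] %in% allowed
  }
  which(ok)
}

# codon-table translation written independently of Biostrings
oracle_translate <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq) - 2, by = 3),
                      seq(3, nchar(seq), by = 3))
  tab <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  aa <- unname(tab[codons])
  stop_at <- which(aa == "*")[1]
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

# small balanced two-group NB fixture for engine tests
make_two_group_counts <- function(n_genes, mu0, fold = 1, alpha = 0.05,
                                  n_per_group = 4, seed = 1) {
  set.seed(seed)
  mu <- cbind(matrix(mu0, n_genes, n_per_group),
              matrix(mu0 * fold, n_genes, n_per_group))
  k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
              n_genes, 2 * n_per_group)
  rownames(k) <- sprintf("g%05d", seq_len(n_genes))
  colnames(k) <- sprintf("s%02d", seq_len(ncol(k)))
  design <- data.frame(sample = colnames(k), genotype = "gA",
                       treatment = rep(c("control", "stress"),
                                       each = n_per_group))
  list(counts = k, design = design,
       sf = setNames(rep(1, ncol(k)), colnames(k)),
       alpha = setNames(rep(alpha, n_genes), rownames(k)))
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
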