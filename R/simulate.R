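#' Simulation configuration for an allele-swap NIL experiment
#'
#' Builds and validates the configuration for [simulate_counts()]. The default
#' design emulates a reciprocal allele-swap experiment: two recurrent parents
#' and two reciprocal near-isogenic lines (NILs), each grown under control and
#' stress conditions with four biological replicates, i.e. 4 genotypes x
#' 2 treatments x 4 replicates = 32 samples.
#'
#' Genotype labels encode the allele-swap structure:
#' \describe{
#'   \item{parentA}{recurrent parent A (resistant allele, background A)}
#'   \item{nilA}{NIL in background A carrying the sensitive allele}
#'   \item{parentB}{recurrent parent B (sensitive allele, background B)}
#'   \item{nilB}{NIL in background B carrying the resistant allele}
#' }
#' So the resistant allele is carried by \code{parentA} and \code{nilB}, and
#' background B is \code{parentB} plus \code{nilB}.
#'
#' Planted gene classes:
#' \describe{
#'   \item{null}{no effect anywhere.}
#'   \item{allele_dependent}{stress response whose magnitude depends on the
#'     allele: log2FC \code{effect_log2fc["allele_dependent_ref"]} in
#'     resistant-allele genotypes and \code{effect_log2fc["allele_dependent_alt"]}
#'     in sensitive-allele genotypes. Defaults (2.7 vs 0.8) are modeled on the
#'     fold changes printed for the twofold-or-higher allele-responsive genes.}
#'   \item{allele_independent}{identical stress response in all genotypes.}
#'   \item{background_specific}{stress response only in background B.}
#'   \item{introgression_effect}{constitutive (treatment-independent) baseline
#'     shift in genotypes carrying the resistant-allele haplotype, mimicking
#'     genes resident in the introgressed segment.}
#' }
#' Each non-null gene is assigned a random sign so that both up- and
#' down-regulation are represented.
#'
#' @param n_genes number of genes.
#' @param design data frame with columns \code{genotype}, \code{treatment},
#'   \code{n_replicates}; defaults to the full 4 x 2 x 4 design.
#' @param class_fractions named proportions over the five gene classes;
#'   must sum to 1.
#' @param effect_log2fc named effect sizes (log2 units), see Details.
#' @param dispersion_trend numeric \code{c(a0, a1)}: per-gene dispersion is
#'   \code{alpha = a0 + a1 / mu} (DESeq-style \code{Var = mu + alpha * mu^2}).
#' @param lib_size_range multiplicative range for per-sample depth factors,
#'   drawn log-uniformly.
#' @param mu_meanlog,mu_sdlog log-normal parameters for baseline means.
#' @param n_replicates replicate count used when building the default design.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000,
                       design = NULL,
                       class_fractions = c(null = 0.80,
                                           allele_dependent = 0.05,
                                           allele_independent = 0.05,
                                           background_specific = 0.05,
                                           introgression_effect = 0.05),
                       effect_log2fc = c(allele_dependent_ref = 2.7,
                                         allele_dependent_alt = 0.8,
                                         allele_independent = 2.0,
                                         background_specific = 2.0,
                                         introgression_effect = 1.5),
                       dispersion_trend = c(a0 = 0.01, a1 = 2),
                       lib_size_range = c(0.5, 2),
                       mu_meanlog = 4, mu_sdlog = 1.5,
                       n_replicates = 4,
                       seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("'n_genes' must be a positive integer")
  if (is.null(design)) {
    design <- expand.grid(genotype = c("parentA", "nilA", "parentB", "nilB"),
                          treatment = c("control", "stress"),
                          stringsAsFactors = FALSE)
    design$n_replicates <- n_replicates
  }
  req <- c("genotype", "treatment", "n_replicates")
  if (!all(req %in% names(design)))
    stop("'design' needs columns genotype, treatment, n_replicates")
  if (nrow(design) == 0L) stop("empty design")
  if (any(design$n_replicates < 2))
    stop("each design cell needs n_replicates >= 2")
  if (!all(design$treatment %in% c("control", "stress")))
    stop("treatment must be 'control' or 'stress'")
  classes <- c("null", "allele_dependent", "allele_independent",
               "background_specific", "introgression_effect")
  if (!setequal(names(class_fractions), classes))
    stop("class_fractions must be named over the five gene classes")
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (!all(is.finite(effect_log2fc))) stop("effect sizes must be finite")
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    stop("'lib_size_range' must be an increasing positive pair")
  structure(list(n_genes = as.integer(n_genes), design = design,
                 class_fractions = class_fractions,
                 effect_log2fc = effect_log2fc,
                 dispersion_trend = dispersion_trend,
                 lib_size_range = lib_size_range,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 seed = seed),
            class = "sim_config")
}

# genotype -> allele / background indicator helpers
.resistant_allele_genotypes <- c("parentA", "nilB")
.background_b_genotypes <- c("parentB", "nilB")

#' Simulate an allele-swap NIL count matrix with ground truth
#'
#' Draws negative-binomial counts \eqn{K_{gj} \sim NB(mean = s_j \mu_g
#' 2^{x_j \beta_g}, dispersion = \alpha_g)} under the planted gene-class
#' structure described in [sim_config()], where \eqn{s_j} is the sample depth
#' factor and \eqn{x_j} the design covariates. Identical configurations
#' (including \code{seed}) give bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with components
#'   \item{counts}{integer matrix, genes x samples;}
#'   \item{design}{per-sample data frame (sample, genotype, treatment,
#'     replicate, true depth factor);}
#'   \item{truth}{per-gene data frame: class, baseline mean \code{mu},
#'     dispersion \code{alpha}, and the true stress log2FC per genotype
#'     (columns \code{lfc_<genotype>}) plus the constitutive baseline
#'     log2 offset per genotype group.}
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)

  des <- config$design
  samples <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    data.frame(genotype = des$genotype[i], treatment = des$treatment[i],
               replicate = seq_len(des$n_replicates[i]),
               stringsAsFactors = FALSE)
  }))
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype,
                            samples$treatment, samples$replicate)
  n_samp <- nrow(samples)
  G <- config$n_genes
  genotypes <- unique(samples$genotype)

  # per-sample depth factors, log-uniform over lib_size_range
  lr <- log(config$lib_size_range)
  s <- exp(stats::runif(n_samp, lr[1], lr[2]))

  # gene classes, means, dispersions
  cls <- sample(names(config$class_fractions), G, replace = TRUE,
                prob = config$class_fractions)
  mu <- stats::rlnorm(G, meanlog = config$mu_meanlog, sdlog = config$mu_sdlog)
  a <- config$dispersion_trend
  alpha <- pmax(a[[1]] + a[[2]] / mu, 1e-8)
  sgn <- sample(c(-1, 1), G, replace = TRUE)
  eff <- config$effect_log2fc

  # true stress log2FC per genotype and constitutive genotype offset
  lfc <- matrix(0, G, length(genotypes), dimnames = list(NULL, genotypes))
  offset <- matrix(0, G, length(genotypes), dimnames = list(NULL, genotypes))
  res_g <- intersect(genotypes, .resistant_allele_genotypes)
  alt_g <- setdiff(genotypes, .resistant_allele_genotypes)
  bgB_g <- intersect(genotypes, .background_b_genotypes)
  i <- cls == "allele_dependent"
  lfc[i, res_g] <- sgn[i] * eff[["allele_dependent_ref"]]
  lfc[i, alt_g] <- sgn[i] * eff[["allele_dependent_alt"]]
  i <- cls == "allele_independent"
  lfc[i, ] <- sgn[i] * eff[["allele_independent"]]
  i <- cls == "background_specific"
  lfc[i, bgB_g] <- sgn[i] * eff[["background_specific"]]
  i <- cls == "introgression_effect"
  offset[i, res_g] <- sgn[i] * eff[["introgression_effect"]]

  gene_ids <- sprintf("gene%05d", seq_len(G))
  stress <- as.numeric(samples$treatment == "stress")
  counts <- matrix(0L, G, n_samp, dimnames = list(gene_ids, samples$sample))
  for (j in seq_len(n_samp)) {
    gcol <- samples$genotype[j]
    m <- s[j] * mu * 2^(offset[, gcol] + stress[j] * lfc[, gcol])
    counts[, j] <- stats::rnbinom(G, mu = m, size = 1 / alpha)
  }

  truth <- data.frame(gene = gene_ids, class = cls, mu = mu, alpha = alpha,
                      stringsAsFactors = FALSE)
  for (gcol in genotypes) truth[[paste0("lfc_", gcol)]] <- lfc[, gcol]
  for (gcol in genotypes) truth[[paste0("offset_", gcol)]] <- offset[, gcol]
  samples$depth_factor <- s
  list(counts = counts,
       design = samples[, c("sample", "genotype", "treatment",
                            "replicate", "depth_factor")],
       truth = truth)
}

#' Simulate a promoter library, optionally with planted motif instances
#'
#' Generates i.i.d. random sequences with P(G) = P(C) = \code{gc}/2 and plants
#' \code{planted_count} concrete expansions of an IUPAC motif at
#' non-overlapping random positions of each sequence. With
#' \code{avoid_motif = TRUE} the background is re-drawn (rejection sampling)
#' until it contains no motif match before planting, so recovered counts can
#' be compared to planted counts exactly.
#'
#' @param n_seqs number of sequences (0 gives an empty library).
#' @param length sequence length (bases).
#' @param gc GC fraction in (0, 1).
#' @param planted_motif IUPAC motif string, or \code{NULL} for none.
#' @param planted_count motif instances planted per sequence.
#' @param avoid_motif logical; reject backgrounds already containing the motif.
#' @param seed integer seed or \code{NULL}.
#' @return A \code{promoter_library}: list with \code{seq}
#'   (a [Biostrings::DNAStringSet]) and \code{info} (per-entry data frame).
#' @export
simulate_promoters <- function(n_seqs, length, gc = 0.5,
                               planted_motif = NULL, planted_count = 0,
                               avoid_motif = FALSE, seed = NULL) {
  if (gc <= 0 || gc >= 1) stop("'gc' must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  if (n_seqs == 0) {
    return(new_promoter_library(Biostrings::DNAStringSet(),
                                data.frame(gene = character(0),
                                           length = integer(0))))
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m_len <- 0L
  if (!is.null(planted_motif)) {
    planted_motif <- motif_pattern(planted_motif)
    m_len <- nchar(planted_motif)
    if (planted_count * m_len > length)
      stop("planted motif instances do not fit in the sequence length")
  }
  draw_bg <- function() {
    repeat {
      x <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
                 collapse = "")
      if (!avoid_motif || is.null(planted_motif) ||
          length(.match_iupac(planted_motif, x)) == 0L)
        return(x)
    }
  }
  seqs <- vapply(seq_len(n_seqs), function(i) {
    x <- draw_bg()
    if (!is.null(planted_motif) && planted_count > 0) {
      # non-overlapping slots: sample start positions until disjoint
      repeat {
        st <- sort(sample.int(length - m_len + 1L, planted_count))
        if (planted_count == 1L || all(diff(st) >= m_len)) break
      }
      for (p in st) {
        word <- .sample_iupac_word(planted_motif)
        substr(x, p, p + m_len - 1L) <- word
      }
    }
    x
  }, character(1))
  ids <- sprintf("promoter%04d", seq_len(n_seqs))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  new_promoter_library(ss, data.frame(gene = ids, length = length,
                                      stringsAsFactors = FALSE))
}

# one uniformly-chosen concrete expansion of an IUPAC pattern
.sample_iupac_word <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]],
               function(ch) sample(.IUPAC_SETS[[ch]], 1L), character(1)),
        collapse = "")
}
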