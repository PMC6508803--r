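#' Differential-expression calling criteria
#'
#' The three-part rule used to call Al-responsive genes: at least a twofold
#' change (|log2FC| >= 1), adjusted p value at most 0.05, and at least eight
#' normalized counts in at least one sample.
#'
#' @param min_abs_log2fc minimum |log2 fold change| (default 1).
#' @param max_padj maximum BH-adjusted p value (default 0.05).
#' @param min_count_one_sample minimum normalized count required in at least
#'   one sample (default 8).
#' @return list of class \code{"de_criteria"}.
#' @export
de_criteria <- function(min_abs_log2fc = 1, max_padj = 0.05,
                        min_count_one_sample = 8) {
  if (min_abs_log2fc <= 0 || max_padj <= 0 || min_count_one_sample <= 0)
    stop("criteria thresholds must be positive")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_padj = max_padj,
                 min_count_one_sample = min_count_one_sample),
            class = "de_criteria")
}

#' Call differentially expressed genes from a contrast result
#'
#' @param result a \code{contrast_result} from [nb_wald_contrast()].
#' @param norm_counts normalized count matrix (counts divided by size
#'   factors) covering all tested genes.
#' @param criteria a [de_criteria()] object.
#' @return list of class \code{"de_gene_set"}: \code{up} and \code{down}
#'   gene-id vectors (disjoint), plus the criteria used.
#' @export
call_de_genes <- function(result, norm_counts, criteria = de_criteria()) {
  if (is.null(result$padj)) stop("contrast result lacks a 'padj' column")
  genes <- result$gene
  missing <- setdiff(genes, rownames(norm_counts))
  if (length(missing)) stop("normalized counts missing for tested genes")
  max_norm <- apply(norm_counts[genes, , drop = FALSE], 1, max)
  expressed <- max_norm >= criteria$min_count_one_sample
  sig <- !is.na(result$padj) & result$padj <= criteria$max_padj & expressed
  up <- genes[sig & result$log2FoldChange >= criteria$min_abs_log2fc]
  down <- genes[sig & result$log2FoldChange <= -criteria$min_abs_log2fc]
  structure(list(up = up, down = down, criteria = criteria),
            class = "de_gene_set")
}

#' Allele-responsiveness ratio test
#'
#' A gene is "fold_threshold-times more responsive" under the reference
#' allele when the linear ratio of its fold changes meets the threshold:
#' \eqn{2^{lfc_{ref} - lfc_{alt}} \ge threshold}, i.e.
#' \eqn{lfc_{ref} - lfc_{alt} \ge \log_2(threshold)}, inclusive.
#'
#' @param lfc_ref log2FC in the line carrying the reference (resistant)
#'   allele.
#' @param lfc_alt log2FC in the line carrying the alternative allele.
#' @param fold_threshold linear fold-ratio threshold, > 1 (e.g. 2 or 1.5).
#' @return logical (vectorized over the inputs).
#' @export
ratio_classify <- function(lfc_ref, lfc_alt, fold_threshold) {
  if (any(fold_threshold <= 1)) stop("fold_threshold must exceed 1")
  if (any(!is.finite(lfc_ref)) || any(!is.finite(lfc_alt)))
    stop("fold changes must be finite")
  (lfc_ref - lfc_alt) >= log2(fold_threshold)
}

#' Classify paired parent/NIL fold changes by allele-responsiveness ratio
#'
#' Sorts genes by descending \eqn{\Delta = lfc_{ref} - lfc_{alt}} and labels
#' each row by the strongest threshold it passes, reproducing the
#' ratio-sorted heat-map ordering with its >= 2x and >= 1.5x brackets.
#'
#' @param genes gene ids.
#' @param lfc_ref,lfc_alt paired log2 fold changes (reference-allele line
#'   and alternative-allele line).
#' @param thresholds increasing fold thresholds (default \code{c(1.5, 2)}).
#' @return list with \code{table} (sorted data frame: gene, lfc_ref,
#'   lfc_alt, delta, ratio_class) and \code{counts} (named pass counts per
#'   threshold; nested, so every >= 2x gene also counts as >= 1.5x).
#' @export
classify_table <- function(genes, lfc_ref, lfc_alt, thresholds = c(1.5, 2)) {
  stopifnot(length(genes) == length(lfc_ref),
            length(lfc_ref) == length(lfc_alt))
  thresholds <- sort(thresholds)
  if (length(genes) == 0L) {
    counts <- stats::setNames(rep(0L, length(thresholds)),
                              sprintf(">=%gx", thresholds))
    return(list(table = data.frame(gene = character(0), lfc_ref = numeric(0),
                                   lfc_alt = numeric(0), delta = numeric(0),
                                   ratio_class = character(0)),
                counts = counts))
  }
  delta <- lfc_ref - lfc_alt
  pass <- vapply(thresholds, function(th) ratio_classify(lfc_ref, lfc_alt, th),
                 logical(length(genes)))
  pass <- matrix(pass, ncol = length(thresholds))
  labs <- sprintf(">=%gx", thresholds)
  cls <- rep(sprintf("<%gx", thresholds[1]), length(genes))
  for (i in seq_along(thresholds)) cls[pass[, i]] <- labs[i]
  ord <- order(delta, decreasing = TRUE)
  tab <- data.frame(gene = genes, lfc_ref = lfc_ref, lfc_alt = lfc_alt,
                    delta = delta, ratio_class = cls,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  list(table = tab, counts = stats::setNames(colSums(pass), labs))
}

#' Two-set Venn partition counts
#'
#' @param set_a,set_b gene-id vectors (duplicates ignored).
#' @return list with \code{only_a}, \code{shared}, \code{only_b}.
#' @export
venn_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- length(intersect(set_a, set_b))
  list(only_a = length(set_a) - shared, shared = shared,
       only_b = length(set_b) - shared)
}

#' Depth-normalized log2 transform
#'
#' \eqn{\log_2(K_{gj}/s_j + 1)}: a monotone, variance-compressing transform
#' of the normalized counts used for heat maps and PCA.
#'
#' @param counts genes x samples count matrix.
#' @param sf positive size factors.
#' @return transformed matrix of the same shape.
#' @export
transform_counts <- function(counts, sf) {
  if (any(sf <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' PCA on the top-variance genes
#'
#' Ranks genes by row variance of the transformed matrix, keeps the
#' \code{n_top} most variable, centers each gene (no scaling), and computes
#' principal components of the samples.
#'
#' @param x transformed matrix (genes x samples), e.g. from
#'   [transform_counts()].
#' @param n_top number of top-variance genes to use (default 500; capped at
#'   the number of genes available).
#' @return list with \code{scores} (samples x PCs), \code{prop_var}
#'   (proportion of variance per PC, summing to 1), and \code{genes} (ids of
#'   the genes used, in decreasing variance order).
#' @export
pca_top_variance <- function(x, n_top = 500) {
  if (ncol(x) < 2) stop("PCA needs at least two samples")
  if (n_top > nrow(x)) stop("'n_top' exceeds the number of genes")
  rv <- apply(x, 1, stats::var)
  top <- order(rv, decreasing = TRUE)[seq_len(n_top)]
  pc <- stats::prcomp(t(x[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, prop_var = prop,
       genes = rownames(x)[top])
}

#' Compare fold-change magnitudes between two gene sets
#'
#' Welch's two-sample t test (default) on the log2 fold changes of two DE
#' gene sets, used to ask whether one line's response is globally stronger.
#' A Mann-Whitney (Wilcoxon rank-sum) alternative is available.
#'
#' @param lfc_set_a,lfc_set_b numeric log2FC vectors, each of length >= 2.
#' @param method \code{"welch"} (default) or \code{"wilcoxon"}.
#' @return list with \code{statistic} and two-sided \code{p_value}.
#' @export
magnitude_test <- function(lfc_set_a, lfc_set_b,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(lfc_set_a) < 2 || length(lfc_set_b) < 2)
    stop("each set needs at least two values")
  if (identical(sort(lfc_set_a), sort(lfc_set_b)) &&
      stats::sd(lfc_set_a) == 0 && stats::sd(lfc_set_b) == 0)
    return(list(statistic = 0, p_value = 1))
  tt <- if (method == "welch")
    stats::t.test(lfc_set_a, lfc_set_b, var.equal = FALSE) else
    stats::wilcox.test(lfc_set_a, lfc_set_b, exact = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Relative root growth
#'
#' The Al-resistance phenotype index: total root growth under stress divided
#' by total root growth under control conditions.
#'
#' @param trg_stress mean total root growth under stress.
#' @param trg_control mean total root growth under control; must be positive.
#' @return the ratio (vectorized).
#' @export
rrg <- function(trg_stress, trg_control) {
  if (any(trg_control <= 0)) stop("control root growth must be positive")
  trg_stress / trg_control
}
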