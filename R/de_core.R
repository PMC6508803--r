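#' Median-of-ratios size factors
#'
#' Per-sample depth factors \eqn{s_j} computed by the median-of-ratios
#' convention: the median over reference genes of \eqn{K_{gj} / g_g}, where
#' \eqn{g_g} is the geometric mean of gene g across samples and the reference
#' genes are those with all counts positive.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- .check_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has nonzero counts in every sample")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Remove low-expression genes by the normalized-mean total-count rule
#'
#' A gene is retained iff its total raw count across samples is at least
#' \eqn{T = \bar{K} / n}, where \eqn{\bar{K}} is the overall mean of the
#' normalized counts \eqn{K_{gj}/s_j} over all genes and samples and n the
#' number of samples; genes strictly below T are eliminated.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors from [estimate_size_factors()].
#' @return list with \code{counts} (the filtered matrix), \code{threshold},
#'   \code{kept} and \code{removed} gene-id vectors.
#' @export
prefilter_low_expression <- function(counts, sf) {
  counts <- .check_counts(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  norm <- sweep(counts, 2, sf, "/")
  threshold <- mean(norm) / ncol(counts)
  keep <- rowSums(counts) >= threshold
  list(counts = counts[keep, , drop = FALSE], threshold = threshold,
       kept = rownames(counts)[keep], removed = rownames(counts)[!keep])
}

#' Method-of-moments dispersion estimation with a 1/mu trend
#'
#' Gene-wise dispersions are estimated from within-cell (genotype x treatment)
#' variability of normalized counts: \eqn{\hat\alpha_g = \max(0, (s^2 -
#' \bar\mu) / \bar\mu^2)} with the within-cell variance pooled over cells
#' having at least two replicates. A mean-dispersion trend \eqn{\alpha(\mu) =
#' a_0 + a_1/\mu} is fitted by least squares to the gene-wise values, and the
#' final dispersion shrinks \eqn{\log\hat\alpha} toward the trend:
#' \eqn{\alpha^* = \exp(w \log\hat\alpha + (1-w)\log\alpha_{tr})}, floored at
#' 1e-8.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors.
#' @param design per-sample data frame with \code{genotype} and
#'   \code{treatment} columns, rows aligned to \code{colnames(counts)}.
#' @param shrink_weight weight w on the gene-wise estimate (default 0.5).
#' @return data frame with per-gene \code{mu} (mean normalized count),
#'   \code{gene_wise}, \code{trend} and \code{final} dispersions.
#' @export
estimate_dispersions <- function(counts, sf, design, shrink_weight = 0.5) {
  counts <- .check_counts(counts)
  design <- .check_design(design, counts)
  cell <- interaction(design$genotype, design$treatment, drop = TRUE)
  reps <- table(cell)
  use_cells <- names(reps)[reps >= 2]
  if (!length(use_cells))
    stop("dispersion estimation needs >= 2 replicates in at least one cell")
  norm <- sweep(counts, 2, sf, "/")

  num <- 0; dfree <- 0; musum <- 0; muw <- 0
  for (cl in use_cells) {
    idx <- which(cell == cl)
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (length(idx) - 1)
    num <- num + v * (length(idx) - 1)
    dfree <- dfree + (length(idx) - 1)
    musum <- musum + m * length(idx)
    muw <- muw + length(idx)
  }
  pooled_var <- num / dfree
  mu_bar <- musum / muw
  gene_wise <- ifelse(mu_bar > 0,
                      pmax(0, (pooled_var - mu_bar) / mu_bar^2), 0)

  # trend fit on genes with informative gene-wise estimates
  ok <- gene_wise > 0 & mu_bar > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(gene_wise[ok] ~ I(1 / mu_bar[ok]))
    a0 <- max(stats::coef(fit)[1], 1e-8)
    a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- max(mean(gene_wise), 1e-8); a1 <- 0
  }
  trend <- pmax(a0 + a1 / pmax(mu_bar, 1e-8), 1e-8)
  final <- exp(shrink_weight * log(pmax(gene_wise, 1e-8)) +
               (1 - shrink_weight) * log(trend))
  data.frame(gene = rownames(counts), mu = mu_bar, gene_wise = gene_wise,
             trend = trend, final = pmax(final, 1e-8),
             row.names = rownames(counts), stringsAsFactors = FALSE)
}

#' Negative-binomial Wald contrast for stress vs control within a genotype
#'
#' Fits, per gene, the NB log-link model \eqn{\log \mu_{gj} = \log s_j +
#' \beta_0 + \beta_1 x_j} (x = 1 for stress samples) over the named
#' genotype's samples, with the per-gene dispersion held fixed at the final
#' value from [estimate_dispersions()]. Fitting is iteratively reweighted
#' least squares, vectorized across genes. The reported log2 fold change is
#' \eqn{\hat\beta_1/\ln 2}, the standard error comes from the Fisher
#' information of the weighted design, the Wald p value is two-sided normal,
#' and padj is Benjamini-Hochberg over the tested genes. Genes with all-zero
#' counts in the contrast, or that fail to converge, are flagged with NA
#' statistics and excluded from the BH denominator.
#'
#' @param counts genes x samples count matrix (typically pre-filtered).
#' @param sf size factors.
#' @param disp dispersion table from [estimate_dispersions()], or a numeric
#'   vector of known per-gene dispersions aligned to \code{rownames(counts)}.
#' @param design per-sample design data frame.
#' @param genotype genotype label naming the contrast
#'   (stress vs control within that genotype).
#' @param max_iter,tol IRLS controls.
#' @return data frame of class \code{"contrast_result"} with columns
#'   \code{gene}, \code{baseMean}, \code{log2FoldChange}, \code{lfcSE},
#'   \code{stat}, \code{pvalue}, \code{padj}, \code{converged}.
#' @export
nb_wald_contrast <- function(counts, sf, disp, design, genotype,
                             max_iter = 100L, tol = 1e-8) {
  counts <- .check_counts(counts)
  design <- .check_design(design, counts)
  if (!genotype %in% design$genotype)
    stop("genotype '", genotype, "' not present in the design")
  idx <- which(design$genotype == genotype)
  trt <- design$treatment[idx]
  if (!all(c("control", "stress") %in% trt))
    stop("genotype '", genotype, "' lacks both treatments")
  alpha <- if (is.data.frame(disp)) {
    stats::setNames(disp$final, rownames(disp))[rownames(counts)]
  } else disp[rownames(counts)]
  if (anyNA(alpha)) stop("dispersions missing for some genes")

  k <- counts[, idx, drop = FALSE]
  s <- sf[idx]
  x <- as.numeric(trt == "stress")
  o <- matrix(log(s), nrow(k), length(s), byrow = TRUE)
  fit <- .nb_irls_two_group(k, o, x, alpha, max_iter = max_iter, tol = tol)

  base_mean <- rowMeans(sweep(k, 2, s, "/"))
  testable <- rowSums(k) > 0 & fit$converged & is.finite(fit$b1) &
    is.finite(fit$se)
  log2fc <- ifelse(testable, fit$b1 / log(2), NA_real_)
  lfcse <- ifelse(testable, fit$se / log(2), NA_real_)
  stat <- ifelse(testable, fit$b1 / fit$se, NA_real_)
  pval <- ifelse(testable, 2 * stats::pnorm(-abs(stat)), NA_real_)
  padj <- rep(NA_real_, length(pval))
  padj[testable] <- bh_adjust(pval[testable])
  out <- data.frame(gene = rownames(counts), baseMean = base_mean,
                    log2FoldChange = log2fc, lfcSE = lfcse, stat = stat,
                    pvalue = pval, padj = padj,
                    converged = fit$converged & rowSums(k) > 0,
                    row.names = rownames(counts), stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(genotype = genotype,
                             test = "stress_vs_control")
  class(out) <- c("contrast_result", class(out))
  out
}

# Vectorized IRLS for the per-gene model log mu = offset + b0 + b1*x with
# fixed NB dispersion (Var = mu + alpha*mu^2).  k: G x n counts, o: G x n
# offsets, x: length-n covariate, alpha: length-G dispersions.
.nb_irls_two_group <- function(k, o, x, alpha, max_iter = 100L, tol = 1e-8) {
  G <- nrow(k); n <- ncol(k)
  xm <- matrix(x, G, n, byrow = TRUE)
  # initial values from group means of offset-corrected counts
  kn <- k / exp(o)
  m0 <- rowMeans(kn[, x == 0, drop = FALSE])
  m1 <- rowMeans(kn[, x == 1, drop = FALSE])
  b0 <- log(pmax(m0, 0.1))
  b1 <- log(pmax(m1, 0.1)) - b0
  converged <- rep(FALSE, G)
  active <- rep(TRUE, G)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- o + b0 + b1 * xm
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - o) + (k - mu) / mu
    A <- rowSums(w); B <- rowSums(w * xm); C <- rowSums(w * xm^2)
    D <- rowSums(w * z); E <- rowSums(w * xm * z)
    det <- A * C - B^2
    det[det <= 0 | !is.finite(det)] <- NA_real_
    nb0 <- (C * D - B * E) / det
    nb1 <- (A * E - B * D) / det
    step_ok <- is.finite(nb0) & is.finite(nb1)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    upd <- active & step_ok
    b0[upd] <- nb0[upd]; b1[upd] <- nb1[upd]
    newly <- upd & delta < tol
    converged[newly] <- TRUE
    active <- active & step_ok & !newly
  }
  # Fisher-information SE of b1 at the final fit
  eta <- o + b0 + b1 * xm
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w <- mu / (1 + alpha * mu)
  A <- rowSums(w); B <- rowSums(w * xm); C <- rowSums(w * xm^2)
  det <- A * C - B^2
  se <- sqrt(ifelse(det > 0, A / det, NA_real_))
  list(b0 = b0, b1 = b1, se = se, converged = converged)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input; NA entries are excluded from ranking and
#' returned as NA.
#'
#' @param pvalues numeric vector of p values in \[0, 1\] (NAs allowed).
#' @return adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

.check_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

.check_design <- function(design, counts) {
  if (!all(c("genotype", "treatment") %in% names(design)))
    stop("design needs 'genotype' and 'treatment' columns")
  if (nrow(design) != ncol(counts))
    stop("design must have one row per sample")
  if (!is.null(design$sample) && !is.null(colnames(counts))) {
    if (!all(design$sample == colnames(counts))) {
      if (!setequal(design$sample, colnames(counts)))
        stop("design samples do not match count matrix columns")
      design <- design[match(colnames(counts), design$sample), ]
    }
  }
  design
}
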