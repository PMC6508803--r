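test_that("size factors follow the median-of-ratios formula", {
  # identical samples
  k <- matrix(c(5, 9, 3, 5, 9, 3), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(k)), c(1, 1))

  # scaling equivariance: sample 2 = 2 x sample 1
  k2 <- cbind(a = c(2, 8, 2), b = c(4, 16, 4))
  rownames(k2) <- paste0("g", 1:3)
  sf <- estimate_size_factors(k2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # hand-computed oracle for [[2,4],[8,16],[2,8]]:
  # geometric means (sqrt(8), sqrt(128), 4); per-sample ratio medians are
  # 1/sqrt(2) and sqrt(2)
  k3 <- cbind(a = c(2, 8, 2), b = c(4, 16, 8))
  rownames(k3) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(k3)),
               c(1 / sqrt(2), sqrt(2)))

  # error when no gene covers every sample
  k4 <- cbind(a = c(0, 3), b = c(2, 0))
  rownames(k4) <- paste0("g", 1:2)
  expect_error(estimate_size_factors(k4), "nonzero")
})

test_that("size factors permute with the samples", {
  set.seed(2)
  k <- matrix(rnbinom(200, mu = 50, size = 5), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  sf <- estimate_size_factors(k)
  perm <- sample(10)
  expect_equal(unname(estimate_size_factors(k[, perm])), unname(sf[perm]))
})

test_that("the low-expression pre-filter applies the normalized-mean rule", {
  k <- rbind(g1 = c(0, 0), g2 = c(1, 1), g3 = c(100, 100), g4 = c(3, 1))
  colnames(k) <- c("a", "b")
  sf <- c(a = 1, b = 1)
  filt <- prefilter_low_expression(k, sf)
  # T = (206/8)/2 = 12.875; only gene 3 has total >= T
  expect_equal(filt$threshold, 12.875)
  expect_equal(filt$kept, "g3")
  expect_equal(sort(filt$removed), c("g1", "g2", "g4"))

  # all-zero genes are always removed when T > 0
  expect_false("g1" %in% filt$kept)

  # boundary is inclusive: single gene, single sample, total == T
  k1 <- matrix(7L, 1, 1, dimnames = list("g1", "a"))
  f1 <- prefilter_low_expression(k1, c(a = 1))
  expect_equal(f1$threshold, 7)
  expect_equal(f1$kept, "g1")
})

test_that("normalized means are invariant to global count rescaling", {
  set.seed(3)
  k <- matrix(rnbinom(300, mu = 80, size = 5), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  sf1 <- estimate_size_factors(k)
  sf3 <- estimate_size_factors(k * 3L)
  expect_equal(rowMeans(sweep(k, 2, sf1, "/")) * 3,
               rowMeans(sweep(k * 3L, 2, sf3, "/")))
})

test_that("dispersion estimation recovers the Poisson and NB regimes", {
  des <- function(n) data.frame(sample = sprintf("s%02d", 1:(2 * n)),
                                genotype = "gA",
                                treatment = rep(c("control", "stress"),
                                                each = n))
  # Poisson counts: median final dispersion collapses toward zero
  set.seed(4)
  kp <- matrix(rpois(2000 * 40, 100), 2000, 40,
               dimnames = list(sprintf("g%04d", 1:2000),
                               sprintf("s%02d", 1:40)))
  dp <- estimate_dispersions(kp, setNames(rep(1, 40), colnames(kp)), des(20))
  expect_lte(median(dp$final), 0.01)

  # NB alpha = 0.2 at mu = 200 with 50 replicates per cell: the fraction of
  # gene-wise estimates within 25% of truth matches a brute-force oracle of
  # the same pooled moment estimator (0.891 +/- 0.006 by direct simulation)
  set.seed(5)
  kn <- matrix(rnbinom(400 * 100, mu = 200, size = 1 / 0.2), 400, 100,
               dimnames = list(sprintf("g%04d", 1:400),
                               sprintf("s%02d", 1:100)))
  dn <- estimate_dispersions(kn, setNames(rep(1, 100), colnames(kn)),
                             des(50))
  oracle_est <- vapply(seq_len(400), function(g) {
    k1 <- rnbinom(50, mu = 200, size = 5)
    k2 <- rnbinom(50, mu = 200, size = 5)
    s2 <- (49 * var(k1) + 49 * var(k2)) / 98
    m <- (mean(k1) + mean(k2)) / 2
    max(0, (s2 - m) / m^2)
  }, numeric(1))
  frac_impl <- mean(abs(dn$gene_wise - 0.2) / 0.2 <= 0.25)
  frac_oracle <- mean(abs(oracle_est - 0.2) / 0.2 <= 0.25)
  expect_lt(abs(frac_impl - frac_oracle), 0.06)   # ~4 MC sd at 400 genes
  expect_gte(frac_impl, 0.85)
  expect_equal(median(dn$gene_wise), 0.2, tolerance = 0.1)

  # constant gene: zero within-cell variance gives gene-wise alpha = 0
  kc <- rbind(g1 = rep(50L, 8), g2 = c(10L, 60L, 20L, 90L, 15L, 70L, 25L,
                                       95L))
  colnames(kc) <- sprintf("s%02d", 1:8)
  dc <- estimate_dispersions(kc, setNames(rep(1, 8), colnames(kc)), des(4))
  expect_equal(dc["g1", "gene_wise"], 0)
  expect_gte(dc["g1", "final"], 1e-8)
})

test_that("the Wald contrast is exact under symmetry and flags degeneracies", {
  # identical treatment groups: log2FC and statistic are exactly zero
  k <- cbind(s1 = c(10L, 40L), s2 = c(20L, 80L), s3 = c(10L, 40L),
             s4 = c(20L, 80L))
  rownames(k) <- c("g1", "g2")
  design <- data.frame(sample = colnames(k), genotype = "gA",
                       treatment = c("control", "control", "stress",
                                     "stress"))
  sf <- setNames(rep(1, 4), colnames(k))
  res <- nb_wald_contrast(k, sf, setNames(c(0.1, 0.1), rownames(k)),
                          design, "gA")
  expect_equal(res$log2FoldChange, c(0, 0), tolerance = 1e-8)
  expect_equal(res$stat, c(0, 0), tolerance = 1e-6)

  # all-zero gene is flagged, never silently estimated
  kz <- rbind(g1 = c(10L, 12L, 30L, 35L), g2 = c(0L, 0L, 0L, 0L))
  colnames(kz) <- colnames(k)
  resz <- nb_wald_contrast(kz, sf, setNames(c(0.1, 0.1), rownames(kz)),
                           design, "gA")
  expect_true(is.na(resz["g2", "pvalue"]))
  expect_false(resz["g2", "converged"])
  # and excluded from the BH denominator
  expect_equal(resz["g1", "padj"], resz["g1", "pvalue"])

  expect_error(nb_wald_contrast(k, sf, setNames(c(0.1, 0.1), rownames(k)),
                                design, "missing"), "not present")
})

test_that("planted fold changes are recovered without bias", {
  fx <- make_two_group_counts(500, mu0 = 200, fold = 4, alpha = 0.05,
                              seed = 6)
  res <- nb_wald_contrast(fx$counts, fx$sf, fx$alpha, fx$design, "gA")
  expect_equal(mean(res$log2FoldChange, na.rm = TRUE), 2, tolerance = 0.05)
  expect_gt(mean(res$padj < 0.05, na.rm = TRUE), 0.99)
})

test_that("Wald p values are calibrated under the null", {
  fx <- make_two_group_counts(4000, mu0 = 100, fold = 1, alpha = 0.05,
                              seed = 7)
  res <- nb_wald_contrast(fx$counts, fx$sf, fx$alpha, fx$design, "gA")
  rej <- mean(res$pvalue < 0.05, na.rm = TRUE)
  expect_gte(rej, 0.035); expect_lte(rej, 0.065)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the naive step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))                  # sandwich: >= raw p
    expect_true(all(adj <= pmin(1, length(p) * p)))  # <= Bonferroni
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.02, NA, 0.04))[2], NA_real_)
})
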