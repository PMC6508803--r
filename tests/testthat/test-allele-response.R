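# Paired log2 fold changes for genes at least twofold more Al-responsive in
# the line carrying the resistant-parent ART1 allele, as printed for the two
# genetic backgrounds (reference-allele line first).
azucena_bg_pairs <- data.frame(
  gene = c("LOC_Os12g38270", "LOC_Os10g38340", "LOC_Os03g16030",
           "LOC_Os01g43750", "LOC_Os08g05960", "LOC_Os08g05970",
           "ChrSy.fgenesh.gene.47", "LOC_Os03g16020", "LOC_Os01g43774",
           "LOC_Os04g27060", "LOC_Os12g38290", "LOC_Os08g05980"),
  lfc_ref = c(3.25, 3.20, 3.16, 2.89, 2.80, 2.95, 2.51, 2.62, 2.38, 2.12,
              2.77, 1.30),
  lfc_alt = c(0.79, 0.74, 0.90, 0.85, 0.86, 1.02, 0.65, 0.79, 0.78, 0.53,
              1.20, 0.26),
  stringsAsFactors = FALSE)

ir64_bg_pairs <- data.frame(
  gene = c("LOC_Os06g19130", "LOC_Os05g11320", "LOC_Os01g69010",
           "LOC_Os04g01690", "LOC_Os05g33900", "LOC_Os12g38290",
           "LOC_Os04g41750", "LOC_Os11g41840", "LOC_Os06g39700",
           "LOC_Os02g09390"),
  lfc_ref = c(2.31, 1.16, 4.79, 1.87, 1.09, 1.66, 2.92, 1.28, 1.21, 2.65),
  lfc_alt = c(0.88, -0.13, 3.56, 0.65, -0.04, 0.58, 1.85, 0.27, 0.21,
              1.65),
  stringsAsFactors = FALSE)

test_that("DE calling applies the three-part rule", {
  res <- data.frame(gene = c("up_strong", "weak_fc", "weak_p", "low_expr",
                             "down_strong"),
                    log2FoldChange = c(3.25, 0.9, 2, -1.5, -2.1),
                    padj = c(0.01, 0.001, 0.06, 0.01, 0.004),
                    stringsAsFactors = FALSE)
  norm <- matrix(500, 5, 3, dimnames = list(res$gene, c("a", "b", "c")))
  norm["low_expr", ] <- c(2, 5, 7)   # never reaches 8 normalized counts
  de <- call_de_genes(res, norm, de_criteria())
  expect_equal(de$up, "up_strong")
  expect_equal(de$down, "down_strong")
  expect_length(intersect(de$up, de$down), 0)
  expect_error(call_de_genes(res[, c("gene", "log2FoldChange")], norm),
               "padj")
})

test_that("ratio classification works on the linear fold-change scale, inclusive", {
  # delta exactly 1.00 passes the twofold threshold
  expect_true(ratio_classify(2.65, 1.65, 2))
  expect_true(ratio_classify(4.79, 3.56, 2))
  expect_false(ratio_classify(1.5, 1.5, 2))
  expect_false(ratio_classify(-2, -2, 2))
  expect_true(ratio_classify(1.0, 0.3, 1.5))    # 0.7 >= log2(1.5)
  expect_error(ratio_classify(1, 0, 1), "exceed 1")
  expect_error(ratio_classify(Inf, 0, 2), "finite")
})

test_that("a twofold ratio call implies a 1.5-fold call (threshold nesting)", {
  set.seed(1)
  lfc_ref <- rnorm(500, 1, 2)
  lfc_alt <- rnorm(500, 0.5, 2)
  two <- ratio_classify(lfc_ref, lfc_alt, 2)
  onefive <- ratio_classify(lfc_ref, lfc_alt, 1.5)
  expect_true(all(!two | onefive))
})

test_that("the printed background tables classify as reported", {
  ct_a <- classify_table(azucena_bg_pairs$gene, azucena_bg_pairs$lfc_ref,
                         azucena_bg_pairs$lfc_alt)
  expect_equal(unname(ct_a$counts[">=2x"]), 12L)
  ct_b <- classify_table(ir64_bg_pairs$gene, ir64_bg_pairs$lfc_ref,
                         ir64_bg_pairs$lfc_alt)
  expect_equal(unname(ct_b$counts[">=2x"]), 10L)
  # sorted by descending delta, and nested counts match a brute-force filter
  expect_true(all(diff(ct_a$table$delta) <= 0))
  expect_equal(unname(ct_a$counts[">=1.5x"]),
               sum(azucena_bg_pairs$lfc_ref - azucena_bg_pairs$lfc_alt >=
                     log2(1.5)))
})

test_that("classify_table counts equal a brute-force filter on random rows", {
  set.seed(2)
  for (i in 1:3) {
    n <- sample(5:40, 1)
    ref <- rnorm(n); alt <- rnorm(n)
    ct <- classify_table(paste0("g", 1:n), ref, alt)
    expect_equal(unname(ct$counts[">=2x"]), sum(ref - alt >= 1))
    expect_equal(unname(ct$counts[">=1.5x"]), sum(ref - alt >= log2(1.5)))
  }
  empty <- classify_table(character(0), numeric(0), numeric(0))
  expect_equal(unname(empty$counts), c(0L, 0L))
})

test_that("venn counts partition and conserve set sizes", {
  expect_equal(venn_counts(c("1", "2", "3"), c("3", "4")),
               list(only_a = 2L, shared = 1L, only_b = 1L))
  expect_equal(venn_counts(letters[1:3], letters[1:3])$only_a, 0L)
  expect_equal(venn_counts(letters[1:3], letters[4:6])$shared, 0L)
  set.seed(3)
  a <- sample(letters, 10); b <- sample(letters, 15)
  v <- venn_counts(a, b)
  expect_equal(v$only_a + v$shared, length(unique(a)))
  expect_equal(v$only_b + v$shared, length(unique(b)))
})

test_that("the log2 normalized transform anchors at zero and scales with depth", {
  k <- matrix(c(0L, 255L, 10L, 10L), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  tx <- transform_counts(k, c(a = 1, b = 1))
  expect_equal(tx["g1", "a"], 0)
  expect_equal(tx["g2", "a"], 8)
  tx2 <- transform_counts(k, c(a = 2, b = 1))
  expect_equal(2^tx2["g2", "a"] - 1, 255 / 2)
  expect_error(transform_counts(k, c(a = 0, b = 1)), "positive")
})

test_that("top-variance PCA separates planted clusters and normalizes variance", {
  set.seed(4)
  x <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  x[1:50, 6:10] <- x[1:50, 6:10] + 4    # two well-separated sample groups
  pc <- pca_top_variance(x, n_top = 100)
  expect_equal(sum(pc$prop_var), 1, tolerance = 1e-9)
  s1 <- sign(pc$scores[1:5, 1]); s2 <- sign(pc$scores[6:10, 1])
  expect_true(all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] != s2[1])
  # duplicating every sample leaves variance proportions unchanged
  pc2 <- pca_top_variance(cbind(x, x + 0), n_top = 100)
  expect_equal(pc2$prop_var[1:9], pc$prop_var[1:9], tolerance = 1e-8)
  expect_error(pca_top_variance(x[, 1, drop = FALSE]), "two samples")
  expect_error(pca_top_variance(x, n_top = 1000), "exceeds")
})

test_that("magnitude comparison behaves under symmetry and has power", {
  expect_equal(magnitude_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  set.seed(5)
  hits <- 0
  for (i in 1:20) {
    a <- rnorm(100, 2, 0.5); b <- rnorm(100, 1, 0.5)
    mt <- magnitude_test(a, b)
    if (mt$p_value < 1e-10) hits <- hits + 1
    flipped <- magnitude_test(b, a)
    expect_equal(flipped$statistic, -mt$statistic)
    expect_equal(flipped$p_value, mt$p_value)
  }
  expect_gte(hits, 20 * 0.99)
  expect_error(magnitude_test(1, c(1, 2)), "at least two")
  mw <- magnitude_test(rnorm(20), rnorm(20, 3), method = "wilcoxon")
  expect_lt(mw$p_value, 0.01)
})

test_that("relative root growth is the stress/control ratio", {
  expect_equal(rrg(90, 90), 1)
  expect_equal(rrg(0, 90), 0)
  expect_equal(rrg(45, 90), 0.5)
  expect_error(rrg(45, 0), "positive")
})
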