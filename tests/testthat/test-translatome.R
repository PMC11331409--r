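test_that("low-count prefilter keeps genes with enough covered samples", {
  m <- rbind(g1 = c(4, 4, 4, 0, 0, 0),
             g2 = c(3, 3, 3, 3, 3, 3),
             g3 = c(0, 0, 0, 0, 0, 0),
             g4 = c(10, 10, 0, 0, 0, 0))
  kept <- filter_low_counts(m)
  expect_equal(rownames(kept), "g1")
})

test_that("median-of-ratios size factors match the closed form", {
  # sample 2 exactly twice sample 1: factors (1/sqrt(2), sqrt(2))
  m <- cbind(s1 = c(10, 20, 30, 40), s2 = c(20, 40, 60, 80))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # identical samples: all ones
  m2 <- cbind(s1 = c(5, 9, 14), s2 = c(5, 9, 14), s3 = c(5, 9, 14))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  expect_error(size_factors(cbind(c(0, 5), c(5, 0))), "nonzero")
  # planted factors recovered within 2% at 2000 genes
  sc <- sim_config()
  sim <- gen_count_matrix(2000, config = sc, seed = 17, fractions = "total")
  sf <- size_factors(sim$counts)
  truth <- sim$truth$size_factors / exp(mean(log(sim$truth$size_factors)))
  expect_lt(max(abs(sf / truth - 1)), 0.02)
  # cross-check against the reference implementation
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(33)
  for (k in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # a large random vector against the oracle
  p <- runif(1000)
  expect_equal(bh_adjust(p), bh_oracle(p))
  # NA propagation and validation
  expect_true(is.na(bh_adjust(c(0.1, NA))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-group NB Wald recovers a planted log2 effect at high counts", {
  sc <- sim_config(mu_meanlog = log(3000), mu_sdlog = 0.4)
  eff <- data.frame(gene_id = sprintf("gene%04d", 1:40), cell_line_l2fc = 1)
  sim <- gen_count_matrix(400, effects = eff, config = sc, seed = 19,
                          fractions = "total")
  res <- nb_wald(sim$counts, sim$meta, "two_group")
  m <- match(eff$gene_id, res$gene_id)
  expect_lt(abs(mean(res$log2FC[m]) - 1), 0.1)
  expect_true(all(res$padj[m] < 0.05, na.rm = TRUE))
})

test_that("the interaction sign convention matches enhanced polysome loading", {
  sc <- sim_config(mu_meanlog = log(1000), mu_sdlog = 0.5)
  # a gene whose polysomal share rises in the knockout
  eff <- data.frame(gene_id = sprintf("gene%04d", 1:10),
                    interaction_l2fc = -1.5)
  sim <- gen_count_matrix(300, effects = eff, config = sc, seed = 23)
  res <- nb_wald(sim$counts, sim$meta, "interaction")
  m <- match(eff$gene_id, res$gene_id)
  expect_true(all(res$log2FC[m] < 0))
  cls <- classify_translation(res)
  expect_true(all(cls$class[match(eff$gene_id, cls$gene_id)] == "enhanced"))
})

test_that("results are invariant under sample permutation", {
  sc <- sim_config()
  sim <- gen_count_matrix(60, config = sc, seed = 29)
  res <- nb_wald(sim$counts, sim$meta, "interaction")
  perm <- sample(ncol(sim$counts))
  res2 <- nb_wald(sim$counts[, perm], sim$meta[perm, ], "interaction")
  expect_equal(res$log2FC, res2$log2FC, tolerance = 1e-6)
  expect_equal(res$pvalue, res2$pvalue, tolerance = 1e-6)
})

test_that("classification applies both thresholds to the point estimate", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2FC = c(-1.43, 0.4, 0.9, -2, 1.2),
                   padj = c(0.001, 0.001, 0.2, NA, 0.04))
  cls <- classify_translation(de)
  expect_equal(cls$class, c("enhanced", "unchanged", "unchanged",
                            "unchanged", "retarded"))
})

test_that("interaction estimates agree with DESeq2 on the same data", {
  skip_if_not_installed("DESeq2")
  sc <- sim_config(mu_meanlog = log(500), mu_sdlog = 0.6)
  eff <- data.frame(gene_id = sprintf("gene%04d", 1:20),
                    interaction_l2fc = rep(c(1.5, -1.5), 10))
  sim <- gen_count_matrix(200, effects = eff, config = sc, seed = 31)
  res <- nb_wald(sim$counts, sim$meta, "interaction")
  meta <- sim$meta
  meta$cell_line <- factor(meta$cell_line, c("wt", "ko"))
  meta$fraction <- factor(meta$fraction, c("polysomal", "unbound"))
  dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts, meta,
                                        ~ cell_line * fraction)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, name = "cell_lineko.fractionunbound")
  m <- match(res$gene_id, rownames(ref))
  expect_gt(cor(res$log2FC, ref$log2FoldChange[m], use = "complete.obs"),
            0.99)
  expect_lt(mean(abs(res$log2FC - ref$log2FoldChange[m]), na.rm = TRUE), 0.1)
})

test_that("PCA separates the dominant factor on PC1", {
  sc <- sim_config()
  sim <- gen_count_matrix(500, config = sc, seed = 37, fraction_sd = 2)
  pca <- pca_counts(sim$counts, sim$meta)
  # fraction effect dominates: PC1 splits unbound vs polysomal
  pc1 <- split(pca$PC1, pca$fraction)
  expect_true(max(pc1$unbound) < min(pc1$polysomal) ||
                max(pc1$polysomal) < min(pc1$unbound))
  # duplicated sample lands on identical coordinates
  cts <- cbind(sim$counts, dup = sim$counts[, 1])
  meta <- rbind(sim$meta, data.frame(sample = "dup", cell_line = "wt",
                                     fraction = sim$meta$fraction[1],
                                     replicate = 9))
  colnames(cts) <- meta$sample
  pca2 <- pca_counts(cts, meta, sf = rep(1, ncol(cts)))
  expect_equal(unlist(pca2[pca2$sample == "dup", c("PC1", "PC2")]),
               unlist(pca2[1, c("PC1", "PC2")]), tolerance = 1e-8)
  # component orthogonality
  expect_equal(sum(pca$PC1 * pca$PC2), 0, tolerance = 1e-6)
  expect_error(pca_counts(sim$counts[, 1, drop = FALSE], sim$meta[1, ]),
               "two samples")
})

test_that("designs with missing replication are rejected", {
  sc <- sim_config()
  sim <- gen_count_matrix(30, config = sc, seed = 41)
  keep <- sim$meta$sample != "wt_unbound_1" & sim$meta$sample != "wt_unbound_2"
  expect_error(nb_wald(sim$counts[, keep], sim$meta[keep, ], "interaction"),
               "fewer than two replicates")
})
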