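test_that("gene model generator respects quotas, nesting and determinism", {
  gm <- gen_gene_models(50, seed = 1)
  expect_equal(nrow(gm$genes), 50)
  # features nested in transcripts, transcripts in genes
  f <- merge(gm$features, gm$transcripts, by = "transcript_id")
  expect_true(all(f$start >= f$tx_start & f$end <= f$tx_end))
  t <- merge(gm$transcripts, gm$genes, by = "gene_id")
  expect_true(all(t$tx_start >= t$gene_start & t$tx_end <= t$gene_end))
  # upstream and downstream zones exist
  expect_true(all(t$tx_start > t$gene_start) || any(t$tx_start > t$gene_start))
  # quotas: at least one exon-only gene and one snoRNA host
  coding <- unique(gm$features$gene_id[gm$features$type == "CDS"])
  expect_gt(length(setdiff(gm$genes$gene_id, coding)), 0)
  expect_gt(sum(gm$genes$is_snoRNA_host), 0)
  # every CDS length is a multiple of 3
  for (tid in unique(gm$features$transcript_id[gm$features$type == "CDS"])) {
    cds <- gm$features[gm$features$transcript_id == tid &
                         gm$features$type == "CDS", ]
    expect_equal(sum(cds$end - cds$start + 1) %% 3, 0)
  }
  expect_identical(gm, gen_gene_models(50, seed = 1))
  expect_error(gen_gene_models(0, seed = 1), "positive integer")
})

test_that("single-gene model round-trips losslessly through GTF/BED/FASTA", {
  for (n in c(1, 20)) {
    gm <- gen_gene_models(n, seed = 7)
    d <- withr::local_tempdir()
    write_gene_models(gm, gtf = file.path(d, "g.gtf"),
                      bed = file.path(d, "r.bed"),
                      fasta = file.path(d, "g.fa"))
    gm2 <- read_gene_models(file.path(d, "g.gtf"), file.path(d, "r.bed"),
                            file.path(d, "g.fa"))
    expect_equal(gm$genes, gm2$genes)
    ord <- function(x) {
      x <- x[order(x$transcript_id, x$type, x$start), ]
      rownames(x) <- NULL
      x
    }
    expect_equal(ord(gm$features), ord(gm2$features))
    expect_equal(gm$repeats, gm2$repeats, ignore_attr = TRUE)
    expect_equal(as.character(gm$genome[[1]]), as.character(gm2$genome[[1]]))
  }
})

test_that("pileup generator matches its binomial expectations", {
  gm <- gen_gene_models(20, seed = 3)
  sc <- sim_config(flag_rate = 0, lowq_rate = 0)
  # null construction: G fraction equals the error rate within sampling error
  spec <- plant_edit_sites(gm, n_null = 400, seed = 4)
  pu <- gen_pileups(gm, sc, spec, seed = 5)
  gcols <- paste0(pu$samples$sample, "_G")
  acols <- paste0(pu$samples$sample, "_A")
  g <- sum(pu$pileup[, gcols]); a <- sum(pu$pileup[, acols])
  p_hat <- g / (a + g)
  se <- sqrt(sc$error_rate / (a + g))
  expect_lt(abs(p_hat - sc$error_rate), 4 * se + 1e-4)
  # planted site at frequency 0.20, coverage 50: mean wt G ~ 10, ko ~ 0.05
  spec2 <- plant_edit_sites(gm, n_wt_only = 300, freq = 0.20, seed = 6)
  pu2 <- gen_pileups(gm, sc, spec2, seed = 7)
  wt_g <- mean(as.matrix(pu2$pileup[, paste0("wt_", 1:3, "_G")]))
  ko_g <- mean(as.matrix(pu2$pileup[, paste0("ko_", 1:3, "_G")]))
  expect_equal(wt_g, 10, tolerance = 0.05)
  expect_lt(ko_g, 0.2)
  # determinism and out-of-bounds error
  pu3 <- gen_pileups(gm, sc, spec2, seed = 7)
  expect_identical(pu2$pileup, pu3$pileup)
  bad <- spec2[1, ]; bad$pos <- gm$genes$gene_end[nrow(gm$genes)] + 50
  expect_error(gen_pileups(gm, sc, bad, seed = 1), "outside")
})

test_that("editing frequency is monotone in the expected G fraction", {
  gm <- gen_gene_models(10, seed = 2)
  sc <- sim_config(flag_rate = 0, lowq_rate = 0)
  fr <- c(0.02, 0.1, 0.3, 0.6)
  gfrac <- sapply(seq_along(fr), function(k) {
    spec <- plant_edit_sites(gm, n_wt_only = 150, freq = fr[k], seed = 11)
    pu <- gen_pileups(gm, sc, spec, seed = 12)
    g <- sum(pu$pileup[, paste0("wt_", 1:3, "_G")])
    a <- sum(pu$pileup[, paste0("wt_", 1:3, "_A")])
    g / (a + g)
  })
  expect_true(all(diff(gfrac) > 0))
})

test_that("count matrix plants size factors and the interaction ratio", {
  sc <- sim_config(dispersion = 0.001, mu_meanlog = log(5000), mu_sdlog = 0.2)
  eff <- data.frame(gene_id = "gene0001", interaction_l2fc = -1.5)
  sim <- gen_count_matrix(500, effects = eff, config = sc, seed = 8,
                          fraction_sd = 0)
  # planted interaction equals the empirical double ratio at large counts
  norm <- sweep(sim$counts, 2, sim$truth$size_factors, `/`)
  cell <- function(cl, fr)
    mean(norm["gene0001", sim$meta$cell_line == cl & sim$meta$fraction == fr])
  dr <- log2((cell("ko", "unbound") / cell("ko", "polysomal")) /
               (cell("wt", "unbound") / cell("wt", "polysomal")))
  expect_equal(dr, -1.5, tolerance = 0.15)
  # all effects zero: group means differ only by the planted size factors
  sim0 <- gen_count_matrix(2000, config = sc, seed = 9, fraction_sd = 0)
  norm0 <- sweep(sim0$counts, 2, sim0$truth$size_factors, `/`)
  cm <- colMeans(norm0)
  expect_lt(max(abs(cm / mean(cm) - 1)), 0.05)
  expect_identical(sim$counts,
                   gen_count_matrix(500, effects = eff, config = sc, seed = 8,
                                    fraction_sd = 0)$counts)
  expect_error(gen_count_matrix(10, config = sim_config(dispersion = -1)),
               "non-negative")
})

test_that("cell image generator records exact rendered areas", {
  sc <- sim_config()
  img <- gen_cell_images(sc, seed = 13, n_cells = 1, distractors = FALSE)
  # truth area is the rendered pixel count of the disc
  expect_equal(img$truth$area_px, sum(img$green > 0.5))
  r <- sqrt(img$truth$area_px / pi)
  expect_equal(img$truth$area_px, pi * r^2, tolerance = 0.05)
  # empty field
  img0 <- gen_cell_images(sc, seed = 13, n_cells = 0)
  expect_equal(nrow(img0$truth), 0)
  expect_lt(max(img0$green), 0.1)
  # two populations with the study's median ratio
  a_wt <- gen_cell_images(sc, seed = 14, n_cells = 200,
                          median_area = sc$median_area_wt,
                          distractors = FALSE)$truth$area_px
  a_ko <- gen_cell_images(sc, seed = 15, n_cells = 200,
                          median_area = sc$median_area_ko,
                          distractors = FALSE)$truth$area_px
  ratio <- median(a_ko) / median(a_wt)
  expect_equal(ratio, 8472 / 6406, tolerance = 0.08)
  # PNG round trip at 16-bit precision
  d <- withr::local_tempdir()
  write_channel_png(img$green, file.path(d, "g.png"))
  back <- read_channel_png(file.path(d, "g.png"))
  expect_equal(dim(back), dim(img$green))
  expect_lt(max(abs(back - img$green)), 1 / 255)
})

test_that("derived stage seeds are stable and distinct", {
  expect_identical(derive_seed(1, "pileup"), derive_seed(1, "pileup"))
  expect_false(derive_seed(1, "pileup") == derive_seed(1, "counts"))
  expect_false(derive_seed(1, "pileup") == derive_seed(2, "pileup"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
})
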