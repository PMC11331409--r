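test_that("region classification follows the gene anatomy and priorities", {
  gm <- hand_gene_models()
  # upstream / downstream margins
  expect_equal(classify_region(50, gm, "gA"), "upstream")
  expect_equal(classify_region(950, gm, "gA"), "downstream")
  expect_equal(classify_region(1250, gm, "gB"), "upstream")
  expect_equal(classify_region(2150, gm, "gB"), "downstream")
  # transcript anatomy, plus strand
  expect_equal(classify_region(150, gm, "gA"), "five_utr")
  expect_equal(classify_region(250, gm, "gA"), "CDS")
  expect_equal(classify_region(350, gm, "gA"), "intron")
  expect_equal(classify_region(850, gm, "gA"), "three_utr")
  # minus strand: 5'UTR sits at high coordinates
  expect_equal(classify_region(2050, gm, "gB"), "five_utr")
  expect_equal(classify_region(1350, gm, "gB"), "three_utr")
  expect_equal(classify_region(1700, gm, "gB"), "CDS")
  # exon-only transcript yields the plain exon category
  expect_equal(classify_region(2600, gm, "gC"), "exon")
  # cross-transcript conflict: intron of t1 vs exon of t2 -> exon
  expect_equal(classify_region(3500, gm, "gD"), "exon")
  # CDS of t1 beats exon of... (pos in both t1 CDS and nothing else)
  expect_equal(classify_region(3200, gm, "gD"), "CDS")
  expect_error(classify_region(1100, gm, "gA"), "outside")
  expect_error(classify_region(100, gm, "nope"), "unknown gene")
})

test_that("priority is independent of transcript listing order", {
  gm <- hand_gene_models()
  gm2 <- gm
  o <- rev(seq_len(nrow(gm2$transcripts)))
  gm2$transcripts <- gm2$transcripts[o, ]
  for (pos in c(3200, 3500, 3120, 3880))
    expect_equal(classify_region(pos, gm, "gD"),
                 classify_region(pos, gm2, "gD"))
})

test_that("repeat assignment uses half-open intervals and smallest wins", {
  gm <- hand_gene_models()
  r <- gm$repeats
  expect_equal(assign_repeat(1560, r), "SINE")
  expect_equal(assign_repeat(10, r), "none")
  # a position at an interval's end coordinate is outside it (half-open)
  expect_equal(assign_repeat(380, r[1, , drop = FALSE]), "none")
  expect_equal(assign_repeat(380, r), "none")
  # overlapping SINE (320,380] x LINE (340,370]: smallest interval wins
  expect_equal(assign_repeat(350, r), "LINE")
  expect_equal(assign_repeat(330, r), "SINE")
})

test_that("codon consequences follow the standard code on both strands", {
  gm <- hand_gene_models()
  for (g in list(list(id = "gA", tid = "gA.t1"),
                 list(id = "gB", tid = "gB.t1"))) {
    cpos <- adarscope:::cds_positions(gm, g$tid)
    # initiator ATG edited at its A
    r <- codon_consequence(cpos[1], gm, gene_id = g$id)
    expect_equal(r$ref_codon, "ATG")
    expect_equal(r$consequence, "start_loss")
    # codon 2: AAA -> GAA, Lys -> Glu
    r <- codon_consequence(cpos[4], gm, gene_id = g$id)
    expect_equal(c(r$ref_codon, r$alt_codon), c("AAA", "GAA"))
    expect_equal(c(r$ref_aa, r$alt_aa), c("K", "E"))
    expect_equal(r$consequence, "missense")
    # codon 2 offset 1 and 2 are also A's
    r <- codon_consequence(cpos[5], gm, gene_id = g$id)
    expect_equal(r$alt_codon, "AGA")
    expect_equal(r$consequence, "missense")  # Lys -> Arg
    # codon 3: ACA -> GCA, Thr -> Ala
    r <- codon_consequence(cpos[7], gm, gene_id = g$id)
    expect_equal(c(r$ref_codon, r$alt_codon), c("ACA", "GCA"))
    expect_equal(r$consequence, "missense")
    # stop codon TAA edited at offset 1 -> TGA, stop retained
    n <- length(cpos)
    r <- codon_consequence(cpos[n - 1], gm, gene_id = g$id)
    expect_equal(c(r$ref_codon, r$alt_codon), c("TAA", "TGA"))
    expect_equal(r$consequence, "stop_retained")
    # offset 2 -> TAG, also a stop
    r <- codon_consequence(cpos[n], gm, gene_id = g$id)
    expect_equal(r$alt_codon, "TAG")
    expect_equal(r$consequence, "stop_retained")
  }
  # non-A reference errors
  gA_cds <- adarscope:::cds_positions(gm, "gA.t1")
  expect_error(codon_consequence(gA_cds[2], gm, gene_id = "gA"), "not A")
  expect_error(codon_consequence(50, gm, gene_id = "gA"), "not inside")
})

test_that("strand reversal leaves consequences unchanged", {
  gm <- hand_gene_models()
  # gB is the strand-reversed twin of gA: same codon layout
  a <- adarscope:::cds_positions(gm, "gA.t1")
  b <- adarscope:::cds_positions(gm, "gB.t1")
  for (k in c(1, 4, 5, 7, length(a) - 1)) {
    ca <- codon_consequence(a[k], gm, gene_id = "gA")
    cb <- codon_consequence(b[k], gm, gene_id = "gB")
    expect_equal(ca$ref_codon, cb$ref_codon)
    expect_equal(ca$alt_codon, cb$alt_codon)
    expect_equal(ca$consequence, cb$consequence)
  }
})

test_that("site summaries conserve counts and join the truth", {
  gm <- hand_gene_models()
  calls <- data.frame(chrom = "chr1",
                      pos = c(150, 250, 350, 850, 2600, 1700, 50, 330))
  ann <- annotate_sites(calls, gm)
  expect_true(all(!is.na(ann$region)))
  sm <- summarize_sites(ann)
  expect_equal(sum(sm$table), nrow(calls))
  expect_equal(sm$n_genes, 3)
  expect_equal(unname(sm$table["intron", "SINE"]), 1)  # pos 330
  expect_equal(unname(sm$table["CDS", "none"]), 2)     # 250 and 1700
  # every annotated site gets exactly one region and one repeat value
  expect_true(all(table(ann$pos) == 1))
  # empty call set gives an all-zero table
  sm0 <- summarize_sites(annotate_sites(calls[0, , drop = FALSE], gm))
  expect_equal(sum(sm0$table), 0)
  # three intronic SINE sites collapse into a single cell
  calls3 <- data.frame(chrom = "chr1", pos = c(330, 331, 333))
  sm3 <- summarize_sites(annotate_sites(calls3, gm))
  expect_equal(unname(sm3$table["intron", "SINE"]), 3)
  expect_equal(sum(sm3$table), 3)
})

test_that("generator annotations agree with the planted truth join", {
  gm <- gen_gene_models(30, seed = 9)
  sc <- sim_config(flag_rate = 0, lowq_rate = 0)
  spec <- plant_edit_sites(gm, n_wt_only = 60, seed = 10)
  pu <- gen_pileups(gm, sc, spec, seed = 11)
  calls <- call_differential_editing(pu$pileup, groups_3v3)
  ann <- annotate_sites(calls[calls$status == "pass", ], gm)
  tr <- pu$truth$sites
  m <- merge(ann, tr[, c("pos", "gene_id")], by = "pos",
             suffixes = c("", ".truth"))
  expect_true(all(m$gene_id == m$gene_id.truth))
})
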