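#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: a gene annotation with repeats
# and a genome, strand-resolved pileups with wild-type-only editing planted
# at 20% frequency, a polysome-fraction count matrix in which retarded-
# loading effects are planted preferentially in snoRNA-host genes (8x
# odds), class-labelled small-RNA counts (snoRNA up, Y RNA down), and
# two-channel cell images at the reported median-area ratio of 1.32.
suppressMessages(library(adarscope))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gm <- gen_gene_models(600, seed = derive_seed(seed, "annotation"))
write_gene_models(gm, gtf = file.path(out, "genes.gtf"),
                  bed = file.path(out, "repeats.bed"),
                  fasta = file.path(out, "genome.fa"))
message(sprintf("annotation: %d genes (%d snoRNA hosts), %d repeat intervals",
                nrow(gm$genes), sum(gm$genes$is_snoRNA_host),
                nrow(gm$repeats)))

sc <- sim_config()
spec <- plant_edit_sites(gm, n_null = 500, n_wt_only = 90, n_both = 10,
                         n_ct = 15, seed = derive_seed(seed, "sites"))
pu <- gen_pileups(gm, sc, spec, seed = derive_seed(seed, "pileup"))
write_pileup(pu$pileup, file.path(out, "pileup.tsv"))
write_tsv <- function(x, p) utils::write.table(x, p, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE)
write_tsv(pu$truth$sites, file.path(out, "truth_sites.tsv"))
message(sprintf("pileups: %d sites x %d samples (%d planted wt-only)",
                nrow(pu$pileup), nrow(pu$samples),
                sum(spec$group == "wt_only")))

# interaction effects: retarded loading enriched in snoRNA-host genes
set.seed(derive_seed(seed, "effects"))
host <- gm$genes$is_snoRNA_host
p_ret <- ifelse(host, 0.40, 0.40 / 8 / (1 - 0.40 + 0.40 / 8))  # ~8x odds
retarded <- runif(nrow(gm$genes)) < p_ret
enhanced <- !retarded & runif(nrow(gm$genes)) < 0.06
eff <- data.frame(gene_id = gm$genes$gene_id,
                  interaction_l2fc = ifelse(retarded, 1.5,
                                            ifelse(enhanced, -1.5, 0)))
cm <- gen_count_matrix(gm$genes$gene_id, effects = eff, config = sc,
                       seed = derive_seed(seed, "counts"))
write_tsv(cbind(gene_id = rownames(cm$counts), as.data.frame(cm$counts)),
          file.path(out, "counts.tsv"))
write_tsv(cm$meta, file.path(out, "meta.tsv"))
write_tsv(eff, file.path(out, "truth_interaction.tsv"))
message(sprintf("counts: %d genes, %d planted retarded (%d in hosts), %d enhanced",
                nrow(cm$counts), sum(retarded), sum(retarded & host),
                sum(enhanced)))

sr <- gen_smallrna_counts(300, config = sc,
                          seed = derive_seed(seed, "smallrna"))
write_tsv(cbind(feature_id = rownames(sr$counts), as.data.frame(sr$counts)),
          file.path(out, "smallrna_counts.tsv"))
write_tsv(sr$classes, file.path(out, "smallrna_classes.tsv"))
lc <- gen_length_counts(seed = derive_seed(seed, "lengths"))
write_tsv(cbind(length = rownames(lc$counts), as.data.frame(lc$counts)),
          file.path(out, "length_counts.tsv"))

for (pop in c("wt", "ko")) {
  med <- if (pop == "wt") sc$median_area_wt else sc$median_area_ko
  img <- gen_cell_images(sc, seed = derive_seed(seed, paste0("img_", pop)),
                         n_cells = 60, median_area = med)
  write_channel_png(img$green, file.path(out, paste0(pop, "_green.png")))
  write_channel_png(img$blue, file.path(out, paste0(pop, "_blue.png")))
  write_tsv(img$truth, file.path(out, paste0(pop, "_truth_areas.tsv")))
}
message("images: 60 cells/population at medians 6406 (wt) and 8472 (ko) px")
message("done: synthetic inputs under ", out)
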