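#!/usr/bin/env Rscript
# Stage 3 — annotate the wild-type-only edited positions with transcript
# regions (upstream / 5'UTR / CDS / 3'UTR / intron / exon / downstream),
# repeat classes, and codon consequences under the I-as-G decoding rule;
# tabulate the region-by-repeat summary.
suppressMessages(library(adarscope))

data_dir <- "results/data"; out <- "results"
gm <- read_gene_models(file.path(data_dir, "genes.gtf"),
                       file.path(data_dir, "repeats.bed"),
                       file.path(data_dir, "genome.fa"))
wtonly <- read.delim(file.path(out, "editing_wt_only.tsv"))

ann <- annotate_sites(wtonly, gm)
sm <- summarize_sites(ann)
message(sprintf("%d edited positions in %d unique genes", sm$n_sites,
                sm$n_genes))
message("region x repeat table:")
print(sm$table)
cds <- ann[!is.na(ann$consequence) & !ann$consequence %in% "noncoding", ]
if (nrow(cds))
  message(sprintf("coding consequences: %s",
                  paste(sprintf("%s (%d)", names(table(cds$consequence)),
                                table(cds$consequence)), collapse = ", ")))

utils::write.table(ann, file.path(out, "sites_annotated.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(region = rownames(sm$table),
                         as.data.frame(sm$table)),
                   file.path(out, "region_repeat_table.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("done: annotated sites under ", out)
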