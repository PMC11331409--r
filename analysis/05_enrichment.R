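#!/usr/bin/env Rscript
# Stage 5 — membership-odds analyses by logistic regression: do edited
# transcripts fall into the translatome groups more often than chance, and
# are snoRNA-host genes over-represented among retarded-translation genes?
# The synthetic truth plants the host enrichment (8x odds) and leaves
# editing independent of translatome class, so the expected answers are
# OR ~ 8 for hosts and OR ~ 1 for edited transcripts.
suppressMessages(library(adarscope))

data_dir <- "results/data"; out <- "results"
cls <- read.delim(file.path(out, "translatome_calls.tsv"))
ann <- read.delim(file.path(out, "sites_annotated.tsv"))
gm <- read_gene_models(file.path(data_dir, "genes.gtf"))

edited <- data.frame(gene_id = unique(ann$gene_id[!is.na(ann$gene_id)]),
                     flag = TRUE)
hosts <- data.frame(gene_id = gm$genes$gene_id,
                    flag = gm$genes$is_snoRNA_host)

rows <- list()
for (spec in list(list(feat = edited, name = "edited"),
                  list(feat = hosts, name = "snoRNA_host"))) {
  for (grpn in c("retarded", "enhanced")) {
    mb <- build_membership(cls, spec$feat, grpn)
    o <- tryCatch(odds_membership(mb$in_group, mb$has_feature),
                  error = function(e) NULL)
    if (is.null(o)) next
    message(sprintf("%-12s x %-9s OR = %5.2f  (p = %.3g; a=%d b=%d c=%d d=%d)",
                    spec$name, grpn, o$odds_ratio, o$p,
                    o$cells["a"], o$cells["b"], o$cells["c"], o$cells["d"]))
    rows[[length(rows) + 1]] <- data.frame(
      feature = spec$name, group = grpn, odds_ratio = o$odds_ratio,
      p = o$p, a = o$cells["a"], b = o$cells["b"], c = o$cells["c"],
      d = o$cells["d"], corrected = o$corrected)
  }
}
tab <- do.call(rbind, rows)
utils::write.table(tab, file.path(out, "enrichment_odds.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("done: enrichment odds under ", out)
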