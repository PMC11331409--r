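# Hand-built five-gene annotation with a fully controlled genome sequence.
# CDS codon layout (translation order) for the two coding genes:
#   ATG | AAA | ACA | ... filler ... | TAA
# so codon 2 offset 0 tests A->G missense (Lys->Glu), codon 3 offset 0
# tests Thr->Ala, the initiator tests start_loss and the stop codon offset
# 1 tests stop_retained.
hand_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = "chr1",
    strand = c("+", "-", "+", "+", "+"),
    gene_start = c(1L, 1201L, 2401L, 3001L, 4201L),
    gene_end = c(1000L, 2200L, 2800L, 4000L, 4500L),
    is_snoRNA_host = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  transcripts <- data.frame(
    transcript_id = c("gA.t1", "gB.t1", "gC.t1", "gD.t1", "gD.t2", "gE.t1"),
    gene_id = c("gA", "gB", "gC", "gD", "gD", "gE"),
    tx_start = c(101L, 1301L, 2451L, 3101L, 3350L, 4251L),
    tx_end = c(900L, 2100L, 2750L, 3900L, 3650L, 4450L))
  feat <- function(tid, gid, type, s, e)
    data.frame(transcript_id = tid, gene_id = gid, type = type,
               start = as.integer(s), end = as.integer(e))
  features <- rbind(
    # gA (+): exons 101-300, 401-600, 701-900; 5utr 101-200,
    # CDS 201-300 + 401-600 + 701-799 (399 nt), 3utr 800-900
    feat("gA.t1", "gA", "exon", 101, 300),
    feat("gA.t1", "gA", "exon", 401, 600),
    feat("gA.t1", "gA", "exon", 701, 900),
    feat("gA.t1", "gA", "five_utr", 101, 200),
    feat("gA.t1", "gA", "CDS", 201, 300),
    feat("gA.t1", "gA", "CDS", 401, 600),
    feat("gA.t1", "gA", "CDS", 701, 799),
    feat("gA.t1", "gA", "three_utr", 800, 900),
    # gB (-): mirror of gA laid out 1301..2100; transcription right-to-left
    # ascending-genomic order is 3utr, CDS, 5utr
    feat("gB.t1", "gB", "exon", 1301, 1500),
    feat("gB.t1", "gB", "exon", 1601, 1800),
    feat("gB.t1", "gB", "exon", 1901, 2100),
    feat("gB.t1", "gB", "three_utr", 1301, 1401),
    feat("gB.t1", "gB", "CDS", 1402, 1500),
    feat("gB.t1", "gB", "CDS", 1601, 1800),
    feat("gB.t1", "gB", "CDS", 1901, 2000),
    feat("gB.t1", "gB", "five_utr", 2001, 2100),
    # gC: exon-only noncoding
    feat("gC.t1", "gC", "exon", 2451, 2750),
    # gD: coding t1 with an intron 3301-3700 bridged by exon-only t2
    feat("gD.t1", "gD", "exon", 3101, 3300),
    feat("gD.t1", "gD", "exon", 3701, 3900),
    feat("gD.t1", "gD", "five_utr", 3101, 3150),
    feat("gD.t1", "gD", "CDS", 3151, 3300),
    feat("gD.t1", "gD", "CDS", 3701, 3850),
    feat("gD.t1", "gD", "three_utr", 3851, 3900),
    feat("gD.t2", "gD", "exon", 3350, 3650),
    # gE: exon-only
    feat("gE.t1", "gE", "exon", 4251, 4450))
  repeats <- data.frame(
    chrom = "chr1",
    start = c(320L, 340L, 1550L, 4300L),   # 0-based half-open
    end = c(380L, 370L, 1580L, 4350L),
    class = c("SINE", "LINE", "SINE", "SINE"))
  gm <- structure(list(genes = genes, transcripts = transcripts,
                       features = features, repeats = repeats,
                       genome = NULL), class = "gene_model_set")
  # genome: neutral T background, then write CDS codons in translation order
  seqv <- rep("T", 4600)
  write_cds <- function(tid, strand) {
    cpos <- adarscope:::cds_positions(gm, tid)
    n <- length(cpos)
    codons <- c("ATG", "AAA", "ACA",
                rep("CTG", (n - 12) / 3), "TAA")
    sense <- strsplit(paste(codons, collapse = ""), "")[[1]]
    stopifnot(length(sense) == n)
    if (strand == "+") seqv[cpos] <<- sense
    else seqv[cpos] <<- chartr("ACGT", "TGCA", sense)
  }
  write_cds("gA.t1", "+")
  write_cds("gB.t1", "-")
  write_cds("gD.t1", "+")
  gm$genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(gm$genome) <- "chr1"
  gm
}

# one-row pileup data.frame for two groups of `nrep` samples with given
# per-sample base counts (lists of 4-vectors A,C,G,T)
make_pileup <- function(counts_by_sample, ref_base = "A", pos = 100,
                        strand = "+", mean_baseq = 35, flags = ".") {
  smp <- names(counts_by_sample)
  row <- data.frame(chrom = "chr1", pos = pos, strand = strand,
                    ref_base = ref_base, mean_baseq = mean_baseq,
                    flags = flags)
  for (s in smp) {
    v <- counts_by_sample[[s]]
    row[paste0(s, "_", c("A", "C", "G", "T"))] <- as.list(v)
  }
  row
}

# standard 3v3 pileup row: wt samples with (a_wt, g_wt), ko with (a_ko, g_ko)
pileup_3v3 <- function(a_wt, g_wt, a_ko, g_ko, ...) {
  cb <- c(
    stats::setNames(rep(list(c(a_wt, 0, g_wt, 0)), 3), paste0("wt_", 1:3)),
    stats::setNames(rep(list(c(a_ko, 0, g_ko, 0)), 3), paste0("ko_", 1:3)))
  make_pileup(cb, ...)
}

groups_3v3 <- list(wt = paste0("wt_", 1:3), ko = paste0("ko_", 1:3))
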