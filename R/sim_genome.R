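#' Generate a synthetic gene annotation, repeat set and genome
#'
#' Lays `n_genes` genes on one chromosome. Every gene has an upstream margin
#' between its database gene start and the first transcription start site and
#' a downstream margin after the last transcript end, so the "upstream" and
#' "downstream" site categories are populated. Roughly 70% of genes are
#' coding, with three exons carrying a 5'UTR, a CDS whose length is a
#' multiple of 3 (ATG start, TAA stop written into the genome sequence,
#' strand-aware), and a 3'UTR; the rest are exon-only noncoding models. For
#' `n_genes >= 2` at least one exon-only gene and at least one snoRNA-host
#' gene are forced by quota. A configurable fraction of introns and 3'UTRs
#' overlap SINE repeat intervals; LINE/LTR intervals and a few intergenic
#' repeats are added for contrast.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; the same seed reproduces the annotation exactly.
#' @param coding_frac fraction of coding genes.
#' @param host_frac fraction of genes flagged as snoRNA hosts.
#' @param sine_frac fraction of introns / 3'UTRs receiving a SINE interval.
#' @param second_tx_frac fraction of coding genes receiving a second,
#'   exon-only transcript (creates cross-transcript annotation conflicts).
#' @return a `gene_model_set`: list with data.frames `genes` (gene_id, chrom,
#'   strand, gene_start, gene_end, is_snoRNA_host), `transcripts`
#'   (transcript_id, gene_id, tx_start, tx_end), `features` (transcript_id,
#'   gene_id, type in exon/five_utr/CDS/three_utr, start, end; 1-based
#'   inclusive), `repeats` (chrom, start, end, class; 0-based half-open),
#'   and `genome` (a [Biostrings::DNAStringSet-class]).
#' @export
gen_gene_models <- function(n_genes, seed, coding_frac = 0.7, host_frac = 0.15,
                            sine_frac = 0.6, second_tx_frac = 0.2) {
  n_genes <- stop_if_not_scalar_count(n_genes, "n_genes")
  with_seed(seed, {
    # decide gene classes up front; quotas guarantee both kinds exist
    n_nc <- if (n_genes >= 2) max(1L, round((1 - coding_frac) * n_genes)) else 0L
    coding <- rep(TRUE, n_genes)
    if (n_nc > 0) coding[sample.int(n_genes, n_nc)] <- FALSE
    host <- rep(FALSE, n_genes)
    cod_idx <- which(coding)
    if (n_genes >= 2 && length(cod_idx) > 0) {
      n_host <- max(1L, round(host_frac * n_genes))
      host[sample(cod_idx, min(n_host, length(cod_idx)))] <- TRUE
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    genes <- transcripts <- features <- list()
    reps <- list()
    cursor <- 500L
    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%04d", i)
      up <- sample(50:300, 1); down <- sample(50:300, 1)
      gene_start <- cursor
      tss <- gene_start + up
      if (coding[i]) {
        e <- c(sample(150:400, 1), sample(120:300, 1), sample(200:600, 1))
        intr <- c(sample(200:800, 1), sample(200:800, 1))
        u5 <- sample(30:120, 1)
        # the 3'UTR lives in exon 3 (+) or exon 1 (-); keep it inside
        u3_max <- (if (strand[i] == "+") e[3] else e[1]) - 30L
        u3 <- sample(60:min(180L, u3_max), 1)
        cds_len <- (e[1] - u5) + e[2] + (e[3] - u3)
        u3 <- u3 + cds_len %% 3                      # keep CDS %% 3 == 0
        ex_start <- tss + c(0L, e[1] + intr[1], e[1] + intr[1] + e[2] + intr[2])
        ex_end <- ex_start + e - 1L
        tx_start <- ex_start[1]; tx_end <- ex_end[3]
        # transcription order: plus strand reads exon1->3, minus reads 3->1
        if (strand[i] == "+") {
          f <- data.frame(
            type = c("exon", "exon", "exon", "five_utr", "CDS", "CDS", "CDS",
                     "three_utr"),
            start = c(ex_start, ex_start[1], ex_start[1] + u5, ex_start[2],
                      ex_start[3], ex_end[3] - u3 + 1L),
            end = c(ex_end, ex_start[1] + u5 - 1L, ex_end[1], ex_end[2],
                    ex_end[3] - u3, ex_end[3]))
        } else {
          f <- data.frame(
            type = c("exon", "exon", "exon", "three_utr", "CDS", "CDS", "CDS",
                     "five_utr"),
            start = c(ex_start, ex_start[1], ex_start[1] + u3, ex_start[2],
                      ex_start[3], ex_end[3] - u5 + 1L),
            end = c(ex_end, ex_start[1] + u3 - 1L, ex_end[1], ex_end[2],
                    ex_end[3] - u5, ex_end[3]))
        }
      } else {
        e <- sample(300:900, 1)
        tx_start <- tss; tx_end <- tss + e - 1L
        f <- data.frame(type = "exon", start = tx_start, end = tx_end)
      }
      gene_end <- tx_end + down
      tid <- paste0(gid, ".t1")
      f$transcript_id <- tid; f$gene_id <- gid
      tx <- data.frame(transcript_id = tid, gene_id = gid,
                       tx_start = tx_start, tx_end = tx_end)
      if (coding[i] && stats::runif(1) < second_tx_frac) {
        # nested exon-only isoform spanning part of the gene body
        t2s <- tx_start + sample(50:150, 1); t2e <- min(tx_end, t2s + sample(300:800, 1))
        tid2 <- paste0(gid, ".t2")
        tx <- rbind(tx, data.frame(transcript_id = tid2, gene_id = gid,
                                   tx_start = t2s, tx_end = t2e))
        f <- rbind(f, data.frame(type = "exon", start = t2s, end = t2e,
                                 transcript_id = tid2, gene_id = gid))
      }
      # repeats: SINEs inside introns / 3'UTR, rarer LINE/LTR
      if (coding[i]) {
        intr_iv <- data.frame(start = ex_end[1:2] + 1L, end = ex_start[2:3] - 1L)
        for (k in 1:2) {
          if (stats::runif(1) < sine_frac) {
            w <- sample(80:250, 1)
            s0 <- sample(intr_iv$start[k]:(intr_iv$end[k] - w), 1)
            reps[[length(reps) + 1L]] <- data.frame(
              chrom = "chr1", start = s0 - 1L, end = s0 - 1L + w, class = "SINE")
          } else if (stats::runif(1) < 0.3) {
            w <- sample(150:400, 1)
            s0 <- sample(intr_iv$start[k]:max(intr_iv$start[k], intr_iv$end[k] - w), 1)
            reps[[length(reps) + 1L]] <- data.frame(
              chrom = "chr1", start = s0 - 1L, end = min(s0 - 1L + w, intr_iv$end[k]),
              class = sample(c("LINE", "LTR"), 1))
          }
        }
        utr3 <- f[f$type == "three_utr", ]
        if (stats::runif(1) < sine_frac && (utr3$end - utr3$start) > 90) {
          w <- sample(60:min(200, utr3$end - utr3$start), 1)
          s0 <- sample(utr3$start:(utr3$end - w), 1)
          reps[[length(reps) + 1L]] <- data.frame(
            chrom = "chr1", start = s0 - 1L, end = s0 - 1L + w, class = "SINE")
        }
      }
      genes[[i]] <- data.frame(gene_id = gid, chrom = "chr1", strand = strand[i],
                               gene_start = gene_start, gene_end = gene_end,
                               is_snoRNA_host = host[i])
      transcripts[[i]] <- tx
      features[[i]] <- f
      cursor <- gene_end + sample(300:600, 1)
    }
    genes <- do.call(rbind, genes)
    transcripts <- do.call(rbind, transcripts)
    features <- do.call(rbind, features)
    features <- features[, c("transcript_id", "gene_id", "type", "start", "end")]
    # a few intergenic repeats
    if (n_genes >= 2) {
      for (j in seq_len(max(1L, n_genes %/% 10))) {
        g <- sample(n_genes - 1L, 1)
        gap_s <- genes$gene_end[g] + 10L; gap_e <- genes$gene_start[g + 1L] - 10L
        if (gap_e - gap_s > 120) {
          w <- sample(60:100, 1); s0 <- sample(gap_s:(gap_e - w), 1)
          reps[[length(reps) + 1L]] <- data.frame(
            chrom = "chr1", start = s0 - 1L, end = s0 - 1L + w, class = "SINE")
        }
      }
    }
    repeats <- if (length(reps)) do.call(rbind, reps) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 class = character())
    repeats <- repeats[order(repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL

    chrom_len <- max(genes$gene_end) + 500L
    seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
    # write start and stop codons into each coding CDS (transcription sense)
    for (gid in genes$gene_id[coding]) {
      cds <- features[features$gene_id == gid & features$type == "CDS", ]
      str <- genes$strand[genes$gene_id == gid]
      pos <- unlist(lapply(seq_len(nrow(cds)), function(k) cds$start[k]:cds$end[k]))
      pos <- sort(pos)
      if (str == "+") {
        seq[pos[1:3]] <- c("A", "T", "G")
        seq[pos[(length(pos) - 2):length(pos)]] <- c("T", "A", "A")
      } else {
        # minus strand: genomic complement of ATG...TAA read high->low
        seq[pos[(length(pos) - 2):length(pos)]] <- c("C", "A", "T")
        seq[pos[1:3]] <- c("T", "T", "A")
      }
    }
    genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
    names(genome) <- "chr1"

    structure(list(genes = genes, transcripts = transcripts,
                   features = features, repeats = repeats, genome = genome),
              class = "gene_model_set")
  })
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf(
    "gene_model_set: %d genes (%d coding, %d snoRNA-host), %d transcripts, %d repeats, chr1 %d bp\n",
    nrow(x$genes),
    length(unique(x$features$gene_id[x$features$type == "CDS"])),
    sum(x$genes$is_snoRNA_host), nrow(x$transcripts), nrow(x$repeats),
    Biostrings::width(x$genome)[1]))
  invisible(x)
}

#' Write a gene_model_set to GTF, BED and FASTA
#'
#' GTF uses 1-based closed intervals with `gene_id`/`transcript_id`
#' attributes and a `snoRNA_host` attribute on gene records; the repeat BED
#' is 0-based half-open with the repeat class in the name column.
#'
#' @param gm a `gene_model_set`.
#' @param gtf,bed,fasta output paths (NULL to skip a file).
#' @return invisibly, the paths written.
#' @export
write_gene_models <- function(gm, gtf = NULL, bed = NULL, fasta = NULL) {
  stopifnot(inherits(gm, "gene_model_set"))
  out <- character()
  if (!is.null(gtf)) {
    g <- gm$genes; tx <- gm$transcripts; f <- gm$features
    strand_of <- stats::setNames(g$strand, g$gene_id)
    rows <- rbind(
      data.frame(type = "gene", start = g$gene_start, end = g$gene_end,
                 gene_id = g$gene_id, transcript_id = NA_character_,
                 snoRNA_host = ifelse(g$is_snoRNA_host, "1", "0")),
      data.frame(type = "transcript", start = tx$tx_start, end = tx$tx_end,
                 gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                 snoRNA_host = NA_character_),
      data.frame(type = ifelse(f$type == "five_utr", "five_prime_utr",
                        ifelse(f$type == "three_utr", "three_prime_utr", f$type)),
                 start = f$start, end = f$end, gene_id = f$gene_id,
                 transcript_id = f$transcript_id, snoRNA_host = NA_character_))
    gr <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(rows$start, rows$end),
      strand = strand_of[rows$gene_id], type = rows$type,
      gene_id = rows$gene_id, transcript_id = rows$transcript_id,
      snoRNA_host = rows$snoRNA_host)
    gr <- gr[order(GenomicRanges::start(gr),
                   match(rows$type, c("gene", "transcript", "exon",
                                      "five_prime_utr", "CDS", "three_prime_utr")))]
    # phase is irrelevant downstream (codon frame derives from CDS order)
    suppressWarnings(rtracklayer::export(gr, gtf, format = "gtf"))
    out <- c(out, gtf)
  }
  if (!is.null(bed)) {
    r <- gm$repeats
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(r$start + 1L, r$end),
                                 name = r$class)
    rtracklayer::export(gr, bed, format = "bed")
    out <- c(out, bed)
  }
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(gm$genome, fasta)
    out <- c(out, fasta)
  }
  invisible(out)
}

#' Read a gene_model_set back from GTF (+ optional BED / FASTA)
#'
#' Inverse of [write_gene_models()]; BED intervals are converted back to the
#' 0-based half-open convention used internally.
#'
#' @param gtf GTF path.
#' @param bed optional repeat BED path.
#' @param fasta optional genome FASTA path.
#' @return a `gene_model_set` (with empty repeats / NULL genome when the
#'   corresponding file is not given).
#' @export
read_gene_models <- function(gtf, bed = NULL, fasta = NULL) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as.data.frame(gr)
  gg <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gg$gene_id, chrom = as.character(gg$seqnames),
                      strand = as.character(gg$strand),
                      gene_start = gg$start, gene_end = gg$end,
                      is_snoRNA_host = !is.na(gg$snoRNA_host) & gg$snoRNA_host == "1")
  tt <- df[df$type == "transcript", ]
  transcripts <- data.frame(transcript_id = tt$transcript_id, gene_id = tt$gene_id,
                            tx_start = tt$start, tx_end = tt$end)
  ff <- df[df$type %in% c("exon", "five_prime_utr", "CDS", "three_prime_utr"), ]
  features <- data.frame(
    transcript_id = ff$transcript_id, gene_id = ff$gene_id,
    type = ifelse(ff$type == "five_prime_utr", "five_utr",
           ifelse(ff$type == "three_prime_utr", "three_utr", as.character(ff$type))),
    start = ff$start, end = ff$end)
  o <- order(genes$gene_start); genes <- genes[o, ]; rownames(genes) <- NULL
  repeats <- if (!is.null(bed)) {
    b <- as.data.frame(rtracklayer::import(bed, format = "bed"))
    data.frame(chrom = as.character(b$seqnames), start = b$start - 1L,
               end = b$end, class = b$name)
  } else data.frame(chrom = character(), start = integer(), end = integer(),
                    class = character())
  genome <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(genes = genes, transcripts = transcripts, features = features,
                 repeats = repeats, genome = genome), class = "gene_model_set")
}
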