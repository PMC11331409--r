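REGION_PRIORITY <- c("CDS", "five_utr", "three_utr", "exon", "intron")

#' Classify a position into a transcript-region category
#'
#' Implements the gene-anatomy scheme used for edited-site annotation:
#' positions between the database gene start and the first transcription
#' start site are `upstream`; positions after the last transcript end up to
#' the gene end are `downstream`; positions inside the transcribed body are
#' resolved across transcripts with the priority CDS > 5'UTR > 3'UTR >
#' exon > intron (exon-only transcripts contribute only `exon`/`intron`).
#' Coordinates are genomic 1-based; upstream/downstream are defined on
#' genomic coordinates (min transcript start / max transcript end across
#' the gene's transcripts), matching database attribute semantics.
#'
#' @param pos 1-based genomic position.
#' @param gm a `gene_model_set`.
#' @param gene_id the gene to classify against.
#' @return one of `"upstream"`, `"five_utr"`, `"CDS"`, `"three_utr"`,
#'   `"exon"`, `"intron"`, `"downstream"`.
#' @export
classify_region <- function(pos, gm, gene_id) {
  g <- gm$genes[gm$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene_id", call. = FALSE)
  if (pos < g$gene_start || pos > g$gene_end)
    stop("position outside the gene bounds", call. = FALSE)
  tx <- gm$transcripts[gm$transcripts$gene_id == gene_id, ]
  if (pos < min(tx$tx_start)) return("upstream")
  if (pos > max(tx$tx_end)) return("downstream")
  cats <- character()
  for (k in seq_len(nrow(tx))) {
    if (pos < tx$tx_start[k] || pos > tx$tx_end[k]) next
    f <- gm$features[gm$features$transcript_id == tx$transcript_id[k], ]
    typed <- f[f$type != "exon" & f$start <= pos & f$end >= pos, ]
    if (nrow(typed)) {
      cats <- c(cats, typed$type)
    } else if (any(f$type == "exon" & f$start <= pos & f$end >= pos)) {
      cats <- c(cats, "exon")
    } else {
      cats <- c(cats, "intron")
    }
  }
  if (!length(cats)) return("intron")  # between transcripts of the gene body
  REGION_PRIORITY[min(match(cats, REGION_PRIORITY))]
}

#' Assign a repeat class to a position
#'
#' Returns the class of the covering repeat interval. Repeat intervals use
#' the half-open convention: a position equal to an interval's end
#' coordinate lies outside it. Overlapping repeats resolve to the smallest
#' interval, ties to the alphabetically first class. Positions covered by
#' no repeat return `"none"`.
#'
#' @param pos genomic position.
#' @param repeats data.frame with `start`, `end` (half-open), `class`.
#' @return repeat class or `"none"`.
#' @export
assign_repeat <- function(pos, repeats) {
  hit <- which(repeats$start <= pos & pos < repeats$end)
  if (!length(hit)) return("none")
  w <- repeats$end[hit] - repeats$start[hit]
  hit <- hit[order(w, repeats$class[hit])]
  repeats$class[hit[1]]
}

# CDS genomic positions of a transcript in translation order
cds_positions <- function(gm, transcript_id) {
  f <- gm$features[gm$features$transcript_id == transcript_id &
                     gm$features$type == "CDS", ]
  if (nrow(f) == 0) return(integer())
  pos <- sort(unlist(lapply(seq_len(nrow(f)), function(k) f$start[k]:f$end[k])))
  gid <- f$gene_id[1]
  if (gm$genes$strand[gm$genes$gene_id == gid] == "-") pos <- rev(pos)
  pos
}

#' Coding consequence of an A-to-G edit under the I-as-G decoding rule
#'
#' Locates the edited adenosine within the CDS of a transcript, substitutes
#' G at its codon offset, and translates both codons with the standard
#' genetic code. Categories: `synonymous`, `missense`, `nonsense` (codon
#' gains a stop), `stop_retained` (stop stays a stop), `stop_loss`,
#' `start_loss` (initiator ATG edited).
#'
#' @param pos 1-based genomic position of the edited A (transcript sense).
#' @param gm a `gene_model_set` with its genome sequence.
#' @param transcript_id transcript whose CDS covers `pos`; if `NULL`, the
#'   first CDS-bearing transcript of `gene_id` covering the position is
#'   used.
#' @param gene_id used when `transcript_id` is `NULL`.
#' @return list with `consequence`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `codon_index` (1-based), `codon_offset` (0-2).
#' @export
codon_consequence <- function(pos, gm, transcript_id = NULL, gene_id = NULL) {
  stopifnot(!is.null(gm$genome))
  if (is.null(transcript_id)) {
    tx <- gm$transcripts[gm$transcripts$gene_id == gene_id, ]
    for (t in tx$transcript_id)
      if (pos %in% cds_positions(gm, t)) { transcript_id <- t; break }
    if (is.null(transcript_id))
      stop("position is not inside any CDS of the gene", call. = FALSE)
  }
  cpos <- cds_positions(gm, transcript_id)
  if (length(cpos) %% 3 != 0)
    stop("CDS length is not a multiple of 3", call. = FALSE)
  i <- match(pos, cpos)
  if (is.na(i)) stop("position is not inside the CDS", call. = FALSE)
  gid <- gm$features$gene_id[gm$features$transcript_id == transcript_id][1]
  strand <- gm$genes$strand[gm$genes$gene_id == gid]
  base_at <- function(p) {
    b <- as.character(Biostrings::subseq(gm$genome[[1]], p, p))
    if (strand == "-") chartr("ACGT", "TGCA", b) else b
  }
  if (base_at(pos) != "A")
    stop("reference base at the edited position is not A", call. = FALSE)
  ci <- (i - 1) %/% 3
  off <- (i - 1) %% 3
  codon_pos <- cpos[(ci * 3 + 1):(ci * 3 + 3)]
  ref_codon <- paste(vapply(codon_pos, base_at, ""), collapse = "")
  alt <- strsplit(ref_codon, "")[[1]]
  alt[off + 1] <- "G"
  alt_codon <- paste(alt, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  cons <- if (ci == 0 && ref_codon == "ATG") "start_loss"
    else if (ref_aa == "*" && alt_aa == "*") "stop_retained"
    else if (ref_aa == "*") "stop_loss"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  list(consequence = cons, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, codon_index = ci + 1L,
       codon_offset = off)
}

#' Annotate editing calls with region, repeat and consequence
#'
#' Maps each call to its covering gene, classifies its transcript region
#' and repeat class, and — for CDS sites with an A reference — the codon
#' consequence.
#'
#' @param calls editing-call data.frame (needs `chrom`, `pos`).
#' @param gm a `gene_model_set`.
#' @return the calls with `gene_id`, `region`, `repeat_class`,
#'   `consequence` columns (`consequence` is `"noncoding"` outside CDS).
#' @export
annotate_sites <- function(calls, gm) {
  g <- gm$genes
  gi <- vapply(calls$pos, function(p) {
    h <- which(g$gene_start <= p & p <= g$gene_end)
    if (length(h)) h[1] else NA_integer_
  }, 0L)
  calls$gene_id <- g$gene_id[gi]
  calls$region <- rep(NA_character_, nrow(calls))
  calls$repeat_class <- rep(NA_character_, nrow(calls))
  calls$consequence <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(gi[i])) next
    calls$region[i] <- classify_region(calls$pos[i], gm, calls$gene_id[i])
    calls$repeat_class[i] <- assign_repeat(calls$pos[i], gm$repeats)
    calls$consequence[i] <- if (calls$region[i] == "CDS" &&
                                !is.null(gm$genome)) {
      tryCatch(codon_consequence(calls$pos[i], gm,
                                 gene_id = calls$gene_id[i])$consequence,
               error = function(e) NA_character_)
    } else "noncoding"
  }
  calls
}

#' Region-by-repeat summary of annotated sites
#'
#' Cross-tabulates annotated calls by transcript-region category and repeat
#' class (including `none`); the marginals conserve the total number of
#' annotated sites. Also reports the number of unique genes carrying at
#' least one site.
#'
#' @param annotated output of [annotate_sites()].
#' @return list with `table` (region x repeat matrix), `n_sites`,
#'   `n_genes`.
#' @export
summarize_sites <- function(annotated) {
  ann <- annotated[!is.na(annotated$region), , drop = FALSE]
  regions <- c("upstream", "five_utr", "CDS", "three_utr", "intron", "exon",
               "downstream")
  rep_lv <- sort(unique(c("none", ann$repeat_class)))
  tab <- table(factor(ann$region, levels = regions),
               factor(ann$repeat_class, levels = rep_lv))
  list(table = unclass(tab), n_sites = nrow(ann),
       n_genes = length(unique(ann$gene_id)))
}
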