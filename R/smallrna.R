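SMALLRNA_CLASSES <- c("miRNA", "snoRNA", "RNY", "scaRNA", "SNHG", "other")

#' Per-class counts of significant small RNAs
#'
#' Summarises class-labelled differential results into up/down counts per
#' small-RNA class at the usual thresholds; the class totals sum to the
#' overall significant counts.
#'
#' @param results a [nb_wald()] result on small-RNA counts.
#' @param classes data.frame with `feature_id` and `class` (one of
#'   miRNA/snoRNA/RNY/scaRNA/SNHG/other).
#' @param fc fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame class, n_up, n_down, n_total, plus a `total` row.
#' @export
class_summary <- function(results, classes, fc = 1.5, alpha = 0.05) {
  if (!all(classes$class %in% SMALLRNA_CLASSES))
    stop("unknown small-RNA class label: ",
         paste(setdiff(classes$class, SMALLRNA_CLASSES), collapse = ", "),
         call. = FALSE)
  cls <- classes$class[match(results$gene_id, classes$feature_id)]
  if (anyNA(cls)) stop("every feature needs a class label", call. = FALSE)
  l2 <- log2(fc)
  sig <- !is.na(results$padj) & results$padj < alpha
  up <- sig & results$log2FC >= l2
  down <- sig & results$log2FC <= -l2
  out <- data.frame(class = SMALLRNA_CLASSES)
  out$n_up <- vapply(out$class, function(k) sum(up & cls == k), 0L)
  out$n_down <- vapply(out$class, function(k) sum(down & cls == k), 0L)
  out$n_total <- vapply(out$class, function(k) sum(cls == k), 0L)
  rbind(out, data.frame(class = "total", n_up = sum(up), n_down = sum(down),
                        n_total = length(cls)))
}

#' Read-length profile comparison between two groups
#'
#' Library-size-normalises per-length counts, then reports the per-length
#' log2 ratio of knockout to wild-type group means with a seeded bootstrap
#' confidence interval over replicates. Length bins empty in every sample
#' (or empty in one group) yield `NA`.
#'
#' @param counts integer matrix, rows = read lengths (rownames give nt),
#'   columns = samples.
#' @param meta data.frame with `sample` and `cell_line` (`wt`/`ko`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed seed of the bootstrap stream.
#' @return data.frame length, log2_ratio, ci_lo, ci_hi.
#' @export
length_profile_compare <- function(counts, meta, n_boot = 1000, conf = 0.95,
                                   seed = 1) {
  stopifnot(all(meta$sample == colnames(counts)))
  norm <- sweep(counts, 2, colSums(counts) / mean(colSums(counts)), `/`)
  wt <- which(meta$cell_line == "wt"); ko <- which(meta$cell_line == "ko")
  ratio_of <- function(wi, ki) {
    mw <- rowMeans(norm[, wi, drop = FALSE])
    mk <- rowMeans(norm[, ki, drop = FALSE])
    r <- log2(mk / mw)
    r[!is.finite(r)] <- NA
    r
  }
  est <- ratio_of(wt, ko)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      ratio_of(sample(wt, length(wt), replace = TRUE),
               sample(ko, length(ko), replace = TRUE)),
      numeric(nrow(counts)))
  })
  qs <- apply(boots, 1, function(r) {
    if (all(is.na(r))) return(c(NA_real_, NA_real_))
    stats::quantile(r, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  })
  data.frame(length = as.integer(rownames(counts)), log2_ratio = unname(est),
             ci_lo = qs[1, ], ci_hi = qs[2, ])
}
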