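#' Apply the editing-site filter cascade
#'
#' Labels each pileup site `kept` or `filtered:<reason>`, recording the
#' first failing reason in the fixed order: `low_coverage` (any sample
#' below `min_coverage` reads), `low_quality` (mean base quality below
#' `min_baseq`), `artifact_flag` (any read-start/end, splice-vicinity or
#' homopolymer flag), `non_AG` (reference is not A on the transcript sense,
#' or a non-G mismatch dominates). Sites with no mismatch at all are kept
#' with G as the implicit variant allele (their editing signal is simply
#' zero), so null sites stay in the denominator of downstream rate
#' estimates.
#'
#' @param pileup pileup data.frame (transcript-sense counts).
#' @param min_coverage minimum per-sample coverage (default 5 reads).
#' @param min_baseq minimum mean base quality (default 20).
#' @return the pileup with a `status` column (`kept` / `filtered:<reason>`).
#' @export
filter_sites <- function(pileup, min_coverage = 5, min_baseq = 20) {
  smp <- pileup_samples(pileup)
  if (!all(pileup$ref_base %in% c("A", "C", "G", "T")))
    stop("unknown ref_base in pileup", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  tot <- sapply(bases, function(b)
    rowSums(as.matrix(pileup[, paste0(smp, "_", b), drop = FALSE])))
  if (is.null(dim(tot))) tot <- matrix(tot, nrow = 1, dimnames = list(NULL, bases))
  cov <- matrix(0, nrow(pileup), length(smp))
  for (j in seq_along(smp))
    cov[, j] <- rowSums(as.matrix(pileup[, paste0(smp[j], "_", bases)]))
  low_cov <- apply(cov < min_coverage, 1, any)
  low_q <- pileup$mean_baseq < min_baseq
  flagged <- !(pileup$flags %in% c(".", "", NA))
  g_tot <- tot[, "G"]
  other_max <- pmax(tot[, "C"], tot[, "T"])
  non_ag <- pileup$ref_base != "A" | other_max > g_tot
  status <- rep("kept", nrow(pileup))
  status[non_ag] <- "filtered:non_AG"
  status[flagged] <- "filtered:artifact_flag"
  status[low_q] <- "filtered:low_quality"
  status[low_cov] <- "filtered:low_coverage"
  pileup$status <- status
  pileup
}

# beta-binomial log-likelihood at fixed overdispersion rho
bb_loglik <- function(g, n, p, rho) {
  if (rho < 1e-8)
    return(sum(stats::dbinom(g, n, min(max(p, 1e-12), 1 - 1e-12), log = TRUE)))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  sum(lbeta(g + a, n - g + b) - lbeta(a, b) + lchoose(n, g))
}

bb_mle <- function(g, n, rho) {
  if (rho < 1e-8) {
    p <- sum(g) / sum(n)
    return(list(p = p, ll = bb_loglik(g, n, p, rho)))
  }
  opt <- stats::optimize(function(p) bb_loglik(g, n, p, rho),
                         interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                         tol = 1e-9)
  list(p = opt$maximum, ll = opt$objective)
}

#' Beta-binomial likelihood-ratio score for differential base composition
#'
#' Compares the A/G base composition of a site between two replicate
#' groups. The null model shares one beta-binomial (the two-category
#' Dirichlet-multinomial) composition across all samples; the alternative
#' gives each group its own composition. The overdispersion is estimated
#' once by method of moments from within-group replicate variability
#' (group-specific means, so a true group difference does not inflate it)
#' and held fixed in both models, making this a one-degree-of-freedom test
#' on the editing frequency. The score is the log likelihood ratio, so the
#' workflow threshold of 2.00 corresponds to a chi-square(1) deviance of 4
#' (a ~4.6% null exceedance rate).
#'
#' @param a_counts,g_counts named or ordered integer vectors of A and G
#'   counts per sample.
#' @param groups factor/character of the same length giving each sample's
#'   group; exactly two groups.
#' @return non-negative score, with attributes `p_hat` (per-group pooled G
#'   frequencies) and `rho` (the moment overdispersion estimate).
#' @export
dm_score <- function(a_counts, g_counts, groups) {
  stopifnot(length(a_counts) == length(g_counts),
            length(groups) == length(a_counts))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  n <- a_counts + g_counts
  for (g in lv) {
    if (sum(groups == g) < 2)
      stop("at least two replicates per group are required", call. = FALSE)
    if (sum(n[groups == g]) == 0)
      stop(sprintf("zero total coverage in group '%s'", g), call. = FALSE)
  }
  # moment estimate of the overdispersion factor from replicate scatter
  x2 <- 0; df <- 0
  for (g in lv) {
    i <- groups == g & n > 0
    if (sum(i) < 2) next
    ph <- sum(g_counts[i]) / sum(n[i])
    if (ph <= 0 || ph >= 1) next
    x2 <- x2 + sum((g_counts[i] - n[i] * ph)^2 / (n[i] * ph * (1 - ph)))
    df <- df + sum(i) - 1
  }
  rho <- 0
  if (df > 0) {
    chat <- x2 / df
    nbar <- mean(n[n > 0])
    if (nbar > 1) rho <- max(0, min(0.99, (chat - 1) / (nbar - 1)))
  }
  null <- bb_mle(g_counts, n, rho)
  alt <- lapply(lv, function(g) bb_mle(g_counts[groups == g], n[groups == g], rho))
  stat <- max(0, sum(vapply(alt, `[[`, 0, "ll")) - null$ll)
  freqs <- vapply(lv, function(g)
    sum(g_counts[groups == g]) / sum(n[groups == g]), 0)
  structure(stat, p_hat = stats::setNames(freqs, lv), rho = rho)
}

#' Call differential A-to-G editing across a pileup table
#'
#' Runs the filter cascade, scores every kept site with [dm_score()], and
#' passes sites whose score reaches `threshold` (default 2.00, the
#' stringent workflow setting for triplicate comparisons). Group
#' frequencies are pooled over replicates (sum of G over sum of A+G), which
#' is robust at low coverage.
#'
#' @param pileup pileup data.frame.
#' @param groups named list mapping the two group names to their sample
#'   names, e.g. `list(wt = c("wt_1", ...), ko = c("ko_1", ...))`.
#' @param threshold passing score threshold.
#' @param min_coverage,min_baseq forwarded to [filter_sites()].
#' @return data.frame of editing calls: site columns, `stat`, pooled
#'   `<group>_freq` columns, `status` (`pass` / `fail` / `filtered:<reason>`),
#'   with a `summary` attribute counting sites per status.
#' @export
call_differential_editing <- function(pileup, groups, threshold = 2.00,
                                      min_coverage = 5, min_baseq = 20) {
  stopifnot(is.list(groups), length(groups) == 2)
  fl <- filter_sites(pileup, min_coverage, min_baseq)
  gname <- names(groups)
  calls <- fl[, c("chrom", "pos", "strand", "ref_base", "status")]
  calls$stat <- NA_real_
  for (g in gname) calls[[paste0(g, "_freq")]] <- NA_real_
  kept <- which(fl$status == "kept")
  smp <- unlist(groups, use.names = FALSE)
  grp <- rep(gname, vapply(groups, length, 0L))
  a_mat <- as.matrix(fl[, paste0(smp, "_A"), drop = FALSE])
  g_mat <- as.matrix(fl[, paste0(smp, "_G"), drop = FALSE])
  for (i in kept) {
    s <- dm_score(a_mat[i, ], g_mat[i, ], grp)
    calls$stat[i] <- as.numeric(s)
    ph <- attr(s, "p_hat")
    for (g in gname) calls[[paste0(g, "_freq")]][i] <- ph[[g]]
  }
  calls$status[kept] <- ifelse(calls$stat[kept] >= threshold, "pass", "fail")
  tab <- table(calls$status)
  attr(calls, "summary") <- list(
    n_sites = nrow(calls), n_pass = sum(calls$status == "pass"),
    n_fail = sum(calls$status == "fail"),
    n_filtered = sum(startsWith(calls$status, "filtered")),
    by_status = as.list(tab), threshold = threshold)
  calls
}

#' Retain sites edited only in the foreground group
#'
#' Keeps passing calls whose pooled frequency is at least `min_freq` in the
#' foreground group (`wt` by convention) and at most `max_bg_freq` in the
#' background group — the "edited only in wild type, not in the knockout"
#' selection. The background ceiling defaults to 0.01: at a pooled
#' background coverage of ~150x a single sequencing-error read already
#' yields a frequency of ~0.007, so a ceiling at the per-base error rate
#' itself would reject ~14% of genuinely foreground-only sites; 0.01 stays
#' an order of magnitude below the typical 0.20 signal while tolerating
#' one stray error read.
#'
#' @param calls output of [call_differential_editing()].
#' @param fg,bg names of the foreground / background groups.
#' @param min_freq minimum foreground pooled frequency.
#' @param max_bg_freq maximum background pooled frequency.
#' @return the retained subset, with an `n_retained` attribute.
#' @export
wt_only_filter <- function(calls, fg = "wt", bg = "ko",
                           min_freq = 0.005, max_bg_freq = 0.01) {
  fc <- paste0(fg, "_freq"); bc <- paste0(bg, "_freq")
  if (!all(c(fc, bc) %in% names(calls)))
    stop("calls lack the required group frequency columns", call. = FALSE)
  keep <- calls$status == "pass" &
    calls[[fc]] >= min_freq & calls[[bc]] <= max_bg_freq
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Alu editing index
#'
#' Coverage-weighted aggregate editing level: the sum of G counts divided
#' by the sum of A+G counts over reference-A positions that fall inside
#' Alu (SINE) intervals, pooled over the given samples.
#'
#' @param pileup pileup data.frame.
#' @param alu_intervals data.frame with `start`, `end` in 0-based half-open
#'   (BED) convention, optionally a `class` column (rows with
#'   `class == "SINE"` are used when present).
#' @param samples samples to pool (default: all).
#' @return a single number in [0, 1].
#' @export
compute_aei <- function(pileup, alu_intervals, samples = pileup_samples(pileup)) {
  iv <- alu_intervals
  if (!is.null(iv$class)) iv <- iv[iv$class == "SINE", , drop = FALSE]
  if (nrow(iv) == 0) stop("no Alu intervals supplied", call. = FALSE)
  # half-open repeat intervals: start <= pos < end
  hit <- IRanges::overlapsAny(
    IRanges::IRanges(pileup$pos, pileup$pos),
    IRanges::IRanges(iv$start, iv$end - 1L))
  sel <- pileup[hit & pileup$ref_base == "A", , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no reference-A positions overlap the Alu intervals", call. = FALSE)
  a <- sum(as.matrix(sel[, paste0(samples, "_A"), drop = FALSE]))
  g <- sum(as.matrix(sel[, paste0(samples, "_G"), drop = FALSE]))
  if (a + g == 0) stop("zero A+G coverage over Alu positions", call. = FALSE)
  g / (a + g)
}
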