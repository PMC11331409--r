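#' Choose planted editing sites inside synthetic gene bodies
#'
#' Samples genomic positions whose transcript-sense base is A (or C for the
#' negative-control C-to-T sites) within gene bounds and assigns each to a
#' truth group: `wt_only` (edited only in the wild-type group), `ko_only`,
#' `both`, `none` (null site), or `ct` (C-to-T change, used to verify the
#' A-to-G-only restriction).
#'
#' @param gm a `gene_model_set` from [gen_gene_models()].
#' @param n_null,n_wt_only,n_ko_only,n_both,n_ct site counts per group.
#' @param freq planted editing frequency for edited groups.
#' @param seed integer seed.
#' @return data.frame with chrom, pos, strand, ref_base (transcript sense),
#'   gene_id, group, freq.
#' @export
plant_edit_sites <- function(gm, n_null = 0, n_wt_only = 0, n_ko_only = 0,
                             n_both = 0, n_ct = 0, freq = 0.20, seed = 1) {
  stopifnot(inherits(gm, "gene_model_set"), !is.null(gm$genome))
  with_seed(seed, {
    seqv <- strsplit(as.character(gm$genome[[1]]), "")[[1]]
    pick <- function(n, sense_base) {
      if (n == 0) return(NULL)
      out <- vector("list", n)
      for (k in seq_len(n)) {
        repeat {
          gi <- sample.int(nrow(gm$genes), 1)
          g <- gm$genes[gi, ]
          want <- if (g$strand == "+") sense_base else
            chartr("ACGT", "TGCA", sense_base)
          cand <- g$gene_start:g$gene_end
          cand <- cand[seqv[cand] == want]
          if (length(cand)) {
            out[[k]] <- data.frame(chrom = "chr1", pos = sample(cand, 1),
                                   strand = g$strand, ref_base = sense_base,
                                   gene_id = g$gene_id)
            break
          }
        }
      }
      do.call(rbind, out)
    }
    groups <- c(none = n_null, wt_only = n_wt_only, ko_only = n_ko_only,
                both = n_both, ct = n_ct)
    res <- list()
    for (grp in names(groups)) {
      if (groups[[grp]] == 0) next
      d <- pick(groups[[grp]], if (grp == "ct") "C" else "A")
      d$group <- grp
      d$freq <- if (grp == "none") 0 else freq
      res[[grp]] <- d
    }
    out <- do.call(rbind, res)
    out <- out[!duplicated(out$pos), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-site base-count pileups for two replicate groups
#'
#' Emulates strand-resolved RNA-seq pileups for `wt` and `ko` groups with
#' `n_replicates` samples each. Per site and sample, coverage is Poisson
#' (mean `coverage_mean`); the variant base (G for A sites, T for C sites)
#' is Binomial(coverage, freq) in edited groups and
#' Binomial(coverage, error_rate) otherwise; the two remaining bases carry
#' error-rate noise. Counts are reported in transcript sense (minus-strand
#' sites are already flipped, mirroring a stranded first-strand library). A
#' configurable fraction of sites receives artifact flags or low base
#' quality so the filter cascade is exercised.
#'
#' @param gm a `gene_model_set`.
#' @param config a [sim_config()].
#' @param truth_spec planted-site data.frame from [plant_edit_sites()].
#' @param seed integer seed.
#' @return list with `pileup` (data.frame: chrom, pos, strand, ref_base,
#'   mean_baseq, flags, then `<sample>_A/C/G/T` count columns), `samples`
#'   (data.frame sample/group) and `truth` (the planted spec + seed).
#' @export
gen_pileups <- function(gm, config, truth_spec, seed) {
  stopifnot(inherits(gm, "gene_model_set"), inherits(config, "sim_config"))
  need <- c("chrom", "pos", "strand", "ref_base", "gene_id", "group", "freq")
  if (!all(need %in% names(truth_spec)))
    stop("truth_spec must come from plant_edit_sites() or carry its columns")
  idx <- match(truth_spec$gene_id, gm$genes$gene_id)
  if (anyNA(idx) ||
      any(truth_spec$pos < gm$genes$gene_start[idx] |
          truth_spec$pos > gm$genes$gene_end[idx]))
    stop("planted site outside the annotated gene bounds")
  with_seed(seed, {
    nrep <- config$n_replicates
    samples <- data.frame(
      sample = c(paste0("wt_", seq_len(nrep)), paste0("ko_", seq_len(nrep))),
      group = rep(c("wt", "ko"), each = nrep))
    ns <- nrow(truth_spec)
    alt_of <- c(A = "G", C = "T")
    bases <- c("A", "C", "G", "T")
    cnt <- matrix(0L, ns, 4 * nrow(samples))
    colnames(cnt) <- as.vector(t(outer(samples$sample, bases, paste, sep = "_")))
    for (j in seq_len(nrow(samples))) {
      grp <- samples$group[j]
      cov <- stats::rpois(ns, config$coverage_mean)
      edited <- truth_spec$group == "both" |
        (truth_spec$group == "wt_only" & grp == "wt") |
        (truth_spec$group == "ko_only" & grp == "ko") |
        (truth_spec$group == "ct" & grp == "wt")
      p_alt <- ifelse(edited, truth_spec$freq, config$error_rate)
      alt <- stats::rbinom(ns, cov, p_alt)
      o1 <- stats::rbinom(ns, pmax(cov - alt, 0L), config$error_rate)
      o2 <- stats::rbinom(ns, pmax(cov - alt - o1, 0L), config$error_rate)
      ref <- cov - alt - o1 - o2
      for (i in seq_len(ns)) {
        rb <- truth_spec$ref_base[i]
        ab <- alt_of[[rb]]
        others <- setdiff(bases, c(rb, ab))
        v <- stats::setNames(integer(4), bases)
        v[rb] <- ref[i]; v[ab] <- alt[i]; v[others] <- c(o1[i], o2[i])
        cnt[i, 4 * (j - 1) + 1:4] <- v
      }
    }
    flags <- rep(".", ns)
    fl <- stats::runif(ns) < config$flag_rate
    flags[fl] <- sample(c("near_read_end", "near_splice", "homopolymer"),
                        sum(fl), replace = TRUE)
    baseq <- round(stats::rnorm(ns, 35, 2), 1)
    lq <- stats::runif(ns) < config$lowq_rate
    baseq[lq] <- round(stats::rnorm(sum(lq), 15, 2), 1)
    pileup <- cbind(
      data.frame(chrom = truth_spec$chrom, pos = truth_spec$pos,
                 strand = truth_spec$strand, ref_base = truth_spec$ref_base,
                 mean_baseq = baseq, flags = flags),
      as.data.frame(cnt))
    o <- order(pileup$pos); pileup <- pileup[o, ]; rownames(pileup) <- NULL
    truth <- truth_spec[o, ]; rownames(truth) <- NULL
    truth$flags <- pileup$flags; truth$mean_baseq <- pileup$mean_baseq
    list(pileup = pileup, samples = samples,
         truth = list(sites = truth, seed = seed))
  })
}

#' Write / read the pileup TSV dialect
#'
#' @param x a pileup data.frame as returned in `gen_pileups()$pileup`.
#' @param path file path.
#' @return `write_pileup` the path, `read_pileup` the data.frame.
#' @export
write_pileup <- function(x, path) write_tsv(x, path)

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  p <- read_tsv(path)
  p$flags <- as.character(p$flags)
  p
}

#' Sample names present in a pileup table
#' @param pileup a pileup data.frame.
#' @return character vector of sample names.
#' @export
pileup_samples <- function(pileup) {
  cn <- grep("_A$", names(pileup), value = TRUE)
  sub("_A$", "", cn)
}
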