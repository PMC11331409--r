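#' Simulate a gene-level RNA-seq count matrix with planted effects
#'
#' Counts are negative-binomial with
#' log2 mu = baseline + cell-line effect + fraction effect + interaction,
#' multiplied by planted per-sample size factors (log-uniform in
#' `config$sf_range`). The interaction term is added to the (ko, unbound)
#' design cell, so a planted `interaction_l2fc` equals the population value
#' of log2[(unbound/polysomal)_ko / (unbound/polysomal)_wt]: positive values
#' mean unbound enrichment (retarded polysome loading) in the knockout and
#' negative values mean enhanced polysome loading, matching the sign
#' convention of the downstream interaction test.
#'
#' @param genes gene identifiers (character) or a single integer, expanded
#'   to `gene0001...`.
#' @param effects optional data.frame with `gene_id` plus any of
#'   `cell_line_l2fc` (ko vs wt) and `interaction_l2fc`; genes absent from
#'   it carry zero effects.
#' @param config a [sim_config()]; `dispersion` must be non-negative.
#' @param seed integer seed.
#' @param fractions fractions present in the design; `"total"` alone gives
#'   the two-group total-RNA design, `c("unbound","polysomal")` the 2x2
#'   interaction design.
#' @param fraction_sd per-gene log2 sd of random fraction main effects
#'   (unbound vs polysomal); exercises normalisation/PCA without touching
#'   the interaction null.
#' @return list with `counts` (integer matrix genes x samples), `meta`
#'   (sample, cell_line, fraction, replicate) and `truth` (size factors,
#'   per-gene effect table, baseline means, seed).
#' @export
gen_count_matrix <- function(genes, effects = NULL, config = sim_config(),
                             seed = 1, fractions = c("unbound", "polysomal"),
                             fraction_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) stop("negative dispersion", call. = FALSE)
  if (is.numeric(genes) && length(genes) == 1)
    genes <- sprintf("gene%04d", seq_len(genes))
  ng <- length(genes)
  with_seed(seed, {
    nrep <- config$n_replicates
    meta <- expand.grid(replicate = seq_len(nrep), fraction = fractions,
                        cell_line = c("wt", "ko"), stringsAsFactors = FALSE)
    meta$sample <- paste(meta$cell_line, meta$fraction, meta$replicate, sep = "_")
    meta <- meta[, c("sample", "cell_line", "fraction", "replicate")]
    nsmp <- nrow(meta)
    sf <- exp(stats::runif(nsmp, log(config$sf_range[1]), log(config$sf_range[2])))
    names(sf) <- meta$sample
    base_mu <- stats::rlnorm(ng, config$mu_meanlog, config$mu_sdlog)
    eff <- data.frame(gene_id = genes, cell_line_l2fc = 0, interaction_l2fc = 0)
    if (!is.null(effects)) {
      m <- match(effects$gene_id, genes)
      if (anyNA(m)) stop("effects reference unknown gene ids")
      if (!is.null(effects$cell_line_l2fc))
        eff$cell_line_l2fc[m] <- effects$cell_line_l2fc
      if (!is.null(effects$interaction_l2fc))
        eff$interaction_l2fc[m] <- effects$interaction_l2fc
    }
    frac_eff <- if (length(fractions) > 1)
      stats::rnorm(ng, 0, fraction_sd) else rep(0, ng)
    l2mu <- matrix(log2(base_mu), ng, nsmp)
    for (j in seq_len(nsmp)) {
      is_ko <- meta$cell_line[j] == "ko"
      is_unb <- meta$fraction[j] == "unbound"
      l2mu[, j] <- l2mu[, j] +
        (if (is_ko) eff$cell_line_l2fc else 0) +
        (if (is_unb) frac_eff else 0) +
        (if (is_ko && is_unb) eff$interaction_l2fc else 0)
    }
    mu <- sweep(2^l2mu, 2, sf, `*`)
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) stats::rnbinom(ng * nsmp, mu = mu, size = size)
      else stats::rpois(ng * nsmp, mu),
      ng, nsmp, dimnames = list(genes, meta$sample))
    list(counts = counts, meta = meta,
         truth = list(size_factors = sf, effects = eff,
                      fraction_l2fc = frac_eff, base_mu = base_mu, seed = seed))
  })
}

#' Simulate class-labelled small-RNA counts with planted class shifts
#'
#' Runs the same negative-binomial machinery on a two-group (wt vs ko,
#' total RNA) design; every member of a shifted class receives the class
#' log2 effect as its cell-line effect. Defaults plant the observed
#' pattern: snoRNAs up, Y RNAs down in the knockout.
#'
#' @param n_features number of small-RNA features.
#' @param class_shifts named numeric, class -> log2 effect (ko vs wt).
#' @param class_probs sampling weights of classes
#'   miRNA/snoRNA/RNY/scaRNA/SNHG/other.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `counts`, `meta`, `classes` (feature_id, class) and
#'   `truth`.
#' @export
gen_smallrna_counts <- function(n_features = 300,
                                class_shifts = c(snoRNA = 1.5, RNY = -1.5),
                                class_probs = c(miRNA = 0.45, snoRNA = 0.15,
                                                RNY = 0.05, scaRNA = 0.05,
                                                SNHG = 0.05, other = 0.25),
                                config = sim_config(), seed = 1) {
  with_seed(seed, {
    cls <- sample(names(class_probs), n_features, replace = TRUE,
                  prob = class_probs)
    ids <- sprintf("sRNA%04d", seq_len(n_features))
    shift <- ifelse(cls %in% names(class_shifts), class_shifts[cls], 0)
    inner_seed <- sample.int(.Machine$integer.max, 1)
    sim <- gen_count_matrix(
      ids, effects = data.frame(gene_id = ids, cell_line_l2fc = shift),
      config = config, seed = inner_seed, fractions = "total")
    sim$classes <- data.frame(feature_id = ids, class = cls)
    sim$truth$class_shifts <- class_shifts
    sim$truth$seed <- seed
    sim
  })
}

#' Simulate read-length-binned small-RNA counts
#'
#' One count per (length bin, sample); a smooth baseline length profile with
#' NB noise, with a planted log2 depletion/enrichment in the knockout at the
#' given bins (default: 2-fold depletion at 30 and 37 nt, the sizes at which
#' Y RNA fragments change).
#'
#' @param depleted_bins read lengths (nt) shifted in the knockout.
#' @param l2fc planted log2 fold change (ko vs wt) at those bins.
#' @param lengths length range of the profile.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `counts` (matrix length x samples), `meta`, `truth`.
#' @export
gen_length_counts <- function(depleted_bins = c(30, 37), l2fc = -1,
                              lengths = 15:50, config = sim_config(),
                              seed = 1) {
  with_seed(seed, {
    nrep <- config$n_replicates
    meta <- data.frame(
      sample = c(paste0("wt_", seq_len(nrep)), paste0("ko_", seq_len(nrep))),
      cell_line = rep(c("wt", "ko"), each = nrep))
    # unimodal baseline peaking near 22 nt (miRNA-sized reads dominate)
    base <- 5e4 * stats::dnorm(lengths, 22, 5) + 200
    shift <- ifelse(lengths %in% depleted_bins, l2fc, 0)
    sf <- exp(stats::runif(nrow(meta), log(config$sf_range[1]),
                           log(config$sf_range[2])))
    mu <- outer(base, sf)
    for (j in seq_len(nrow(meta)))
      if (meta$cell_line[j] == "ko") mu[, j] <- mu[, j] * 2^shift
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     nrow = length(lengths),
                     dimnames = list(lengths, meta$sample))
    list(counts = counts, meta = meta,
         truth = list(depleted_bins = depleted_bins, l2fc = l2fc,
                      size_factors = sf, seed = seed))
  })
}
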