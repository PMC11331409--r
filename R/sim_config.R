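#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with the study's
#' defaults: three biological replicates per group, a per-base sequencing
#' error rate of 0.001, a planted editing frequency of 0.20 (the frequency
#' reported for the edited miRNA nucleotides), site coverage drawn from a
#' Poisson with mean 50, and adherent-cell areas drawn log-normally around
#' the reported medians of 6406 px (wt) and 8472 px (ADAR1 KO), a 32% ratio.
#'
#' @param n_genes number of genes in the synthetic annotation.
#' @param n_replicates biological replicates per group (>= 2).
#' @param error_rate per-base sequencing error rate in [0,1].
#' @param editing_frequency default planted editing frequency in [0,1].
#' @param coverage_mean mean of the Poisson per-sample site coverage.
#' @param dispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); must be non-negative.
#' @param mu_meanlog,mu_sdlog log-normal parameters of per-gene baseline
#'   mean counts.
#' @param sf_range range of planted per-sample size factors; factors are
#'   drawn log-uniformly within it.
#' @param flag_rate fraction of pileup sites carrying a read-level artifact
#'   flag (near_read_end / near_splice / homopolymer).
#' @param lowq_rate fraction of pileup sites with mean base quality below 20.
#' @param median_area_wt,median_area_ko median cell areas in pixels of the
#'   two simulated populations.
#' @param area_sdlog log-scale standard deviation of cell areas.
#' @param n_cells cells per simulated image population.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 50, n_replicates = 3,
                       error_rate = 0.001, editing_frequency = 0.20,
                       coverage_mean = 50, dispersion = 0.02,
                       mu_meanlog = log(200), mu_sdlog = 1.2,
                       sf_range = c(0.5, 2),
                       flag_rate = 0.05, lowq_rate = 0.02,
                       median_area_wt = 6406, median_area_ko = 8472,
                       area_sdlog = 0.35, n_cells = 60) {
  stop_if_not_scalar_count(n_genes, "n_genes")
  stop_if_not_scalar_count(n_replicates, "n_replicates")
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  for (nm in c("error_rate", "editing_frequency", "flag_rate", "lowq_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a rate in [0, 1]", nm), call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  if (coverage_mean <= 0) stop("coverage_mean must be positive", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    error_rate = error_rate, editing_frequency = editing_frequency,
    coverage_mean = coverage_mean, dispersion = dispersion,
    mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog, sf_range = sf_range,
    flag_rate = flag_rate, lowq_rate = lowq_rate,
    median_area_wt = median_area_wt, median_area_ko = median_area_ko,
    area_sdlog = area_sdlog, n_cells = as.integer(n_cells)
  ), class = "sim_config")
}
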