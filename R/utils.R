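#' Derive a stage-specific random seed from a master seed
#'
#' Each pipeline stage draws from its own seeded stream so that enabling or
#' disabling one stage never perturbs the randomness of another. The stage
#' seed is a deterministic hash of the master seed and the stage name,
#' reduced modulo 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param stage character stage name (e.g. "pileup", "counts").
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' library code never clobbers user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# write a data.frame as a plain TSV (no quoting, no row names)
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", ...)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}
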