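#' Build a 2x2 membership table over a gene universe
#'
#' Crosses a result group (e.g. more-abundant, retarded) with a gene
#' feature (e.g. edited, snoRNA host) over the universe of tested genes.
#' Genes absent from the feature map default to `FALSE`.
#'
#' @param results a [nb_wald()] result (for `more_abundant`/`less_abundant`
#'   with thresholds `fc`, `alpha`) or a [classify_translation()] result
#'   (for `retarded`/`enhanced`).
#' @param feature_map data.frame with `gene_id` and logical `flag`.
#' @param group_spec one of `"more_abundant"`, `"less_abundant"`,
#'   `"retarded"`, `"enhanced"`.
#' @param fc,alpha thresholds used for the abundance groups.
#' @return list with logical vectors `in_group`, `has_feature` (named by
#'   gene), the 2x2 `cells` (a = feature&group, b = feature only,
#'   c = group only, d = neither) and the Venn-style `overlap` counts.
#' @export
build_membership <- function(results, feature_map, group_spec,
                             fc = 1.5, alpha = 0.05) {
  valid <- c("more_abundant", "less_abundant", "retarded", "enhanced")
  if (!group_spec %in% valid)
    stop("group_spec must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  universe <- results$gene_id
  in_group <- switch(group_spec,
    more_abundant = !is.na(results$padj) & results$padj < alpha &
      results$log2FC >= log2(fc),
    less_abundant = !is.na(results$padj) & results$padj < alpha &
      results$log2FC <= -log2(fc),
    retarded = results$class == "retarded",
    enhanced = results$class == "enhanced")
  has_feature <- universe %in% feature_map$gene_id[feature_map$flag]
  names(in_group) <- names(has_feature) <- universe
  cells <- c(a = sum(has_feature & in_group),
             b = sum(has_feature & !in_group),
             c = sum(!has_feature & in_group),
             d = sum(!has_feature & !in_group))
  list(in_group = in_group, has_feature = has_feature, cells = cells,
       overlap = c(feature_and_group = unname(cells["a"]),
                   feature_only = unname(cells["b"]),
                   group_only = unname(cells["c"])))
}

#' Membership odds by single-predictor logistic regression
#'
#' Fits logit P(in_group) = b0 + b1 * has_feature and reports exp(b1) with
#' its Wald p-value. With all four 2x2 cells positive this equals the
#' cross-product odds ratio (a*d)/(b*c); with a zero cell the
#' Haldane-Anscombe 0.5 correction is applied to all cells (flagged) and
#' the Wald test uses the corrected log-odds standard error.
#'
#' @param in_group,has_feature logical vectors over the same gene universe.
#' @return list with `odds_ratio`, `p` (Wald), `cells`, `corrected`.
#' @export
odds_membership <- function(in_group, has_feature) {
  stopifnot(length(in_group) == length(has_feature))
  if (anyNA(in_group) || anyNA(has_feature))
    stop("membership vectors must not contain NA", call. = FALSE)
  if (length(unique(has_feature)) < 2 || length(unique(in_group)) < 2)
    stop("degenerate membership table: a margin is constant", call. = FALSE)
  cells <- c(a = sum(has_feature & in_group), b = sum(has_feature & !in_group),
             c = sum(!has_feature & in_group), d = sum(!has_feature & !in_group))
  if (all(cells > 0)) {
    fit <- stats::glm(in_group ~ has_feature, family = stats::binomial())
    sm <- stats::summary.glm(fit)$coefficients
    or <- exp(unname(sm["has_featureTRUE", "Estimate"]))
    p <- unname(sm["has_featureTRUE", "Pr(>|z|)"])
    corrected <- FALSE
  } else {
    cc <- cells + 0.5
    lor <- log(cc["a"] * cc["d"] / (cc["b"] * cc["c"]))
    se <- sqrt(sum(1 / cc))
    or <- unname(exp(lor))
    p <- unname(2 * stats::pnorm(-abs(lor / se)))
    corrected <- TRUE
  }
  list(odds_ratio = or, p = p, cells = cells, corrected = corrected)
}
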