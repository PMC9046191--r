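#' Remove genes with low total counts
#'
#' Drops genes whose total count across all samples is strictly below
#' `min_total` (default 10), preserving row order. This is the conventional
#' pre-filter applied before differential-expression testing.
#'
#' @param counts genes x samples numeric matrix.
#' @param min_total minimum total count required to keep a gene.
#' @return the filtered count matrix.
#' @export
prefilter_low_counts <- function(counts, min_total = 10) {
  check_counts(counts)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over genes with a positive geometric mean across samples, of that
#' sample's count divided by the gene's geometric mean. Multiplying one
#' sample's counts by c multiplies its factor by c.
#'
#' @param counts genes x samples numeric matrix; at least one gene must have
#'   all-positive counts.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(2, 2, 8, 8), nrow = 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m)  # 0.5, 2
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has all-positive counts; median-of-ratios size factors ",
      "are undefined (a pseudo-reference fallback is not implemented)",
      call. = FALSE)
  apply(logc[use, , drop = FALSE], 2L, function(lc) exp(median(lc - loggeo[use])))
}

#' Simplified negative-binomial Wald test for two-group differential expression
#'
#' A deliberately simple reimplementation of the NB Wald workflow: counts
#' are normalized by [size_factors()], group means are compared on the log2
#' scale with a pseudo-mean offset `c0 = 0.5` (mandatory for structural
#' zeros), a per-gene NB dispersion is estimated by method of moments from
#' the within-group variance of normalized counts, the standard error of the
#' log2 fold change comes from the delta method on the NB group means, and
#' two-sided p values are taken from the standard normal with
#' Benjamini-Hochberg correction across tested genes.
#'
#' With two or three replicates per group the per-gene variance estimate has
#' very few degrees of freedom, so raw method-of-moments dispersions are
#' floored at the experiment-wide median dispersion (and at 1e-8): this
#' guards against chance variance underestimation that would otherwise give
#' the Wald statistic heavy t-like tails under the null, while leaving
#' strongly separated genes significant. There is no per-gene shrinkage,
#' outlier handling, independent filtering or fold-change moderation, and
#' the numerics are not those of a full GLM fit.
#'
#' A gene is flagged significant when `|log2FC| > lfc_cut` and its adjusted
#' p value is strictly below `alpha` (defaults: more than two-fold change,
#' adjusted p < 1e-4).
#'
#' @param counts pre-filtered genes x samples count matrix (round
#'   pseudo-alignment estimates to integers first).
#' @param groups factor or character vector assigning each column to one of
#'   exactly two groups, each with at least two replicates. The fold change
#'   is the first group (in order of first appearance) over the second.
#' @param lfc_cut minimum absolute log2 fold change for the significance
#'   flag.
#' @param alpha adjusted-p-value cutoff for the significance flag.
#' @return a data.frame with one row per gene: `gene_id`, `base_mean` (mean
#'   normalized count), `log2fc`, `se`, `stat`, `pvalue`, `padj`,
#'   `significant`.
#' @export
nb_wald_test <- function(counts, groups, lfc_cut = 1, alpha = 1e-4) {
  if (nrow(counts) == 0L)
    stop("no genes left to test (empty count matrix)", call. = FALSE)
  check_counts(counts)
  if (length(groups) != ncol(counts))
    stop("'groups' must label every column of 'counts'", call. = FALSE)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 replicates", call. = FALSE)

  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  ia <- groups == levels(groups)[1L]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)

  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  m_all <- (na * ma + nb * mb) / (na + nb)

  # pooled within-group variance, na + nb - 2 df
  ss <- rowSums((norm[, ia, drop = FALSE] - ma)^2) +
    rowSums((norm[, ib, drop = FALSE] - mb)^2)
  s2 <- ss / (na + nb - 2L)

  alpha_raw <- ifelse(m_all > 0, (s2 - m_all) / m_all^2, 0)
  alpha_floor <- max(median(alpha_raw[m_all > 0]), 1e-8)
  disp <- pmax(alpha_raw, alpha_floor)

  c0 <- 0.5
  log2fc <- log2((ma + c0) / (mb + c0))
  var_ma <- (ma + disp * ma^2) / na
  var_mb <- (mb + disp * mb^2) / nb
  se <- sqrt(var_ma / (ma + c0)^2 + var_mb / (mb + c0)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(stat))
  padj <- p.adjust(pvalue, method = "BH")

  data.frame(
    gene_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se = se,
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    significant = abs(log2fc) > lfc_cut & padj < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}
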