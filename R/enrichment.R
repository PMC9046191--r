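#' Overrepresentation test of a gene set against a background
#'
#' For each term in a term-to-gene mapping, tests whether the foreground set
#' contains more genes with that term than expected from the background,
#' using the one-sided Fisher's exact test: with background size N, K
#' foreground genes, n background genes carrying the term and k of them in
#' the foreground, the p value is the hypergeometric upper tail
#' P(X >= k). Benjamini-Hochberg FDR is computed across all tested terms.
#' Genes in the term map outside the background are ignored; terms with no
#' background gene are skipped. The typical use is testing line-specific
#' genes against all genes expressed above 0.5 TPM in that line.
#'
#' @param foreground character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector of gene ids (the gene universe).
#' @param term_map either a data.frame with columns `term_id` and `gene_id`,
#'   or a named list of gene-id vectors.
#' @param alternative `"greater"` (overrepresentation, the default) or
#'   `"two.sided"` (via [stats::fisher.test()]).
#' @return a data.frame ordered by p value then term id, with columns
#'   `term_id`, `k`, `K`, `n`, `N`, `fold_enrichment`, `pvalue`, `fdr`.
#' @examples
#' bg <- paste0("g", 1:10)
#' fg <- bg[1:5]
#' tm <- data.frame(term_id = "T1", gene_id = bg[c(1:3, 5)])
#' fisher_ora(fg, bg, tm)  # p = 6/252
#' @export
fisher_ora <- function(foreground, background, term_map,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  offenders <- setdiff(foreground, background)
  if (length(offenders) > 0)
    stop("foreground gene(s) not in the background: ",
      paste(offenders, collapse = ", "), call. = FALSE)

  if (is.data.frame(term_map)) {
    if (!all(c("term_id", "gene_id") %in% names(term_map)))
      stop("'term_map' data.frame needs columns term_id and gene_id",
        call. = FALSE)
    term_map <- split(as.character(term_map$gene_id),
      as.character(term_map$term_id))
  }
  if (!is.list(term_map) || is.null(names(term_map)))
    stop("'term_map' must be a named list or a term_id/gene_id data.frame",
      call. = FALSE)

  N <- length(background)
  K <- length(foreground)
  rows <- lapply(names(term_map), function(term) {
    genes <- intersect(unique(as.character(term_map[[term]])), background)
    n <- length(genes)
    if (n == 0L) return(NULL)
    k <- length(intersect(foreground, genes))
    p <- if (alternative == "greater") {
      phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n - k, N - n - K + k), 2L))$p.value
    }
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
      fold_enrichment = (k / K) / (n / N), pvalue = p,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), k = integer(), K = integer(),
      n = integer(), N = integer(), fold_enrichment = numeric(),
      pvalue = numeric(), fdr = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
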