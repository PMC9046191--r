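#' Call expressed genes at a minimum-TPM threshold
#'
#' A gene is called expressed when its mean TPM is strictly greater than the
#' threshold. The threshold 0 is a documented special case that returns
#' every gene, including those at TPM 0, so that the fully unfiltered gene
#' set (active and inactive genes alike) is available to the X:autosome
#' sweep.
#'
#' @param profile named numeric vector of mean TPM (one cell line), or a
#'   one-column matrix.
#' @param threshold minimum TPM, >= 0. The conventional low threshold for
#'   calling a gene expressed while keeping rare transcripts is 0.5.
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(profile, threshold = 0.5) {
  profile <- as_profile(profile)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("'threshold' must be a single value >= 0", call. = FALSE)
  if (threshold == 0) return(names(profile))
  names(profile)[profile > threshold]
}

#' Call cell-line-specific genes with the zero-replicate rule
#'
#' A gene is specific to a cell line when it is expressed there (mean TPM
#' strictly above `threshold`) and has zero mapped reads in at least one
#' replicate of the other line (`rule = "any-zero"`, the default). The
#' stricter variant `rule = "all-zero"` requires zero counts in every
#' replicate of the other line.
#'
#' @param profile_self named mean-TPM vector of the focal line.
#' @param counts_other raw count matrix of the other line's replicates
#'   (genes x replicates).
#' @param threshold minimum TPM for calling expression in the focal line.
#' @param rule `"any-zero"` (one zero replicate suffices) or `"all-zero"`.
#' @return character vector of gene ids, in the order of `profile_self`.
#' @export
specific_genes <- function(profile_self, counts_other, threshold = 0.5,
                           rule = c("any-zero", "all-zero")) {
  rule <- match.arg(rule)
  profile_self <- as_profile(profile_self)
  check_counts(counts_other, "counts_other")
  shared <- intersect(names(profile_self), rownames(counts_other))
  if (length(shared) == 0L)
    stop("profile and counts share no genes", call. = FALSE)
  expressed <- intersect(expressed_genes(profile_self, threshold), shared)
  zero <- if (rule == "any-zero") {
    rowSums(counts_other[shared, , drop = FALSE] == 0) > 0
  } else {
    rowSums(counts_other[shared, , drop = FALSE] == 0) == ncol(counts_other)
  }
  intersect(expressed, shared[zero])
}

#' Rank genes by expression and keep the top n
#'
#' Sorts the given genes by mean TPM, descending, with ties broken by gene
#' id ascending so the ordering is deterministic, and returns the first
#' `min(n, length(genes))`. Increasing `n` extends the list without
#' reordering it.
#'
#' @param profile named mean-TPM vector.
#' @param genes gene ids to rank (must be present in `profile`).
#' @param n maximum number of genes to return, >= 1.
#' @return character vector of gene ids, highest expression first.
#' @export
top_ranked <- function(profile, genes, n) {
  profile <- as_profile(profile)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  missing <- setdiff(genes, names(profile))
  if (length(missing) > 0)
    stop("genes absent from profile: ", paste(missing, collapse = ", "),
      call. = FALSE)
  genes <- as.character(genes)
  ord <- order(-profile[genes], genes)
  genes[ord][seq_len(min(n, length(genes)))]
}

#' Partition two expression profiles into shared and specific gene sets
#'
#' Convenience wrapper combining [expressed_genes()] and [specific_genes()]
#' for a two-line comparison.
#'
#' @param means genes x 2 matrix of mean TPM (one column per line).
#' @param counts raw count matrix over all samples.
#' @param metadata sample metadata mapping columns of `counts` to lines.
#' @param threshold minimum TPM for expression calls.
#' @param rule specificity rule, see [specific_genes()].
#' @return a list with per-line `expressed`, the `shared` intersection,
#'   per-line `specific` sets, and the `threshold` and `rule` used.
#' @export
profile_partition <- function(means, counts, metadata, threshold = 0.5,
                              rule = c("any-zero", "all-zero")) {
  rule <- match.arg(rule)
  if (!is.matrix(means) || ncol(means) != 2L)
    stop("'means' must be a genes x 2 matrix of per-line mean TPM", call. = FALSE)
  check_counts(counts)
  check_metadata(metadata, colnames(counts))
  lines <- colnames(means)
  reps <- lapply(lines, function(l)
    counts[, metadata$sample_id[metadata$cell_line == l], drop = FALSE])
  names(reps) <- lines
  expressed <- lapply(lines, function(l) expressed_genes(means[, l], threshold))
  names(expressed) <- lines
  specific <- list(
    specific_genes(means[, lines[1]], reps[[lines[2]]], threshold, rule),
    specific_genes(means[, lines[2]], reps[[lines[1]]], threshold, rule))
  names(specific) <- lines
  list(expressed = expressed,
    shared = intersect(expressed[[1]], expressed[[2]]),
    specific = specific, threshold = threshold, rule = rule)
}
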