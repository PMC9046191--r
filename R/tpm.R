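#' Convert gene-level counts to TPM
#'
#' Transcripts per kilobase million: per sample, each gene's count is divided
#' by its annotated length to give a length-normalized rate, and the rates
#' are rescaled to sum to 1e6. Any count unit cancels, so multiplying a
#' sample's counts by a constant leaves its TPM unchanged. All-zero sample
#' columns yield all-zero TPM columns rather than an error, so degenerate
#' inputs remain processable.
#'
#' Gene length is taken as the annotated length with no effective-length
#' correction; pseudo-alignment tables that already carry TPM bypass this
#' step (see [read_kallisto_abundance()]).
#'
#' @param counts genes x samples numeric matrix with dimnames.
#' @param annotation data.frame with `gene_id` and `length` covering every
#'   gene in `counts`.
#' @return a TPM matrix with the dimnames of `counts`; non-zero columns sum
#'   to 1e6.
#' @examples
#' counts <- matrix(c(100, 200, 50), ncol = 1,
#'   dimnames = list(c("g1", "g2", "g3"), "s1"))
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"),
#'   chromosome = "2L", length = c(1000, 2000, 500))
#' compute_tpm(counts, ann)
#' @export
compute_tpm <- function(counts, annotation) {
  check_counts(counts)
  check_annotation(annotation)
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx))
    stop("no annotated length for gene(s): ",
      paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  len <- annotation$length[idx]
  if (any(len <= 0))
    stop("non-positive length for gene(s): ",
      paste(rownames(counts)[len <= 0], collapse = ", "), call. = FALSE)
  rate <- counts / len
  total <- colSums(rate)
  sweep(rate, 2L, ifelse(total > 0, total, 1), `/`) * 1e6
}

#' Average TPM across replicates of each cell line
#'
#' Arithmetic mean per gene over the replicate columns of each cell line,
#' giving one expression profile per line.
#'
#' @param tpm genes x samples TPM matrix.
#' @param metadata data.frame with `sample_id` and `cell_line` labelling
#'   every column of `tpm`.
#' @return a genes x lines matrix of mean TPM; columns are cell lines in
#'   order of first appearance in `metadata`.
#' @export
mean_by_line <- function(tpm, metadata) {
  check_counts(tpm, "tpm")
  check_metadata(metadata, colnames(tpm))
  lines <- unique(metadata$cell_line)
  out <- vapply(lines, function(line) {
    samples <- metadata$sample_id[metadata$cell_line == line]
    samples <- intersect(colnames(tpm), samples)
    if (length(samples) == 0L)
      stop("cell line '", line, "' has no replicate columns in the TPM matrix",
        call. = FALSE)
    rowMeans(tpm[, samples, drop = FALSE])
  }, numeric(nrow(tpm)))
  rownames(out) <- rownames(tpm)
  out
}
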