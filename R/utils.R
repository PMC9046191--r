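# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

AUTOSOME_ARMS <- c("2R", "2L", "3R", "3L")

#' Classify chromosome labels for X:autosome analysis
#'
#' Maps chromosome labels onto the three classes the X:autosome comparison
#' uses: `"X"`, `"autosome"` (arms 2R, 2L, 3R, 3L) and `"other"` (anything
#' else, e.g. unplaced scaffolds or the mitochondrion). Genes of class
#' `"other"` are excluded from the X:A ratio.
#'
#' @param chromosome character vector of chromosome labels.
#' @return a factor with levels `X`, `autosome`, `other`.
#' @examples
#' chromosome_class(c("X", "2L", "3R", "Mt"))
#' @export
chromosome_class <- function(chromosome) {
  cls <- ifelse(chromosome == "X", "X",
    ifelse(chromosome %in% AUTOSOME_ARMS, "autosome", "other"))
  factor(cls, levels = c("X", "autosome", "other"))
}

check_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'", what, "' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'", what, "' must carry gene ids as rownames and sample ids as colnames",
      call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("'", what, "' contains missing or negative entries", call. = FALSE)
  invisible(counts)
}

check_annotation <- function(annotation) {
  need <- c("gene_id", "chromosome", "length")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("annotation must be a data.frame with columns ",
      paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("annotation gene_ids are not unique", call. = FALSE)
  if (anyNA(annotation$length) || any(annotation$length < 1))
    stop("annotation lengths must be >= 1", call. = FALSE)
  invisible(annotation)
}

check_metadata <- function(metadata, sample_ids = NULL) {
  need <- c("sample_id", "cell_line")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stop("sample metadata must be a data.frame with columns ",
      paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, metadata$sample_id)
    if (length(missing) > 0)
      stop("samples without a cell-line label: ",
        paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(metadata)
}

# Accept a named vector or a one-column matrix as an expression profile.
as_profile <- function(profile) {
  if (is.matrix(profile)) {
    if (ncol(profile) != 1L)
      stop("expected a single expression profile; got a matrix with ",
        ncol(profile), " columns (subset one cell line first)", call. = FALSE)
    profile <- profile[, 1L]
  }
  if (!is.numeric(profile))
    stop("an expression profile must be a named numeric vector", call. = FALSE)
  if (length(profile) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(profile)))
    stop("an expression profile must be a named numeric vector", call. = FALSE)
  profile
}
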