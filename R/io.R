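#' Read a featureCounts-style count table
#'
#' Parses the tab-separated output of read summarization: optional leading
#' comment lines starting with `#`, then a header
#' `Geneid, Chr, Start, End, Strand, Length` followed by one column per
#' sample. `Chr` fields that are semicolon-separated lists (one entry per
#' exon) collapse to their unique value; a list naming more than one
#' distinct chromosome is an error, since the gene cannot be assigned to a
#' single arm for the X:autosome comparison. Coordinates are read but not
#' used downstream.
#'
#' @param path path to the TSV file.
#' @return a list with `counts` (numeric genes x samples matrix) and
#'   `annotation` (data.frame `gene_id`, `chromosome`, `length`).
#' @export
read_featurecounts <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  n_lead <- match(FALSE, is_comment) - 1L
  if (is.na(n_lead)) stop("no header row found in ", path, call. = FALSE)
  tab <- read.delim(text = lines[!is_comment], check.names = FALSE,
    stringsAsFactors = FALSE)
  fixed <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  if (ncol(tab) < 7L || !identical(colnames(tab)[1:6], fixed))
    stop("expected header columns ", paste(fixed, collapse = ", "),
      " followed by sample columns in ", path, call. = FALSE)

  chrom <- vapply(strsplit(as.character(tab$Chr), ";", fixed = TRUE),
    function(parts) {
      u <- unique(parts)
      if (length(u) != 1L) NA_character_ else u
    }, character(1))
  if (anyNA(chrom)) {
    bad <- tab$Geneid[is.na(chrom)]
    stop("gene(s) spanning more than one chromosome: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }

  cmat <- as.matrix(tab[, -(1:6), drop = FALSE])
  if (!is.numeric(cmat) || anyNA(cmat) || any(cmat < 0)) {
    bad_row <- which(apply(cmat, 1L, function(x) anyNA(suppressWarnings(as.numeric(x))) ||
      any(as.numeric(x) < 0, na.rm = TRUE)))[1L]
    # file line = leading comments + header + data row
    stop("negative or non-numeric count at line ",
      n_lead + 1L + bad_row, " of ", path, call. = FALSE)
  }
  rownames(cmat) <- tab$Geneid

  list(
    counts = cmat,
    annotation = data.frame(gene_id = tab$Geneid, chromosome = chrom,
      length = as.integer(tab$Length), stringsAsFactors = FALSE))
}

#' Write a featureCounts-style count table
#'
#' Inverse of [read_featurecounts()]: emits the six fixed annotation columns
#' (with `Start = 1`, `End = length`, `Strand = "+"` as placeholders) plus
#' one column per sample.
#'
#' @param counts genes x samples numeric matrix with dimnames.
#' @param annotation data.frame with `gene_id`, `chromosome`, `length`
#'   covering every row of `counts`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_featurecounts <- function(counts, annotation, path) {
  check_counts(counts)
  check_annotation(annotation)
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (anyNA(ann$gene_id))
    stop("counts contain genes absent from the annotation", call. = FALSE)
  out <- data.frame(Geneid = ann$gene_id, Chr = ann$chromosome,
    Start = 1L, End = ann$length, Strand = "+", Length = ann$length,
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(counts, check.names = FALSE))
  write_result_table(out, path)
}

#' Read kallisto abundance tables into TPM and count matrices
#'
#' Assembles per-sample `abundance.tsv` files (header `target_id, length,
#' eff_length, est_counts, tpm`) into matrices over the union of target ids;
#' targets missing from a sample are filled with 0 and a warning names the
#' sample. `est_counts` are kept as reals; round them before count-based
#' statistics (see [nb_wald_test()]).
#'
#' @param paths character vector of file paths, named by sample id (unnamed
#'   paths use the name of the containing directory).
#' @return a list with `tpm` and `counts` matrices (targets x samples).
#' @export
read_kallisto_abundance <- function(paths) {
  if (length(paths) == 0L) stop("no abundance files given", call. = FALSE)
  ids <- names(paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(paths))
  ids[is.na(ids) | ids == ""] <- basename(dirname(paths[is.na(ids) | ids == ""]))
  need <- c("target_id", "length", "eff_length", "est_counts", "tpm")

  tabs <- lapply(seq_along(paths), function(i) {
    tab <- read.delim(paths[i], stringsAsFactors = FALSE)
    missing <- setdiff(need, colnames(tab))
    if (length(missing) > 0)
      stop("abundance file ", paths[i], " lacks column(s): ",
        paste(missing, collapse = ", "), call. = FALSE)
    if (anyDuplicated(tab$target_id))
      stop("duplicate target_id in ", paths[i], ": ",
        paste(unique(tab$target_id[duplicated(tab$target_id)]), collapse = ", "),
        call. = FALSE)
    tab
  })

  targets <- unique(unlist(lapply(tabs, `[[`, "target_id")))
  fill <- function(field) {
    m <- matrix(0, nrow = length(targets), ncol = length(paths),
      dimnames = list(targets, ids))
    for (i in seq_along(tabs)) {
      tab <- tabs[[i]]
      absent <- setdiff(targets, tab$target_id)
      if (length(absent) > 0)
        warning(length(absent), " target(s) missing from sample '", ids[i],
          "'; filled with 0", call. = FALSE)
      m[tab$target_id, i] <- tab[[field]]
    }
    m
  }
  tpm <- fill("tpm")
  counts <- suppressWarnings(fill("est_counts"))  # warn once, on tpm pass
  list(tpm = tpm, counts = counts)
}

#' Read a gene-annotation table
#'
#' @param path TSV with columns `gene_id`, `chromosome`, `length`.
#' @return a validated annotation data.frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  check_annotation(ann)
  ann
}

#' Read a sample-metadata table
#'
#' Neither featureCounts nor kallisto tables carry the sample-to-cell-line
#' assignment, so it travels in a sidecar table.
#'
#' @param path TSV with columns `sample_id`, `cell_line` and optionally
#'   `replicate`.
#' @return a validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  check_metadata(md)
  md
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, no quoting, no row names. Numbers are written
#' with R's full default precision (15 significant digits), so writing and
#' re-reading a table preserves values to well below 1e-9 relative error.
#'
#' @param x a data.frame (an `xa_curve` or DE/enrichment result included).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_result_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(path)
}
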