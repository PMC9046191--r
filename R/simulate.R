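#' Simulation settings for a two-line count experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' generator emulates a two-cell-line bulk RNA-seq design: line `"A"` carries
#' a single X chromosome whose genes are transcriptionally scaled by a
#' dosage-compensation factor, line `"B"` is diploid-X and serves as the
#' female-like reference.
#'
#' Per-gene baseline expression rates are drawn from a log-normal
#' distribution shared by all chromosome arms. X-linked genes of line A
#' express at `comp_factor_d` times an independent draw from that same
#' distribution, so the population X:A ratio of median expression in line A
#' is exactly `comp_factor_d`, which makes parameter recovery well defined.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_x fraction of genes placed on chromosome X, in (0, 1); the
#'   remainder is spread uniformly over the autosome arms 2R, 2L, 3R, 3L.
#' @param n_replicates_per_line biological replicates per cell line.
#' @param mean_log_mu,mean_log_sigma log-scale mean and standard deviation of
#'   the log-normal from which baseline per-gene expression rates are drawn.
#'   The absolute scale of the rates is arbitrary (library sizes set the
#'   count scale and TPM renormalizes); `mean_log_sigma` controls the
#'   across-gene spread of expression.
#' @param dispersion negative-binomial dispersion `alpha` >= 0, with variance
#'   `mu + alpha * mu^2`; 0 degenerates to Poisson counts.
#' @param lib_size_mean,lib_size_cv mean and coefficient of variation of the
#'   per-sample library size (expected total read count). `lib_size_cv = 0`
#'   gives identical library sizes.
#' @param comp_factor_d dosage-compensation factor in (0, 1.5] applied to the
#'   X-linked genes of the single-X line A: 1 is complete compensation, 0.5
#'   is no compensation (monosomic X at half the diploid output).
#' @param frac_specific_a,frac_specific_b fractions of genes expressed only
#'   in line A (resp. B); the other line gets a structural zero rate.
#' @param frac_de fraction of genes given a spiked fold change in line A;
#'   signs alternate so half go up and half down.
#' @param lfc_de absolute log2 magnitude of the spiked fold changes.
#' @param gene_length_min,gene_length_max bounds (bp) of the uniform gene
#'   length distribution; lengths are shared by both lines.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 5000L,
                       frac_x = 0.1,
                       n_replicates_per_line = 3L,
                       mean_log_mu = 4,
                       mean_log_sigma = 0.4,
                       dispersion = 0.05,
                       lib_size_mean = 5e6,
                       lib_size_cv = 0.1,
                       comp_factor_d = 1,
                       frac_specific_a = 0.05,
                       frac_specific_b = 0.05,
                       frac_de = 0.1,
                       lfc_de = 2,
                       gene_length_min = 500L,
                       gene_length_max = 5000L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), frac_x = frac_x,
    n_replicates_per_line = as.integer(n_replicates_per_line),
    mean_log_mu = mean_log_mu, mean_log_sigma = mean_log_sigma,
    dispersion = dispersion,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    comp_factor_d = comp_factor_d,
    frac_specific_a = frac_specific_a, frac_specific_b = frac_specific_b,
    frac_de = frac_de, lfc_de = lfc_de,
    gene_length_min = as.integer(gene_length_min),
    gene_length_max = as.integer(gene_length_max),
    seed = as.integer(seed))

  if (cfg$n_genes < 1L)
    stop("n_genes must be a positive integer", call. = FALSE)
  if (cfg$n_replicates_per_line < 1L)
    stop("n_replicates_per_line must be a positive integer", call. = FALSE)
  if (!(cfg$frac_x > 0 && cfg$frac_x < 1))
    stop("frac_x must lie in (0, 1)", call. = FALSE)
  fr <- c(cfg$frac_specific_a, cfg$frac_specific_b, cfg$frac_de)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("frac_specific_a, frac_specific_b and frac_de must lie in [0, 1] ",
      "and sum to at most 1", call. = FALSE)
  if (!(cfg$comp_factor_d > 0 && cfg$comp_factor_d <= 1.5))
    stop("comp_factor_d must lie in (0, 1.5]", call. = FALSE)
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$mean_log_sigma < 0) stop("mean_log_sigma must be >= 0", call. = FALSE)
  if (cfg$lib_size_mean <= 0 || cfg$lib_size_cv < 0)
    stop("lib_size_mean must be > 0 and lib_size_cv >= 0", call. = FALSE)
  if (cfg$gene_length_min < 1L || cfg$gene_length_min > cfg$gene_length_max)
    stop("gene lengths require 1 <= gene_length_min <= gene_length_max",
      call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-line RNA-seq count experiment with known truth
#'
#' Generates negative-binomial gene-level counts for two cell lines with
#' `n_replicates_per_line` replicates each, together with the gene annotation
#' (chromosome arm, length), sample metadata and a per-gene truth table. The
#' expected count of gene g in sample s is
#' `lib_factor_s * rate_{g,line(s)} * length_g / 1000`, so counts scale with
#' transcript length (as read summarization does) and the TPM of a gene
#' recovers its molar rate. Line-specific genes are structural zeros (rate 0)
#' in the other line; spiked fold-change genes are multiplied by
#' `2^(+/- lfc_de)` in line A; X-linked genes of line A are scaled by
#' `comp_factor_d`.
#'
#' The random-number stream is consumed in a fixed, documented order
#' (chromosomes, lengths, rates, gene labels, library sizes, then counts
#' column by column A1..Ar, B1..Br), so a fixed seed gives bit-identical
#' output across runs.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `xa_sim` with elements
#'   \describe{
#'     \item{counts}{genes x samples numeric matrix of counts.}
#'     \item{annotation}{data.frame `gene_id`, `chromosome`, `length`.}
#'     \item{metadata}{data.frame `sample_id`, `cell_line`, `replicate`.}
#'     \item{truth}{data.frame `gene_id`, `chromosome`, `base_rate`,
#'       `comp_factor`, `specificity` (`"A-only"`, `"B-only"`, `"both"`),
#'       `true_lfc` (the spiked log2 fold change, 0 otherwise), and the
#'       realized per-line rates `rate_a`, `rate_b`.}
#'     \item{lib_factors}{named per-sample scaling factors such that
#'       `E[count] = lib_factor * rate * length/1000`.}
#'   }
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 200, seed = 7))
#' dim(sim$counts)
#' head(sim$truth)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be created with sim_config()", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_genes
  r <- config$n_replicates_per_line

  arms <- c("X", AUTOSOME_ARMS)
  chrom <- sample(arms, n, replace = TRUE,
    prob = c(config$frac_x, rep((1 - config$frac_x) / 4, 4)))
  len <- floor(runif(n, config$gene_length_min, config$gene_length_max + 1))
  base_rate <- rlnorm(n, config$mean_log_mu, config$mean_log_sigma)

  gene_id <- sprintf("gene%05d", seq_len(n))

  # disjoint label groups: A-only, B-only, spiked DE
  n_sa <- round(config$frac_specific_a * n)
  n_sb <- round(config$frac_specific_b * n)
  n_de <- round(config$frac_de * n)
  pool <- sample.int(n, n_sa + n_sb + n_de)
  idx_sa <- pool[seq_len(n_sa)]
  idx_sb <- pool[n_sa + seq_len(n_sb)]
  idx_de <- pool[n_sa + n_sb + seq_len(n_de)]

  specificity <- rep("both", n)
  specificity[idx_sa] <- "A-only"
  specificity[idx_sb] <- "B-only"

  true_lfc <- numeric(n)
  if (n_de > 0)
    true_lfc[idx_de] <- rep_len(c(1, -1), n_de) * config$lfc_de

  comp_factor <- ifelse(chrom == "X", config$comp_factor_d, 1)

  rate_b <- base_rate
  rate_a <- base_rate * comp_factor * 2^true_lfc
  rate_a[idx_sb] <- 0
  rate_b[idx_sa] <- 0

  n_samp <- 2L * r
  sample_id <- c(sprintf("A_rep%d", seq_len(r)), sprintf("B_rep%d", seq_len(r)))
  cell_line <- rep(c("A", "B"), each = r)
  if (config$lib_size_cv > 0) {
    sdlog <- sqrt(log(1 + config$lib_size_cv^2))
    lib_size <- rlnorm(n_samp, log(config$lib_size_mean) - sdlog^2 / 2, sdlog)
  } else {
    lib_size <- rep(config$lib_size_mean, n_samp)
  }

  len_kb <- len / 1000
  w_a <- rate_a * len_kb
  w_b <- rate_b * len_kb
  lib_factors <- ifelse(cell_line == "A",
    lib_size / sum(w_a), lib_size / sum(w_b))
  names(lib_factors) <- sample_id

  counts <- matrix(0, nrow = n, ncol = n_samp,
    dimnames = list(gene_id, sample_id))
  for (s in seq_len(n_samp)) {
    mu <- lib_factors[s] * (if (cell_line[s] == "A") w_a else w_b)
    counts[, s] <- if (config$dispersion > 0) {
      rnbinom(n, size = 1 / config$dispersion, mu = mu)
    } else {
      rpois(n, mu)
    }
  }

  structure(list(
    counts = counts,
    annotation = data.frame(gene_id = gene_id, chromosome = chrom,
      length = as.integer(len), stringsAsFactors = FALSE),
    metadata = data.frame(sample_id = sample_id, cell_line = cell_line,
      replicate = rep(seq_len(r), 2L), stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_id, chromosome = chrom,
      base_rate = base_rate, comp_factor = comp_factor,
      specificity = specificity, true_lfc = true_lfc,
      rate_a = rate_a, rate_b = rate_b, stringsAsFactors = FALSE),
    lib_factors = lib_factors,
    config = config), class = "xa_sim")
}

#' Write a simulated experiment to disk
#'
#' Writes the count matrix as a featureCounts-style TSV plus annotation,
#' sample-metadata and truth tables, all readable back with the package's
#' readers.
#'
#' @param sim an `xa_sim` object from [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "xa_sim")) stop("'sim' must be an xa_sim object", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.featureCounts.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    metadata = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_featurecounts(sim$counts, sim$annotation, paths[["counts"]])
  write_result_table(sim$annotation, paths[["annotation"]])
  write_result_table(sim$metadata, paths[["metadata"]])
  write_result_table(sim$truth, paths[["truth"]])
  invisible(paths)
}
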