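#' Read a pipeline run configuration
#'
#' Run configurations are plain lists; on disk they may be JSON or YAML.
#' See [run_pipeline()] for the recognised fields.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

default_run_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    simulate = NULL,     # list of sim_config() arguments, or NULL to read inputs
    inputs = NULL,       # list(counts=, annotation=, metadata=) of file paths
    threshold = 0.5,
    top_n = 250L,
    specific_rule = "any-zero",
    de = list(min_total = 10, lfc_cut = 1, alpha = 1e-4),
    dc = list(thresholds = c(0, 1, 2, 5, 10, 20, 30, 40), n_boot = 10000L,
      ci_level = 0.95, stratify_samples = FALSE),
    enrich = list(term_map = NULL))
}

merge_config <- function(defaults, config) {
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], config[[k]])
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  defaults
}

# independent per-stage seed streams derived from the one run seed, so
# toggling one stage does not perturb another's randomness
derive_seed <- function(seed, stage) {
  offset <- c(simulate = 0L, bootstrap_1 = 1000003L, bootstrap_2 = 2000003L)[[stage]]
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Run the full two-line analysis pipeline
#'
#' Orchestrates the stages end to end: obtain counts (simulate, or read a
#' featureCounts-style table with annotation and sample metadata), compute
#' TPM and replicate-averaged profiles, partition genes into expressed /
#' shared / line-specific sets, run the simplified NB Wald differential
#' expression, compute the X:A ratio curve with bootstrap CIs for each cell
#' line and, when a term map is supplied, test the line-specific sets for
#' overrepresentation against that line's expressed background. All stage
#' outputs are written as TSV under `out_dir` together with a
#' `manifest.json` echoing the full configuration (defaults filled in),
#' package version, seed and per-stage gene counts, so every result file is
#' self-describing and a run is reproducible byte for byte from its
#' manifest.
#'
#' @param config a configuration list, or a path to a JSON/YAML file; see
#'   [read_run_config()] and the fields of `default_run_config` in the
#'   package source: `out_dir`, `seed`, `simulate` (arguments to
#'   [sim_config()]) or `inputs` (paths `counts`, `annotation`, `metadata`),
#'   `threshold`, `top_n`, `specific_rule`, `de` (`min_total`, `lfc_cut`,
#'   `alpha`), `dc` (`thresholds`, `n_boot`, `ci_level`,
#'   `stratify_samples`), `enrich` (`term_map` path).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param verbose emit progress messages on stderr.
#' @return invisibly, a list with the in-memory results (`sim` or inputs,
#'   `tpm`, `means`, `partition`, `top`, `de`, `curves`, `enrichment`,
#'   `manifest`) and the written file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  cfg$out_dir <- out_dir
  say <- function(...) if (verbose) message("[xaratio] ", ...)

  # fail fast before any computation
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$inputs))
      stop("config needs either 'simulate' parameters or 'inputs' paths",
        call. = FALSE)
    for (field in c("counts", "annotation", "metadata")) {
      p <- cfg$inputs[[field]]
      if (is.null(p) || !file.exists(p))
        stop("input '", field, "' missing or not found: ",
          p %||% "<unset>", call. = FALSE)
    }
  }
  if (!is.null(cfg$enrich$term_map) && !file.exists(cfg$enrich$term_map))
    stop("term map not found: ", cfg$enrich$term_map, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
  }

  paths <- character()
  manifest_counts <- list()

  # --- counts ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    say("simulating counts")
    sim <- with_stage("simulate", {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(cfg$seed, "simulate")
      simulate_experiment(do.call(sim_config, args))
    })
    counts <- sim$counts; annotation <- sim$annotation; metadata <- sim$metadata
    paths <- c(paths, write_simulation(sim, out_dir))
  } else {
    say("reading counts")
    sim <- NULL
    fc <- with_stage("read", read_featurecounts(cfg$inputs$counts))
    counts <- fc$counts
    annotation <- with_stage("read", read_gene_annotation(cfg$inputs$annotation))
    metadata <- with_stage("read", read_sample_metadata(cfg$inputs$metadata))
    check_metadata(metadata, colnames(counts))
  }
  manifest_counts$n_genes <- nrow(counts)
  manifest_counts$n_samples <- ncol(counts)

  # --- quantification -------------------------------------------------------
  say("computing TPM and per-line means")
  tpm <- with_stage("tpm", compute_tpm(counts, annotation))
  means <- with_stage("tpm", mean_by_line(tpm, metadata))
  lines <- colnames(means)
  p <- file.path(out_dir, "tpm.tsv")
  write_result_table(cbind(gene_id = rownames(tpm),
    as.data.frame(tpm, check.names = FALSE)), p)
  paths <- c(paths, tpm = p)
  p <- file.path(out_dir, "mean_tpm.tsv")
  write_result_table(cbind(gene_id = rownames(means),
    as.data.frame(means, check.names = FALSE)), p)
  paths <- c(paths, mean_tpm = p)

  # --- expression profiles --------------------------------------------------
  say("partitioning expressed / shared / specific genes")
  part <- with_stage("profile", profile_partition(means, counts, metadata,
    threshold = cfg$threshold, rule = cfg$specific_rule))
  top <- lapply(lines, function(l)
    top_ranked(means[, l], part$specific[[l]], cfg$top_n))
  names(top) <- lines
  part_tab <- do.call(rbind, lapply(lines, function(l) {
    data.frame(cell_line = l,
      n_expressed = length(part$expressed[[l]]),
      n_specific = length(part$specific[[l]]),
      n_shared = length(part$shared), stringsAsFactors = FALSE)
  }))
  p <- file.path(out_dir, "partition_summary.tsv")
  write_result_table(part_tab, p)
  paths <- c(paths, partition = p)
  for (l in lines) {
    p <- file.path(out_dir, paste0("specific_", l, ".tsv"))
    write_result_table(data.frame(rank = seq_along(top[[l]]),
      gene_id = top[[l]], mean_tpm = means[top[[l]], l],
      stringsAsFactors = FALSE), p)
    paths <- c(paths, setNames(p, paste0("specific_", l)))
  }
  manifest_counts$expressed <- lapply(part$expressed, length)
  manifest_counts$shared <- length(part$shared)
  manifest_counts$specific <- lapply(part$specific, length)

  # --- differential expression ----------------------------------------------
  say("differential expression")
  de <- with_stage("de", {
    kept <- prefilter_low_counts(round(counts), cfg$de$min_total)
    nb_wald_test(kept, metadata$cell_line[match(colnames(kept),
      metadata$sample_id)], lfc_cut = cfg$de$lfc_cut, alpha = cfg$de$alpha)
  })
  p <- file.path(out_dir, "de.tsv")
  write_result_table(de, p)
  paths <- c(paths, de = p)
  manifest_counts$de_tested <- nrow(de)
  manifest_counts$de_significant <- sum(de$significant)

  # --- dosage compensation --------------------------------------------------
  curves <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    say("X:A curve for line ", l)
    line_tpm <- tpm[, metadata$sample_id[metadata$cell_line == l], drop = FALSE]
    curves[[l]] <- with_stage("dc", xa_curve(means[, l], annotation,
      thresholds = cfg$dc$thresholds, n_boot = cfg$dc$n_boot,
      ci_level = cfg$dc$ci_level,
      seed = derive_seed(cfg$seed, paste0("bootstrap_", i)),
      stratify_samples = isTRUE(cfg$dc$stratify_samples),
      tpm = line_tpm, cell_line = l))
    p <- file.path(out_dir, paste0("xa_curve_", l, ".tsv"))
    write_result_table(curves[[l]], p)
    paths <- c(paths, setNames(p, paste0("xa_curve_", l)))
  }

  # --- enrichment -----------------------------------------------------------
  enrichment <- NULL
  if (!is.null(cfg$enrich$term_map)) {
    say("overrepresentation tests")
    tm <- read.delim(cfg$enrich$term_map, stringsAsFactors = FALSE)
    enrichment <- lapply(lines, function(l) with_stage("enrich",
      fisher_ora(part$specific[[l]], part$expressed[[l]], tm)))
    names(enrichment) <- lines
    for (l in lines) {
      p <- file.path(out_dir, paste0("enrichment_", l, ".tsv"))
      write_result_table(enrichment[[l]], p)
      paths <- c(paths, setNames(p, paste0("enrichment_", l)))
    }
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "xaratio",
    version = as.character(packageVersion("xaratio")),
    seed = cfg$seed,
    config = cfg,
    stage_counts = manifest_counts)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  paths <- c(paths, manifest = p)
  say("done: ", out_dir)

  invisible(list(sim = sim, counts = counts, annotation = annotation,
    metadata = metadata, tpm = tpm, means = means, partition = part,
    top = top, de = de, curves = curves, enrichment = enrichment,
    manifest = manifest, paths = paths))
}
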