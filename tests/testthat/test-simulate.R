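test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_replicates_per_line = 0), "replicates")
  expect_error(sim_config(frac_x = 0), "frac_x")
  expect_error(sim_config(frac_x = 1), "frac_x")
  expect_error(sim_config(frac_specific_a = 0.6, frac_specific_b = 0.3,
    frac_de = 0.3), "sum")
  expect_error(sim_config(comp_factor_d = 0), "comp_factor_d")
  expect_error(sim_config(comp_factor_d = 2), "comp_factor_d")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(gene_length_min = 0), "length")
  expect_error(sim_config(gene_length_min = 600, gene_length_max = 500),
    "length")
  expect_error(simulate_experiment(list(n_genes = 5)), "sim_config")
})

test_that("a triplicate design yields six labelled sample columns", {
  sim <- simulate_experiment(sim_config(n_genes = 50, seed = 3))
  expect_equal(ncol(sim$counts), 6L)
  expect_equal(sum(sim$metadata$cell_line == "A"), 3L)
  expect_equal(sum(sim$metadata$cell_line == "B"), 3L)
  expect_identical(colnames(sim$counts), sim$metadata$sample_id)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$annotation$chromosome %in% c("X", "2R", "2L", "3R", "3L")))
  expect_true(all(sim$annotation$length >= 500 & sim$annotation$length <= 5000))
  expect_equal(nrow(sim$truth), 50L)
})

test_that("a fixed seed reproduces counts bit for bit; seeds differ", {
  cfg <- sim_config(n_genes = 300, seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_experiment(sim_config(n_genes = 300, seed = 43))
  expect_false(identical(a$counts, c$counts))
})

test_that("truth labels are consistent with the emitted counts", {
  sim <- simulate_experiment(sim_config(n_genes = 1000, seed = 5))
  a_cols <- sim$metadata$sample_id[sim$metadata$cell_line == "A"]
  b_cols <- sim$metadata$sample_id[sim$metadata$cell_line == "B"]
  a_only <- sim$truth$gene_id[sim$truth$specificity == "A-only"]
  b_only <- sim$truth$gene_id[sim$truth$specificity == "B-only"]
  expect_gt(length(a_only), 0)
  expect_true(all(sim$counts[a_only, b_cols] == 0))
  expect_true(all(sim$counts[b_only, a_cols] == 0))
  expect_true(all(sim$truth$comp_factor[sim$truth$chromosome != "X"] == 1))
})

test_that("the symmetric Poisson construction gives an X:A TPM ratio near 1", {
  sim <- simulate_experiment(sim_config(n_genes = 20000, dispersion = 0,
    lib_size_cv = 0, comp_factor_d = 1, frac_specific_a = 0,
    frac_specific_b = 0, frac_de = 0, seed = 8))
  means <- mean_by_line(compute_tpm(sim$counts, sim$annotation), sim$metadata)
  r <- median_xa_ratio(means[, "A"], sim$annotation, 0)
  expect_lt(abs(r$ratio - 1), 0.04)
})

test_that("per-gene count means recover the truth rates", {
  sim <- simulate_experiment(sim_config(n_genes = 1000,
    n_replicates_per_line = 60, frac_specific_a = 0, frac_specific_b = 0,
    frac_de = 0, seed = 21))
  b_cols <- sim$metadata$sample_id[sim$metadata$cell_line == "B"]
  lf <- sim$lib_factors[b_cols]
  scaled <- sweep(sim$counts[, b_cols], 2L, lf, `/`)
  expected <- sim$truth$rate_b * sim$annotation$length / 1000
  # per-gene z score of the observed mean against its sampling SE
  var_scaled <- sapply(seq_along(b_cols), function(s) {
    mu <- lf[s] * expected
    (mu + sim$config$dispersion * mu^2) / lf[s]^2
  })
  se <- sqrt(rowSums(var_scaled)) / length(b_cols)
  z <- (rowMeans(scaled) - expected) / se
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("truth-rate medians encode the compensation factor", {
  for (d in c(0.5, 1)) {
    sim <- simulate_experiment(sim_config(n_genes = 20000, comp_factor_d = d,
      frac_specific_a = 0, frac_specific_b = 0, frac_de = 0, seed = 31))
    x <- sim$truth$rate_a[sim$truth$chromosome == "X"]
    a <- sim$truth$rate_a[sim$truth$chromosome != "X"]
    expect_lt(abs(median(x) / median(a) - d), 0.02 * max(d, 1))
  }
})
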