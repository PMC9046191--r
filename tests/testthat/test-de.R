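test_that("the low-count prefilter drops totals strictly below the cutoff", {
  counts <- matrix(c(3, 3, 3, 4, 3, 3, 4, 4, 3), nrow = 3, byrow = TRUE,
    dimnames = list(c("g9", "g10", "g11"), c("s1", "s2", "s3")))
  # totals 9, 10, 11: "less than 10" removed, 10 itself kept
  kept <- prefilter_low_counts(counts, 10)
  expect_equal(rownames(kept), c("g10", "g11"))
  expect_identical(prefilter_low_counts(counts, 0), counts)
  empty <- prefilter_low_counts(counts, 1000)
  expect_equal(nrow(empty), 0L)
  expect_error(nb_wald_test(empty, rep(c("A", "B"), c(2, 1))), "no genes")
})

test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(2, 2, 8, 8), nrow = 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 0.5, s2 = 2))

  ident <- matrix(rep(c(4, 9, 25), 3), nrow = 3,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  # scale equivariance: the ratio reference is the across-sample geometric
  # mean, so rescaling one sample moves its factor by c relative to the rest
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 6))
  sf1 <- size_factors(sim$counts)
  scaled <- sim$counts
  scaled[, 4] <- scaled[, 4] * 3
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[4] / sf2[1]), unname(3 * sf1[4] / sf1[1]),
    tolerance = 1e-12)
  expect_equal(unname(sf2[-4] / sf2[1]), unname(sf1[-4] / sf1[1]),
    tolerance = 1e-12)

  allzero <- matrix(c(0, 1, 1, 0), 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(allzero), "all-positive")
})

test_that("BH adjustment agrees with a brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(300)
  for (i in 1:25) {
    m <- sample(1:10, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("identical groups give the exact null result", {
  counts <- matrix(rep(c(5, 10, 20), each = 6), nrow = 3, byrow = TRUE,
    dimnames = list(paste0("g", 1:3),
      c("A1", "A2", "A3", "B1", "B2", "B3")))
  de <- nb_wald_test(counts, rep(c("A", "B"), each = 3))
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$stat, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3))
  expect_false(any(de$significant))
})

test_that("swapping group labels negates fold changes and keeps p values", {
  sim <- simulate_experiment(sim_config(n_genes = 400, seed = 13))
  kept <- prefilter_low_counts(sim$counts)
  g <- sim$metadata$cell_line
  de_ab <- nb_wald_test(kept, g)
  de_ba <- nb_wald_test(kept, factor(g, levels = c("B", "A")))
  expect_equal(de_ba$log2fc, -de_ab$log2fc, tolerance = 1e-12)
  expect_equal(de_ba$pvalue, de_ab$pvalue, tolerance = 1e-12)
})

test_that("spiked fold changes are detected and null genes are not", {
  sim <- simulate_experiment(sim_config(n_genes = 2000, seed = 77))
  de <- nb_wald_test(prefilter_low_counts(sim$counts),
    sim$metadata$cell_line)
  tr <- sim$truth[match(de$gene_id, sim$truth$gene_id), ]
  spiked <- tr$true_lfc != 0
  nulls <- tr$true_lfc == 0 & tr$specificity == "both"
  expect_gte(mean(de$significant[spiked]), 0.80)
  expect_lte(mean(de$significant[nulls]), 0.001)
  # estimated fold changes track the spiked magnitudes
  expect_gt(cor(de$log2fc[spiked], tr$true_lfc[spiked]), 0.95)
})

test_that("p values are roughly uniform at the 5% level under the null", {
  props <- vapply(1:10, function(s) {
    sim <- simulate_experiment(sim_config(n_genes = 2000, frac_de = 0,
      frac_specific_a = 0, frac_specific_b = 0, seed = 4000 + s))
    de <- nb_wald_test(prefilter_low_counts(sim$counts),
      sim$metadata$cell_line)
    mean(de$pvalue < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.05), 0.02)
})

test_that("group structure is validated", {
  counts <- toy_counts()
  expect_error(nb_wald_test(counts, rep("A", 6)), "two groups")
  expect_error(nb_wald_test(counts, c("A", "B", "B", "B", "B", "B")),
    "2 replicates")
  expect_error(nb_wald_test(counts, c("A", "B")), "every column")
})
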