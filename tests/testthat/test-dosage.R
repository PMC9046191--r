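test_that("the X:A ratio matches hand-computed midpoint medians", {
  prof <- c(x1 = 4, x2 = 6, a1 = 2, a2 = 8, a3 = 10, a4 = 12)
  ann <- data.frame(gene_id = names(prof),
    chromosome = c("X", "X", "2L", "2R", "3L", "3R"), length = 1000)
  r <- median_xa_ratio(prof, ann, 0)
  expect_equal(r$ratio, 5 / 9)  # medians 5 and 9
  expect_equal(round(r$ratio, 4), 0.5556)
  expect_equal(r$n_x, 2L)
  expect_equal(r$n_a, 4L)

  # identical expression everywhere -> ratio exactly 1
  flat <- setNames(rep(3, 6), names(prof))
  expect_equal(median_xa_ratio(flat, ann, 0)$ratio, 1)

  # scale invariance of a ratio of medians
  expect_equal(median_xa_ratio(prof * 2, ann, 0)$ratio, r$ratio)
})

test_that("genes off the arms are excluded and thresholding is strict", {
  prof <- c(x1 = 4, x2 = 6, a1 = 2, a2 = 8, mt = 1000, un = 500)
  ann <- data.frame(gene_id = names(prof),
    chromosome = c("X", "X", "2L", "3R", "Mt", "UNKN"), length = 1000)
  r <- median_xa_ratio(prof, ann, 0)
  expect_equal(r$n_a, 2L)  # Mt and UNKN dropped
  expect_equal(r$ratio, 5 / 5)
  # threshold 4 removes x1 (strict >) leaving x2 only
  r4 <- median_xa_ratio(prof, ann, 4)
  expect_equal(r4$n_x, 1L)
  expect_equal(r4$ratio, 6 / 8)
})

test_that("undefined ratios raise informative errors or NA rows", {
  prof <- c(x1 = 4, a1 = 2)
  ann <- data.frame(gene_id = names(prof), chromosome = c("X", "2L"),
    length = 1000)
  expect_error(median_xa_ratio(prof, ann, 10), "threshold 10")
  zeros <- c(x1 = 0, a1 = 0)
  expect_error(median_xa_ratio(zeros, ann, 0), "undefined")
  cv <- xa_curve(prof, ann, thresholds = c(0, 10), n_boot = 10, seed = 1,
    on_error = "skip")
  expect_equal(cv$ratio[1], 2)
  expect_true(is.na(cv$ratio[2]))
  expect_error(xa_curve(prof, ann, thresholds = c(0, 10), n_boot = 10,
    seed = 1), "threshold 10")
})

test_that("resampling a constant profile gives a degenerate CI", {
  prof <- setNames(rep(7, 10), paste0("g", 1:10))
  ann <- data.frame(gene_id = names(prof),
    chromosome = rep(c("X", "2L"), 5), length = 1000)
  cv <- xa_curve(prof, ann, thresholds = 0, n_boot = 200, seed = 5)
  expect_equal(cv$ratio, 1)
  expect_equal(cv$ci_lo, 1)
  expect_equal(cv$ci_hi, 1)
})

test_that("curves are deterministic and structurally sound", {
  sim <- simulate_experiment(sim_config(n_genes = 800, seed = 19))
  means <- mean_by_line(compute_tpm(sim$counts, sim$annotation), sim$metadata)
  cv1 <- xa_curve(means[, "A"], sim$annotation, thresholds = c(0, 1, 5, 20),
    n_boot = 300, seed = 99)
  cv2 <- xa_curve(means[, "A"], sim$annotation, thresholds = c(0, 1, 5, 20),
    n_boot = 300, seed = 99)
  expect_identical(as.data.frame(cv1), as.data.frame(cv2))
  expect_true(all(cv1$ci_lo <= cv1$ci_hi))
  expect_true(all(cv1$ci_lo <= cv1$ratio & cv1$ratio <= cv1$ci_hi))
  expect_true(all(diff(cv1$n_x) <= 0))
  expect_true(all(diff(cv1$n_a) <= 0))
})

test_that("CI width shrinks roughly by half per fourfold gene count", {
  # widths are averaged over seeds: a single dataset's width is itself noisy
  width_at <- function(n_genes, seed) {
    sim <- simulate_experiment(sim_config(n_genes = n_genes, seed = seed))
    means <- mean_by_line(compute_tpm(sim$counts, sim$annotation),
      sim$metadata)
    cv <- xa_curve(means[, "A"], sim$annotation, thresholds = 0,
      n_boot = 1000, seed = seed + 1)
    cv$ci_hi - cv$ci_lo
  }
  w_small <- mean(vapply(31:38, function(s) width_at(600, s), numeric(1)))
  w_big <- mean(vapply(31:38, function(s) width_at(2400, s), numeric(1)))
  expect_lt(w_big / w_small, 0.70)
  expect_gt(w_big / w_small, 0.30)
})

test_that("bootstrap CIs cover the complete-compensation truth at nominal rate", {
  covered <- vapply(1:200, function(s) {
    sim <- simulate_experiment(sim_config(n_genes = 1000, seed = 10000 + s))
    means <- mean_by_line(compute_tpm(sim$counts, sim$annotation),
      sim$metadata)
    cv <- xa_curve(means[, "A"], sim$annotation, thresholds = 0,
      n_boot = 1000, seed = 20000 + s)
    cv$ci_lo <= 1 && 1 <= cv$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("sample-stratified resampling agrees with the default on averages", {
  sim <- simulate_experiment(sim_config(n_genes = 1000, seed = 55))
  tpm <- compute_tpm(sim$counts, sim$annotation)
  means <- mean_by_line(tpm, sim$metadata)
  a_cols <- sim$metadata$sample_id[sim$metadata$cell_line == "A"]
  cv <- xa_curve(means[, "A"], sim$annotation, thresholds = 0, n_boot = 400,
    seed = 7, stratify_samples = TRUE, tpm = tpm[, a_cols])
  cv2 <- xa_curve(means[, "A"], sim$annotation, thresholds = 0, n_boot = 400,
    seed = 7, stratify_samples = TRUE, tpm = tpm[, a_cols])
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  # same estimand: the two modes agree within their sampling noise
  cv0 <- xa_curve(means[, "A"], sim$annotation, thresholds = 0, n_boot = 400,
    seed = 8)
  expect_lt(abs(cv$ratio - cv0$ratio), 0.1)
  expect_error(xa_curve(means[, "A"], sim$annotation, thresholds = 0,
    n_boot = 10, seed = 1, stratify_samples = TRUE), "tpm")
})

test_that("threshold grids are validated", {
  prof <- toy_xa_profile()
  expect_error(xa_curve(prof$profile, prof$annotation,
    thresholds = c(5, 1)), "sorted")
  expect_error(xa_curve(prof$profile, prof$annotation, thresholds = -1),
    "sorted|non-negative")
  expect_error(xa_curve(prof$profile, prof$annotation, ci_level = 1.2),
    "ci_level")
})
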