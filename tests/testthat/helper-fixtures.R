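# small fixtures shared across test files; everything is built in code

toy_counts <- function() {
  matrix(c(
    10, 12, 9, 11, 10, 13,
    100, 110, 95, 105, 98, 102,
    5, 0, 7, 6, 5, 4),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"),
      c("A_rep1", "A_rep2", "A_rep3", "B_rep1", "B_rep2", "B_rep3")))
}

toy_metadata <- function() {
  data.frame(
    sample_id = c("A_rep1", "A_rep2", "A_rep3", "B_rep1", "B_rep2", "B_rep3"),
    cell_line = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2), stringsAsFactors = FALSE)
}

toy_annotation <- function(gene_ids, chromosome = "2L", length = 1000) {
  data.frame(gene_id = gene_ids, chromosome = chromosome, length = length,
    stringsAsFactors = FALSE)
}

# 10-gene toy profile for bootstrap-oracle checks: 3 X genes, 7 autosomal
toy_xa_profile <- function() {
  prof <- c(x1 = 4, x2 = 5, x3 = 6,
    a1 = 2, a2 = 4, a3 = 6, a4 = 8, a5 = 9, a6 = 10, a7 = 12)
  ann <- data.frame(gene_id = names(prof),
    chromosome = c("X", "X", "X", "2L", "2L", "2R", "2R", "3L", "3R", "3R"),
    length = 1000, stringsAsFactors = FALSE)
  list(profile = prof, annotation = ann)
}

# independent naive reimplementation of the stratified gene bootstrap,
# consuming the RNG in the documented order (per replicate: X then A)
naive_xa_bootstrap <- function(profile, annotation, threshold, n_boot,
                               ci_level, seed) {
  cls <- xaratio::chromosome_class(
    annotation$chromosome[match(names(profile), annotation$gene_id)])
  keep <- if (threshold == 0) rep(TRUE, length(profile)) else profile > threshold
  x <- profile[keep & cls == "X"]
  a <- profile[keep & cls == "autosome"]
  set.seed(seed)
  ratios <- vapply(seq_len(n_boot), function(b) {
    bx <- x[sample.int(length(x), length(x), replace = TRUE)]
    ba <- a[sample.int(length(a), length(a), replace = TRUE)]
    median(bx) / median(ba)
  }, numeric(1))
  list(point = median(x) / median(a),
    ci = unname(quantile(ratios, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
      type = 7)))
}

# brute-force Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# hypergeometric upper tail from first principles (binomial coefficients)
hyper_tail_oracle <- function(k, n, N, K) {
  j <- seq(k, min(n, K))
  if (length(j) == 0) return(0)
  sum(choose(n, j) * choose(N - n, K - j)) / choose(N, K)
}
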