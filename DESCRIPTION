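Package: xaratio
Title: X:Autosome Dosage-Compensation Analysis for Two-Line RNA-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Comparative bulk RNA-seq analysis of two cell lines: TPM
    quantification from gene-level counts, expressed/shared/line-specific
    gene calling with a zero-replicate specificity rule, a simplified
    negative-binomial Wald differential-expression test with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    Fisher's exact overrepresentation testing, and the X-to-autosome ratio
    of median expression across a minimum-TPM threshold sweep with
    stratified bootstrap confidence intervals. Includes a seeded
    negative-binomial count simulator with a tunable dosage-compensation
    factor, line-specific genes and spiked fold changes for validation, and
    readers/writers for featureCounts- and kallisto-style tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
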