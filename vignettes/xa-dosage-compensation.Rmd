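---
title: "Methods: the X:autosome ratio pipeline and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the X:autosome ratio pipeline and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaratio)
```

## The question and the statistic

In species with XY males, dosage compensation (DC) equalizes the
transcriptional output of the single male X chromosome with that of the
diploid autosomes. Whether DC operates in a given cell population can be
read off a chromosome-wide comparison: among transcriptionally active
genes, the median expression of X-linked genes divided by the median
expression of autosomal genes (the X:A ratio) should be near 1 under
complete compensation and near 0.5 for an uncompensated monosomic X.

The difficulty is deciding which genes are "active". Genes expressed at
very low levels are hard to distinguish from transcriptional background,
and including silent genes drags the X median down if the X carries more
silent genes (or up, in the opposite case). Rather than committing to one
activity cutoff, the pipeline computes the ratio across a sweep of
minimum-expression thresholds, from TPM 0 (every annotated gene, active or
not) to TPM 40 (only highly expressed genes), and reports the whole curve.
A flat curve near 1 away from the degenerate t = 0 point is the signature
of complete DC.

Formally, for a replicate-averaged TPM profile and threshold $t$:

$$\mathrm{X{:}A}(t) = \frac{\mathrm{median}\{\bar{x}_g : g \in X,\ \bar{x}_g > t\}}
                          {\mathrm{median}\{\bar{x}_g : g \in A,\ \bar{x}_g > t\}}$$

where $A$ is the union of the autosome arms 2R, 2L, 3R and 3L, and
$t = 0$ is special-cased to keep all genes including those at exactly 0.
Genes on any other sequence (mitochondrion, unplaced scaffolds, Y) are
excluded from both strata. Medians use R's midpoint rule for even counts.

### Bootstrap confidence intervals

Uncertainty in a ratio of medians has no convenient closed form, so the
pipeline uses a stratified nonparametric bootstrap: after thresholding,
the X stratum and the autosome stratum are resampled with replacement
*independently*, the ratio is recomputed, and the 95% interval is the 2.5
and 97.5 percentile of `n_boot` replicate ratios (10,000 by default;
percentile rather than BCa intervals, the plainest reading of "bootstrap
CI"). Stratification matters: unstratified resampling would let the X/A
split itself fluctuate and mix the strata's very different sizes into the
interval.

Three deliberate choices here:

- **Strata are frozen after thresholding.** Resampled genes are not
  re-thresholded; the bootstrap targets the sampling variability of the
  medians of the observed thresholded populations, not of the thresholding
  rule.
- **Replicate handling.** By default the statistic is computed on the
  replicate-averaged profile and resampling is at the gene level —
  chromosome is the stratifying variable, and averaging already collapses
  the sample dimension. `stratify_samples = TRUE` additionally resamples
  genes within each replicate column, computes per-replicate ratios and
  averages them, honouring a stronger reading of stratifying "by
  chromosome and sample". Both are exposed; the default is the simpler
  one, and every curve records which was used in its attributes.
- **A documented RNG order.** For each threshold, each bootstrap replicate
  draws X indices then autosome indices via `sample.int(n, n, replace =
  TRUE)`. Fixing this order makes curves bit-for-bit reproducible under a
  seed and lets an independent reimplementation of the resampling serve as
  an exact oracle in the test suite.

Degenerate inputs are first-class: an empty stratum or a zero autosomal
median raises an error naming the threshold and stratum sizes (or, with
`on_error = "skip"`, records an NA row so a sweep survives its extreme
thresholds); a constant profile yields the degenerate interval [1, 1].

## Quantification and expression calls

TPM is computed per sample as the length-normalized count rate rescaled to
sum to $10^6$: $\mathrm{TPM}_g = 10^6 (c_g/\ell_g) / \sum_j (c_j/\ell_j)$,
with $\ell_g$ the annotated gene length (no effective-length correction —
counts summarized over exons carry no fragment-length model; kallisto
input supplies its own TPM and bypasses this step). All-zero samples give
all-zero TPM columns rather than an error. Replicate averaging is the
arithmetic mean. Non-zero TPM columns sum to $10^6$ within $10^{-6}$
relative tolerance, a conserved quantity the tests enforce.

Expression calls use a *strict* inequality, TPM $> t$, with $t = 0.5$ the
conventional low threshold that retains rare transcripts; $t = 0$ returns
every gene. A gene is **line-specific** when it is expressed in its line
and has zero raw counts in *at least one* replicate of the other line.
That any-zero reading is implemented verbatim as the default because it is
the stated rule, even though an all-zero rule may better match intuition;
`rule = "all-zero"` exposes the stricter variant, and the partition records
which was used. Ranked gene lists break TPM ties by gene id so output is
deterministic and prefix-stable.

## The simplified differential-expression stage

The DE stage reproduces the *decision rules* of the standard NB workflow —
drop genes with fewer than 10 reads total, median-of-ratios normalization,
NB Wald test, BH correction, and the dual cutoff |log2FC| > 1 with
adjusted p < $10^{-4}$ (both strict) — without being a numerical clone of
a full GLM fitter. Per gene:

- normalized counts $y = c/s$ with $s$ the median-of-ratios size factors
  (genes with any zero are excluded from the reference geometric mean; if
  no gene is all-positive the factors are undefined and the stage errors);
- $\widehat{\mathrm{log2FC}} = \log_2\frac{\bar y_A + c_0}{\bar y_B + c_0}$
  with pseudo-mean $c_0 = 0.5$ — some offset is mandatory because
  line-specific genes are structural zeros in one group;
- a method-of-moments dispersion from the pooled within-group variance,
  $\hat\alpha = (s^2 - \bar y)/\bar y^2$;
- a delta-method standard error from the NB variance of each group mean,
  and a two-sided p value from the standard normal.

**The dispersion floor.** With three replicates per line the pooled
variance has four degrees of freedom, and a per-gene plug-in Wald
statistic built on it has heavy, $t_4$-like tails: genes whose variance is
underestimated by chance produce spuriously extreme z scores. Instead of
an absolute near-zero floor, each gene's dispersion is floored at the
experiment-wide *median* of the raw method-of-moments dispersions (and at
$10^{-8}$). This is not per-gene empirical-Bayes shrinkage — every gene
above the median keeps its own estimate — but it removes the left tail of
the variance estimate that small-sample designs cannot estimate reliably.
The property tests verify the consequences: null simulations give a
p < 0.05 proportion within 0.05 ± 0.02 and essentially never survive the
dual cutoff, while spiked four-fold changes are detected with high power.
For real data with a strong mean–dispersion trend a single global floor is
crude; that refinement (and outlier handling, independent filtering, LFC
moderation) is deliberately out of scope.

Overrepresentation testing is the one-sided Fisher's exact test — the
hypergeometric upper tail $P(X \ge k)$ for $k$ of $K$ foreground genes
carrying a term that $n$ of $N$ background genes carry — with BH FDR
across terms, the foreground being a line's specific genes and the
background all genes expressed above 0.5 TPM in that line. The term map is
a flat two-column table; no ontology-graph propagation is attempted.

## What the generator emulates, and what it does not

`simulate_experiment` draws, in a fixed documented order: chromosome arms
(X with probability `frac_x = 0.1`, the approximate X-linked share of the
*A. gambiae* gene complement, the rest uniform over the four autosome
arms); gene lengths uniform on [500, 5000] bp, shared by both lines;
baseline rates from a log-normal; label sets (line-specific, spiked DE);
library sizes; then NB counts with
$\mathbb{E}[c_{gs}] = f_s \, r_{g,\mathrm{line}(s)} \, \ell_g/1000$, so
expected counts scale with transcript length and a gene's TPM recovers its
molar rate $r_g$ directly. The X-linked rates of the single-X line A are
`comp_factor_d` times independent draws from the same log-normal as all
other rates, which makes the population X:A ratio of line A exactly $d$ —
the estimand parameter-recovery tests aim at — while line B's X rates are
plain draws (two-X equivalence). Line-specific genes are structural zeros
(rate 0) in the other line, so the zero-replicate rule holds almost
surely; spiked genes are scaled by $2^{\pm \mathrm{lfc}}$ in line A with
alternating signs.

Default study conditions: 5000 genes, 3 replicates per line, NB dispersion
$\alpha = 0.05$, mean library size $5 \times 10^6$ with CV 0.1, 5% of
genes specific to each line, 10% spiked at |log2FC| = 2. The log-normal
spread `mean_log_sigma = 0.4` is chosen for estimator validation rather
than biological realism: it gives the sample median of a 500-gene X
stratum a standard error of a few percent, so that recovery of $d$ to
within 0.05 is a meaningful check rather than noise. Real transcriptomes
are far more dispersed (log-sd around 1.5–2.5, with a long silent tail),
their X:A point estimates correspondingly noisier, and their thresholds
genuinely prune genes — with these defaults the 0.5–40 TPM sweep removes
only a few percent of genes. Passing tests therefore demonstrate the
*estimator and its intervals* behave correctly where the truth is known;
they do not certify performance on the heavier-tailed expression
distributions of real data, nor do they model GC/length bias, isoforms,
batch effects, or correlated genes.

## Reproducibility plumbing

Every stochastic component takes an explicit integer seed and consumes the
RNG in a documented order; `run_pipeline` derives independent per-stage
seeds (simulation vs per-line bootstrap) from one run seed by fixed
offsets, so toggling one stage never perturbs another. Results are written
as full-precision TSV (15 significant digits; write-then-read agrees
within $10^{-9}$), and the JSON manifest echoes the complete effective
configuration, package version and per-stage gene counts so each output
directory is self-describing.

## Validation problem sizes

The test suite validates on sizes where the checks are sharp but quick:
5000-gene experiments for the threshold-sweep and parameter-recovery
checks ($d \in \{0.5, 0.75, 1\}$, 20 seeds each, 2000 bootstrap
replicates), 200 × 1000-gene experiments for CI coverage at $d = 1$,
2000-gene experiments for DE power/calibration, a 10-gene fixed profile
for bit-level bootstrap-oracle agreement (with a 200,000-replicate
reference), and exhaustive small-N enumeration for the hypergeometric and
BH oracles. `scripts/acceptance.R` re-runs the headline simulate →
quantify → sweep computation from scratch at whatever seed it is given.

## Known limitations

- The DE stage is rule-faithful but numerically simplified; it will not
  reproduce another tool's gene lists, only the same decision structure.
- The X:A ratio is a chromosome-wide summary; the package deliberately
  makes no per-gene compensation calls and no claims about DC machinery.
- Whether published median curves were computed on replicate-averaged or
  pooled per-replicate TPM is generally unstated; both modes exist here
  and the choice is recorded in the curve's metadata.
- The generator's structural zeros make line-specificity unrealistically
  clean; real "specific" genes include lowly expressed stragglers that the
  any-zero rule admits by sampling accident.
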