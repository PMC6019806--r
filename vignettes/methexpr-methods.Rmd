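---
title: "Methods: pairwise expression-methylation modeling in methexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise expression-methylation modeling in methexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

## The question and the model

In a panel of breast cancer cell lines, promoter methylation can silence a
gene or, less intuitively, accompany its over-expression. methexpr asks, for
each gene, whether its expression tracks its DNA methylation once two strong
known drivers of expression in these panels — estrogen-receptor (ER) status
and tumour subtype (Luminal / Basal A / Basal B) — are adjusted for.

The measurement platforms do not align one-to-one with genes: an expression
array reports one RMA-summarized log-abundance value per *probeset* (a gene
may have several), and a two-colour methylation array reports one M-value
(log2 red/green ratio) per *probe*, with many probes tiling a gene's CpG
island. Summarizing either side to a single gene-level value first would
average away real heterogeneity between probesets and between probes, so the
analysis unit is the **probeset-probe pair**: for a gene with `m` probesets
and `n` probes, all `m * n` pairs are fitted with

    y_i = beta0 + beta1 * x_i + beta2 * ER_i + beta3 * subtype_i + eps_i,
    eps_i ~ N(0, sigma^2)

where `i` indexes cell lines, `y` is the probeset's expression and `x` the
probe's M-value. Interest centres on `beta1`, the methylation coefficient.

### Inference on beta1

`fit_pair()` reports the marginal two-sided t-test of `beta1` from the full
model. A sequential (Type I) ANOVA with the methylation term listed first
would test `beta1` *unadjusted* for ER and subtype — the order-dependence of
sequential sums of squares contradicts the point of including the
covariates, which is to absorb expression variation they explain. The
marginal test (equivalent to a Type III test for a 1-df term) is therefore
the default; `anova = "sequential"` exposes the sequential alternative for
comparison.

Categorical coding is by treatment contrasts with ERneg and Luminal as
references. Any full-rank coding gives the same `beta1` inference, which is
all the pipeline consumes. A phenotype level absent from the panel simply
loses its indicator column rather than raising an error.

Fits are flagged `degenerate` — and excluded from all downstream counts,
numerator *and* denominator — when the methylation values are constant, the
design is collinear or over-saturated after pairwise deletion of missing
values, or the fit is perfect (zero residual variance, so no t-test
exists). Counting degenerate pairs in denominators would silently dilute
the significant fractions; the excluded count is logged instead.

### Normality screen

Linear-model p-values assume roughly normal residuals. `shapiro_filter()`
applies a Shapiro-Wilk test to each probeset's expression values and
excludes probesets with p below `alpha_norm` (default 0.05) from pair
enumeration. Raw p-values are the default; a `p_adjust = "BH"` switch is
provided because either convention is defensible for a screen whose purpose
is conservative exclusion. Probesets that cannot be tested (fewer than 3
values, zero variance) are excluded with the reason logged.

## Gene-level aggregation

A gene is **long** when it has more than 2 probesets or more than 20 probes
(strict inequalities; the cuts sit near the third quartiles of typical
annotations and are configurable), otherwise **short**. Long genes have
many pairs, so a fixed count threshold would be too easy for them; instead
a long gene is called significant when *more than* 15% of its pairs have
`beta1_p < 0.05`, a short gene when *more than* 30% do. All comparisons are
strict, so exact-boundary cases (3 of 10 pairs significant for a short
gene) fail.

A gene's **direction** is positive (negative) when strictly more than half
of its non-degenerate pairs have a positive (negative) `beta1` — all pairs,
not only significant ones, and an exactly-zero coefficient counts for
neither side. In parallel, `coeff_filter()` extracts pairs with a large and
significant coefficient (`|beta1| > 0.5`, and the stricter `> 1`), tracking
both pair counts and unique-gene counts (one gene can contribute several
pairs, so genes never exceed pairs). The **final** lists intersect the two
routes: genes with a large significant coefficient in at least one pair
*and* a sufficient significant fraction in the matching direction. All
cutoffs are `run_config()` keys; the defaults are deliberate but not
sacred — tightening them shortens the lists without much affecting which
genes dominate the network analysis downstream.

## Probe methylation states and expression level

For genes of interest, `probe_t_test()` runs a two-sided one-sample t-test
of each probe's mean M-value against zero: hypermethylated if the mean is
positive and `p < 0.05`, hypomethylated if negative and `p < 0.05`,
otherwise `N/A` (which also absorbs untestable probes, flagged
separately). The test is two-sided because the sign gate supplies the
direction; sidedness only rescales p. Per-gene summaries report counts and
percentages rounded half-up to 2 decimals — the convention that reproduces
standard table renderings (24/41 -> 58.54%) — and `is_majority_hyper()`
tests the strict rule "more hypermethylated probes than hypomethylated and
N/A combined". `flag_low_expression()` compares each probeset's maximum
expression across samples with the housekeeping reference level 8 (strictly
below flags the probeset as low-expressed).

## Hub genes

The final gene lists are contextualized in an interaction network imported
as an edge list (e.g. exported from a pathway database after filtering to
high-confidence binary protein, genetic and regulatory interactions — the
filter is re-applied at load). The induced subnetwork keeps isolated input
genes and marks nodes the source added ("intermediate" nodes); both are
eligible hubs. Because visual hub-picking is not reproducible, two explicit
rules are offered: `top_k` (default k = 8, with all nodes tied at the k-th
degree included, so the result cannot depend on row order) and
`degree_min`. The full degree table is always returned so users can apply
their own judgment.

## The synthetic-data generator

`generate_dataset()` emulates the shape of a 40-cell-line microarray panel:
ER is Bernoulli(0.5), subtype uniform over three levels, expression clipped
to [2, 13.5] and M-values falling nearly always in [-4, 4]. Each gene `g`
carries a latent per-sample methylation signal
`t[g,s] ~ N(mu_g, meth_sd^2)` with `mu_g` uniform on [-1, 1]. Every probe
of the gene observes that shared signal plus probe-level noise with SD
`probe_sd` (default 0.1), optionally equicorrelated across probes with
coefficient `rho`; every probeset's expression responds to the *latent*
signal with the gene's true coefficient `beta1`, plus ER/subtype effects
and residual noise `sigma` (default 1).

Two consequences are intentional. First, a gene's `m * n` pair fits are
correlated — some but not all pairs of a truly associated gene reach
significance, which is what gene-level aggregation must cope with on real
arrays. Second, the probe-level noise attenuates the pair-level slope by
the factor `meth_sd^2 / (meth_sd^2 + probe_sd^2)` (about 1% at the
defaults), so parameter recovery can be assessed against the nominal
`beta1` without a correction. What the generator does **not** emulate:
genomic probe coordinates and region-dependent spatial correlation of
methylation (real neighbouring probes correlate weakly and
heterogeneously, roughly within ±0.3; equicorrelation is a deliberate
simplification because no single spatial model fits a whole genome), dye
bias, batch effects and array artifacts, and heavy-tailed expression
noise. Passing tests on this generator therefore validate the *inference
and bookkeeping machinery*, not robustness to every pathology of real
arrays.

Defaults for quantities the study conditions do not pin down were chosen
once for realism and clear power separation: `beta1_magnitude = 1`,
`sigma = 1` (unit signal-to-noise per pair at 40 samples), `m` uniform on
1–3 and `n` on 5–30 (a mix of long and short genes), baseline expression
uniform on [6, 9] with ER effect 0.8 and subtype effects ±0.4 (keeps
clipping events rare — they are counted and reported in the result,
because clipping biases recovery slightly). Expression values are clipped
rather than resampled so the marginal ranges hold exactly.

## Numerical and calibration choices

* OLS is computed through R's QR path (`lm.fit`); tests verify it against
  an independent normal-equations + t-distribution oracle at 1e-8 relative
  tolerance on hundreds of random pairs.
* A fit counts as perfect (degenerate) when the residual sum of squares is
  below `1e-10 * sum(y^2)`.
* Calibration checks (type-I error in [0.040, 0.060] at alpha = 0.05, KS
  uniformity of null p-values) are run on 5000 genes with one probeset and
  one probe each: the band presumes independent tests, and one pair per
  gene is the configuration in which the 5000 pairs are independent. With
  shared per-gene signals, a gene's pairs are near-replicates and the
  effective sample size would be far smaller than the pair count.
* Recovery checks use the default configuration at 100 genes
  (30 positive, 30 negative, 40 null): mean per-gene `beta1` within ±0.05
  of truth per group, at least 80% of true-effect genes entering the
  correct final list, and no more than 5% entering the wrong-direction
  list. Problem sizes throughout the test-suite were chosen so the whole
  suite completes in well under a minute of numerical work per check.
* End-to-end runs are deterministic from the seed; numeric outputs are
  formatted with fixed precision so reruns are byte-identical (manifest
  stage timings are the one intentionally non-reproducible field).

## Known limitations

* Direction calls use coefficient signs over all pairs, so a null gene with
  correlated pairs usually still gets a direction; direction is meaningful
  only in combination with the significance filters, as in the final lists.
* Spatial/AR correlation of probes along a CpG island is not modelled, by
  design; an analysis that exploits it would need a different pair-level
  model, not just a different generator.
* Hypermethylation here is relative to the array's internal zero (equal
  red/green intensity), not to normal-tissue controls, which the design
  does not include.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(simulate = list(n_genes = 40, seed = 1), seed = 1)
res <- run_pipeline(cfg, out_dir = "methexpr_out")
res
res$lists$list_table
truth_confusion(res$summaries, res$data$truth)
```
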