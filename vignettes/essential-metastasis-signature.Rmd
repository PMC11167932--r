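---
title: "Deriving essential gene signatures of breast cancer metastasis"
author: "metsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving essential gene signatures of breast cancer metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsig)
```

## The model

Bulk expression differences between a metastasis and its paired primary
tumor mix two signals: changes intrinsic to the cancer cells, and the
normal tissue of the biopsy site (liver in a liver metastasis, lung in
a lung metastasis). `metsig` separates them by requiring a second,
orthogonal line of evidence: a gene must be both **higher in metastasis
versus paired primary** and **essential for breast cancer cell
proliferation** in CRISPR dependency screens. Normal-tissue
contamination genes are not essential in breast cancer cell lines, so
the intersection is purged of the biopsy-site confound.

Formally, for gene $g$ with per-patient log2 differences
$d_{gi} = x^{met}_{gi} - x^{pri}_{gi}$ over $n$ pairs, the paired test
statistic is $t_g = \bar d_g / (s_g / \sqrt n)$ with $n - 1$ degrees of
freedom. The pipeline never adjusts per-gene p-values; instead it
reports the aggregate expected/observed FDR, $N\alpha / n_{sig}$, the
cohort-level rate implied by the unadjusted threshold. Essentiality is
binarized at a gene-effect score of $-0.75$ per cell line; a
metastasis-high gene is *essential* when the fraction of assayed lines
below that cutoff strictly exceeds 0.10, *nonessential* when no line is
below it, and *intermediate* otherwise. Overlap significance uses the
2×2 table over the measured gene universe: expected overlap
$|A||B|/N$, Pearson chi-square (df 1), and the one-sided Fisher exact
p as the hypergeometric upper tail.

Downstream, a sample's **signature t-score** is the two-sample
t-statistic comparing the SD-from-median-standardized expression of the
signature genes against all other genes in that profile (or up versus
down genes for bidirectional signatures). Scores feed univariate and
multivariate Cox models, a tertile log-rank test, and a null exercise
with random gene signatures of equal size.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| DE threshold `alpha` | 0.001 | p-value | the discovery cutoff for "differential"; strict `<` |
| effect-score threshold | −0.75 | Chronos score | binarizes per-line essentiality; strict `<` |
| essential-line fraction | 0.10 | fraction | strict `>`; denominator is lines assayed for that gene |
| log2 offset | 1 | TPM | log2(TPM+1) maps zero TPM to zero; inverse is 2^x − 1 |
| tissue-contrast `alpha` | 1e-6 | p-value | breast-vs-pooled-nonbreast selection |
| replication `alpha` | 0.05 | p-value | per-gene compendium threshold |
| knockdown threshold | −0.5 | SD units | strict `<`, defines downstream targets |
| upstream window | 2000 | bp | strand-aware promoter window for TF target calls |
| random signatures `n` | 100 | count | size of the coordination/prognosis null |
| log-rank cutpoints | 1/3, 2/3 | quantiles | equal tertiles for low/intermediate/high |

## Design choices where the recipe was open

* **Variance flavor.** All two-sample tests (tissue contrast, t-score)
  use the Welch unequal-variance statistic: the group sizes are wildly
  unbalanced (a few hundred signature genes against thousands of
  background genes; hundreds of breast samples against thousands of
  non-breast). A pooled-variance variant sits behind `pooled = TRUE`.
  SDs use the $n-1$ denominator throughout, consistent with the
  t-statistics.
* **Quantile-normalization ties.** Tied values within a column receive
  the mean of the reference quantiles they span (Bolstad-style, via
  limma), making the operation deterministic and idempotent.
* **Zero-variance genes** are dropped at standardization (they carry no
  information in SD units) with a logged count; per-gene Cox fits and
  centroid correlations likewise exclude them.
* **Degenerate paired tests.** A gene whose paired differences are all
  identical has zero variance: p is set to 1 when the common difference
  is 0, otherwise to the smallest representable double, and the gene is
  flagged rather than silently producing NaN.
* **Compendium scaling scope.** Pair-centered values are divided by one
  SD per study, computed jointly over all centered metastasis and
  primary entries — the most direct reading of "unitless differential
  expression"; a per-profile variant is available via
  `sd_scope = "profile"`.
* **Promoter windows are strand-aware** ([start−2000, start) on the
  plus strand, [end, end+2000) on the minus strand, half-open BED
  coordinates, clipped at zero); a strand-naive mode supports
  sensitivity checks. "Intersects" means nonempty overlap of half-open
  intervals.
* **Cox ties** use Efron's method; discretized survival times make ties
  likely.
* **Subtype assignment ties** are broken by the model's fixed subtype
  order with a warning; original-study labels, when present, should be
  preferred over inferred ones by the caller.
* **Zero-inclusive imputation medians.** The single-cell gene median
  used to impute zeros includes the zeros themselves (the literal
  reading); `include_zeros = FALSE` gives the alternative.
* **Duplicate gene ids on ingest** collapse to the row with the highest
  mean expression.
* **Interface.** The pipeline is exposed as R functions plus
  `run_pipeline()`; readers/writers cover expression TSV, GMT, 6-column
  BED (0-based half-open), and survival CSV. No shell entry point is
  shipped: the package is a library, and `scripts/acceptance.R` shows
  the scripted usage pattern.

## What the synthetic cohorts emulate

`sim_config()` defaults define the study conditions: 5,000 genes, 60
metastasis/primary pairs, four biopsy sites (liver 40% with a doubled
site effect, lung/brain/bone 20% each), 46 CRISPR-screened cell lines,
a 1,000-sample survival cohort, and four single-cell types with 150
cells each. Gene roles partition the universe: 5% cancer-intrinsic
metastasis genes (log2 effect +1, essential in 60% of lines), 6%
site-confounder genes, 4% breast markers (−1 in metastases, +1 in
normal breast), 4% cell-cycle genes (essential but not
metastasis-differential), the rest neutral. Baseline log2 means are
Normal(5, 2) truncated at 1.5 — a TPM-scale dynamic range whose
back-transform 2^x − 1 round-trips losslessly through log2(TPM+1) —
and noise is iid Gaussian with SD 0.5 log2 units.

Site-confounder genes carry a shared non-breast-tissue component
(half the site effect, present in every metastasis and in every
non-breast tissue of the normal panel) plus the full site-specific
effect at their own site. This reflects that every metastatic biopsy
site is non-breast tissue, and it is what makes minority-site
confounder genes recoverable in a 60-pair cohort: a purely
site-specific effect for a site sampled at rate $f$ caps the paired
t-statistic near $\sqrt{nf/(1-f)}$ ($\approx 3.9$ at $f = 0.2$,
$n = 60$), right at the $p < 0.001$ boundary, however large the
effect.

The survival generator draws a latent activity $a \sim N(0,1)$ per
sample that loads on every intrinsic gene (coordinate expression) and
sets the event hazard to $\propto e^{\beta a}$ with $\beta = 0.5$;
censoring is independent exponential with its rate solved numerically
to hit the configured 30% fraction. Effect scores separate cleanly:
essential calls draw from Uniform(−2, −0.8), non-essential from
Uniform(−0.6, 0.5), with a 1% per-line false-call rate — so zero-noise
configurations recover the planted partition exactly. Single-cell
counts are negative binomial (size 2); the cancer-epithelial type
overexpresses intrinsic genes 5-fold and one non-cancer type
overexpresses the dominant site's confounder genes.

All randomness flows from one master seed through named substreams, so
each output is individually reproducible and regenerating with the
same configuration is byte-identical.

**What passing tests do not show.** The generator plants clean additive
log2 effects, independent Gaussian noise, exponential event times, and
role labels that are marginally independent of everything they should
be independent of. Real cohorts have correlated genes, batch structure,
heavy-tailed noise, informative censoring, and partial overlap between
tissue markers and cancer programs; recovery rates on synthetic data
are therefore upper bounds on real-data behavior, and the published
cohort-specific numbers (the 264-gene signature, external survival
curves, 182/248 replication) are not reproducible without the
restricted datasets.

## Problem sizes used in the test suite

Unit tests run on reduced cohorts (800 genes, 24 pairs, 200 survival
samples) chosen so each planted effect remains comfortably detectable
at the thresholds the tests assert; the acceptance-style checks run at
the full default configuration (5,000 genes, 60 pairs, 1,000 survival
samples, 100 random signatures, 20-seed null calibration, 50-seed Cox
calibration). The exhaustive Fisher-vs-enumeration sweep covers every
2×2 table with a universe of 30 or fewer genes.

## Known limitations

* The per-gene Cox screen (`prognosis_gene_overlap`) fits one model per
  gene serially; for very large matrices expect minutes, not seconds.
* `quantile_normalize` targets dense matrices; sparse single-cell
  matrices are densified by the scoring pipeline.
* The aggregate FDR estimate is the expected/observed ratio, not a
  per-gene q-value; it matches the analysis it accompanies, no more.
* Subtype centroids are built from whatever reference is supplied; the
  package ships no canonical PAM50 gene list or centroid set.
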