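# metsig

Essential gene signatures of breast cancer metastasis.

## The problem

When a breast cancer metastasis is profiled next to its paired primary
tumor, thousands of genes look differentially expressed — but most of
that signal is not cancer biology. A liver metastasis biopsy contains
liver; a lung metastasis contains lung. The bulk expression difference
between metastasis and primary is therefore dominated by the *biopsy
site's normal tissue*, not by changes intrinsic to the cancer cells.

`metsig` implements a strategy for separating the two: intersect the
genes **higher in metastasis versus paired primary** (paired t-test on
log2 expression) with the genes **essential for breast cancer cell
survival** in CRISPR dependency screens. Tissue-contamination genes are
not essential in breast cancer cell lines, so the intersection — the
*essential metastasis signature* — is enriched for cancer-cell-intrinsic
biology, while the metastasis-high genes with *no* essential cell lines
(the *nonessential* set) serve as a tissue-confound contrast.

The package is written for computational biologists analyzing paired
tumor cohorts with access to dependency-screen data, and ships a
synthetic-data module that generates every input with planted ground
truth, so the full pipeline is testable with no external downloads.

## The statistics at the core

* **Paired differential expression.** Per gene, a one-sample t-test of
  the per-patient differences d_i = x_met,i − x_pri,i against 0, with
  an aggregate FDR estimate: FDR = (N·α) / n_significant. At the
  published counts (N = 28,248 genes, α = 0.001, 3,927 significant)
  this gives 0.007.
* **Essentiality partition.** A gene is essential in a cell line when
  its Chronos-style gene-effect score is < −0.75; a metastasis-high
  gene is *essential* when more than 10% of assayed lines qualify, and
  *nonessential* when none does.
* **Contingency enrichment.** For sets A, B in a universe of N genes,
  the expected chance overlap |A||B|/N, the Pearson chi-square (df 1,
  no continuity correction), and the one-sided Fisher exact p
  (hypergeometric upper tail). With |A| = 2,115, |B| = 1,810,
  N = 28,248 the expected overlap is 135.5 ≈ 136; an observed overlap
  of 264 gives chi-square p ≈ 1.9 × 10⁻³².
* **Signature t-score.** Per sample, the two-sample t-statistic
  comparing SD-from-median-standardized expression of the signature
  genes against all other genes (or up vs down genes for bidirectional
  signatures), followed by Cox proportional-hazards and log-rank
  survival association and a 100-random-signature null.
* **Supporting stages.** Quantile normalization, normal-tissue
  contrasts, pair-centered cross-study replication, nearest-centroid
  (PAM50-style) subtyping, strand-aware 2 kb promoter-window TF target
  assignment, knockdown target sets (< −0.5 in SD units), and a
  single-cell scoring recipe (filter > 10% nonzero, median-impute
  zeros, quantile normalize, log2, standardize, average).

## Worked example

```r
library(metsig)

cfg   <- sim_config(seed = 1)                 # 5,000 genes, 60 pairs
gen   <- generate_paired_cohort(cfg)
lg    <- gen$cohort
lg$expr <- log2_transform(lg$expr, 1)

de     <- paired_differential(lg)
higher <- select_differential(de, 0.001, "higher")
length(higher)
#> [1] 551

scores <- generate_effect_scores(gen$truth, cfg)
part   <- classify_genes(higher, count_essential_lines(scores))
table(part$class)
#>     essential intermediate nonessential
#>           250          100          201

dep_essential <- subset(count_essential_lines(scores),
                        n_essential / n_assayed > 0.10)$gene
overlap_stats(higher, dep_essential, de$gene)
#> 2x2 overlap: a=250 (expected 49.59 ~ 50), |A|=551, |B|=450, N=5000
#>   chi-square (df 1) = 1000.255, p = 1.58e-219; one-sided Fisher p = 8.62e-140; OR = 17.6
```

The 551 metastasis-high genes split into 250 essential (the planted
cancer-intrinsic genes), 201 nonessential (the planted biopsy-site
genes), and 100 in between; the overlap between metastasis-high and
dependency-essential genes (which also include the planted cell-cycle
genes) is five times its chance expectation of ~50. Scoring a survival cohort
with the essential set and fitting a univariate Cox model on the
planted activity recovers the planted log-hazard coefficient:

```r
sv  <- generate_survival_cohort(gen$truth, cfg)
cox_univariate(sv$planted_score, sv$surv)$coef
#> [1] 0.4679085        # planted beta = 0.5
```

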