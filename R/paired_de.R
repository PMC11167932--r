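#' Paired metastasis-versus-primary differential expression
#'
#' For each gene, a one-sample t-test of the per-patient
#' (metastasis - primary) log2 differences against zero, with two-sided
#' p-values from the t distribution on n_pairs - 1 degrees of freedom.
#' Pairs with a missing value for a gene are dropped gene-wise
#' (pairwise-complete), so n_pairs can vary by gene. A gene whose
#' differences are all identical has zero variance: p is 1 when the common
#' difference is 0, otherwise the smallest representable double, and the
#' gene is flagged in the `degenerate` column.
#'
#' @param cohort a [paired_cohort()] in log2 units with >= 3 pairs.
#' @return data.frame (one row per gene): `gene`, `mean_diff` (log2,
#'   metastasis - primary), `t`, `p`, `n_pairs`, `degenerate`.
#' @export
paired_differential <- function(cohort) {
  .check_units(cohort$expr, "log2")
  .assert(nrow(cohort$pairs) >= 3L, "need >= 3 pairs for a paired t-test")
  d <- pair_differences(cohort)
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  s <- .row_sds(d)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  degen <- is.finite(s) & s == 0
  tstat[degen] <- ifelse(m[degen] == 0, 0, sign(m[degen]) * Inf)
  p[degen] <- ifelse(m[degen] == 0, 1, .Machine$double.xmin)
  data.frame(gene = rownames(d), mean_diff = m, t = tstat, p = p,
             n_pairs = n, degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differential genes at a significance threshold
#'
#' Strict inequalities throughout: `higher` genes have p < alpha and a
#' positive mean paired difference, `lower` the converse.
#'
#' @param res result of [paired_differential()].
#' @param alpha significance level in (0, 1].
#' @param direction `"higher"`, `"lower"`, or `"both"`.
#' @return character vector of gene ids (for `"both"`, a list with
#'   elements `higher` and `lower`).
#' @export
select_differential <- function(res, alpha = 0.001,
                                direction = c("higher", "lower", "both")) {
  direction <- match.arg(direction)
  .assert(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  sig <- !is.na(res$p) & res$p < alpha
  hi <- res$gene[sig & res$mean_diff > 0]
  lo <- res$gene[sig & res$mean_diff < 0]
  switch(direction, higher = hi, lower = lo,
         both = list(higher = hi, lower = lo))
}

#' Aggregate expected/observed FDR estimate
#'
#' The expected number of chance-significant genes (`n_genes * alpha`)
#' divided by the number actually observed significant: a cohort-level
#' false discovery rate for an unadjusted per-gene threshold.
#'
#' @param n_genes number of genes tested.
#' @param alpha the per-gene significance threshold used.
#' @param n_significant number of genes observed significant at `alpha`.
#' @return the FDR estimate (scalar).
#' @export
estimate_fdr <- function(n_genes, alpha, n_significant) {
  .assert(n_significant > 0, "FDR undefined with zero significant genes")
  (n_genes * alpha) / n_significant
}
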