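#' Normal-tissue contrast (target tissue vs pooled others)
#'
#' Welch two-sample t-test per gene comparing the target tissue's samples
#' against all other samples pooled, on log2 values. Gene sets
#' `high_in_target` / `low_in_target` use strict p < alpha split by the
#' sign of t.
#'
#' @param panel expression matrix (log2 units) of normal tissues.
#' @param tissue character vector of tissue labels, one per column of
#'   `panel`.
#' @param target_label the tissue of interest (e.g. breast).
#' @param alpha significance threshold; default 1e-6.
#' @return list of class `tissue_contrast`: `stats` (data.frame gene, t,
#'   p), `high_in_target`, `low_in_target`, `target_label`, `alpha`.
#' @export
tissue_contrast <- function(panel, tissue, target_label, alpha = 1e-6) {
  .check_units(panel, "log2")
  .assert(length(tissue) == ncol(panel), "one tissue label per sample")
  in_target <- tissue == target_label
  .assert(sum(in_target) >= 2L && sum(!in_target) >= 2L,
          "both tissue groups need >= 2 samples")
  w <- .row_welch(panel, which(in_target), which(!in_target))
  sig <- !is.na(w$p) & w$p < alpha
  structure(list(
    stats = data.frame(gene = rownames(panel), t = w$t, p = w$p,
                       row.names = NULL, stringsAsFactors = FALSE),
    high_in_target = rownames(panel)[sig & w$t > 0],
    low_in_target = rownames(panel)[sig & w$t < 0],
    target_label = target_label, alpha = alpha),
    class = "tissue_contrast")
}

#' Cross-tabulate metastasis gene sets against tissue gene sets
#'
#' The four pairwise overlaps (met-high x tissue-high, met-high x
#' tissue-low, met-low x tissue-high, met-low x tissue-low), each tested
#' with [overlap_stats()] over the shared universe.
#'
#' @param met_high,met_low gene sets from the paired analysis.
#' @param tissue_high,tissue_low gene sets from [tissue_contrast()].
#' @param universe gene universe for the tables (typically the
#'   intersection of the two datasets' gene universes).
#' @return named list of four `contingency_result`s:
#'   `met_high_x_tissue_high`, `met_high_x_tissue_low`,
#'   `met_low_x_tissue_high`, `met_low_x_tissue_low`.
#' @export
crosstab_sets <- function(met_high, met_low, tissue_high, tissue_low,
                          universe) {
  f <- function(a, b) overlap_stats(intersect(a, universe),
                                    intersect(b, universe), universe)
  list(met_high_x_tissue_high = f(met_high, tissue_high),
       met_high_x_tissue_low = f(met_high, tissue_low),
       met_low_x_tissue_high = f(met_low, tissue_high),
       met_low_x_tissue_low = f(met_low, tissue_low))
}

#' Immune-infiltrate scoring of paired tumors
#'
#' For each patient and marker set, the mean over the set's genes of the
#' paired (metastasis - primary) log2 differences; per set, a one-sample
#' t-test of those patient means against 0 asks whether the inferred
#' infiltrate changes systematically in metastases.
#'
#' @param cohort a [paired_cohort()] in log2 units.
#' @param marker_sets named list of marker gene sets (e.g. T cells,
#'   B cells).
#' @return list: `scores` (patients x sets matrix of mean paired fold
#'   changes) and `tests` (data.frame set, mean, t, p, n_genes_used).
#' @export
immune_infiltrate_score <- function(cohort, marker_sets) {
  .check_units(cohort$expr, "log2")
  d <- pair_differences(cohort)
  res <- lapply(names(marker_sets), function(nm) {
    g <- intersect(marker_sets[[nm]], rownames(d))
    if (length(g) == 0L)
      stop("marker set '", nm, "' has no genes in the cohort")
    colMeans(d[g, , drop = FALSE], na.rm = TRUE)
  })
  scores <- do.call(cbind, res)
  colnames(scores) <- names(marker_sets)
  tests <- do.call(rbind, lapply(names(marker_sets), function(nm) {
    v <- scores[, nm]
    n <- sum(!is.na(v)); m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    tt <- m / (s / sqrt(n))
    p <- if (s == 0) as.numeric(m == 0) else 2 * pt(-abs(tt), n - 1)
    if (s == 0 && m == 0) { tt <- 0; p <- 1 }
    data.frame(set = nm, mean = m, t = tt, p = p,
               n_genes_used = length(intersect(marker_sets[[nm]],
                                               rownames(d))),
               stringsAsFactors = FALSE)
  }))
  list(scores = scores, tests = tests)
}

#' Per-site summaries of paired fold change over a gene set
#'
#' For each metastasis sample, the mean over the gene set of the paired
#' (metastasis - primary) log2 differences; samples are grouped by biopsy
#' site and summarized with the 5/25/50/75/95% quantiles (type-7).
#'
#' @param cohort a [paired_cohort()] in log2 units whose annotation has a
#'   `site` column.
#' @param gene_set character vector of gene ids.
#' @return list: `per_sample` (data.frame patient, sample, site,
#'   mean_fold_change) and `by_site` (data.frame site, n, q05, q25, q50,
#'   q75, q95).
#' @export
site_foldchange_summary <- function(cohort, gene_set) {
  .check_units(cohort$expr, "log2")
  .assert("site" %in% names(cohort$samples), "annotation lacks a site column")
  d <- pair_differences(cohort)
  g <- intersect(gene_set, rownames(d))
  .assert(length(g) > 0, "gene_set has no genes in the cohort")
  fc <- colMeans(d[g, , drop = FALSE], na.rm = TRUE)
  site <- cohort$samples$site[match(cohort$pairs$metastasis,
                                    cohort$samples$sample)]
  per_sample <- data.frame(patient = cohort$pairs$patient,
                           sample = cohort$pairs$metastasis,
                           site = site, mean_fold_change = fc,
                           row.names = NULL, stringsAsFactors = FALSE)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  by_site <- do.call(rbind, lapply(split(per_sample, per_sample$site),
    function(ss) {
      q <- quantile(ss$mean_fold_change, qs, type = 7, names = FALSE)
      data.frame(site = ss$site[1L], n = nrow(ss),
                 q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5],
                 stringsAsFactors = FALSE)
    }))
  rownames(by_site) <- NULL
  list(per_sample = per_sample, by_site = by_site)
}
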