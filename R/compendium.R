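#' Pair-center and study-scale an external cohort
#'
#' Cross-study normalization for compendium analyses: each metastasis
#' log2 profile is centered on its paired primary (the primary becomes
#' identically zero), then all centered values in the study — metastasis
#' and primary entries jointly — are divided by their standard deviation,
#' rendering the values unitless (SD units) so studies can be pooled.
#' A per-profile SD variant is available for sensitivity checks.
#'
#' @param study a [paired_cohort()] in log2 units.
#' @param sd_scope `"study"` (default: one SD over all centered entries of
#'   the study) or `"profile"` (each profile divided by its own SD).
#' @return list of class `compendium_study`: `centered` (genes x samples
#'   matrix in SD units, primaries all zero), `pairs`, `samples`,
#'   `scale_sd` (the divisor(s) used).
#' @export
center_and_scale <- function(study, sd_scope = c("study", "profile")) {
  sd_scope <- match.arg(sd_scope)
  .check_units(study$expr, "log2")
  keep <- c(study$pairs$metastasis, study$pairs$primary)
  x <- study$expr[, keep, drop = FALSE]
  x[, study$pairs$metastasis] <-
    x[, study$pairs$metastasis, drop = FALSE] -
    x[, study$pairs$primary, drop = FALSE]
  x[, study$pairs$primary] <- 0
  if (sd_scope == "study") {
    s <- sd(as.vector(x))
    if (!is.finite(s) || s == 0)
      stop("degenerate study: zero variance after pair-centering")
    x <- x / s
  } else {
    s <- apply(x, 2L, sd)
    s[colnames(x) %in% study$pairs$primary] <- 1  # primaries are all-zero
    if (any(!is.finite(s) | s == 0))
      stop("degenerate profile: zero variance after pair-centering")
    x <- sweep(x, 2L, s, "/")
  }
  structure(list(centered = .set_units(x, "sd"), pairs = study$pairs,
                 samples = study$samples, scale_sd = s),
            class = "compendium_study")
}

#' Replication of a signature across a compendium of paired studies
#'
#' Pools the pair-centered, SD-scaled metastasis profiles of all studies
#' and tests each gene's centered differences against zero with a paired
#' (one-sample) t-test. A signature gene replicates when p < alpha with a
#' positive mean. The signature's overlap with all replicated genes is
#' tested by one-sided Fisher over the compendium's gene universe.
#'
#' @param studies list of `compendium_study` objects (see
#'   [center_and_scale()]), sharing a gene universe (intersection used).
#' @param signature character vector of gene ids.
#' @param alpha per-gene replication threshold; default 0.05.
#' @return list: `per_gene` (data.frame gene, mean_diff, t, p, n_pairs),
#'   `replicated` (gene set), `signature_tested` (signature genes present
#'   in the compendium), `replicated_fraction` (of the signature),
#'   `overlap` (a `contingency_result`).
#' @export
replication_test <- function(studies, signature, alpha = 0.05) {
  .assert(length(studies) >= 1L, "need at least one study")
  genes <- Reduce(intersect, lapply(studies, function(s) rownames(s$centered)))
  .assert(length(genes) > 0, "studies share no genes")
  d <- do.call(cbind, lapply(studies, function(s)
    s$centered[genes, s$pairs$metastasis, drop = FALSE]))
  sig_in <- intersect(signature, genes)
  if (length(sig_in) == 0L) stop("signature has no genes in the compendium")
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  s <- .row_sds(d)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), n - 1)
  replicated <- genes[!is.na(p) & p < alpha & m > 0]
  list(per_gene = data.frame(gene = genes, mean_diff = m, t = tstat, p = p,
                             n_pairs = n, row.names = NULL,
                             stringsAsFactors = FALSE),
       replicated = replicated,
       signature_tested = sig_in,
       replicated_fraction = mean(sig_in %in% replicated),
       overlap = overlap_stats(sig_in, replicated, genes))
}

#' Overlap of a published signature with the essentiality partition
#'
#' One-sided Fisher enrichment of a previously published metastasis gene
#' set against the essential and nonessential metastasis sets.
#'
#' @param published character vector of gene ids.
#' @param essential,nonessential the two partition classes.
#' @param universe gene universe for the tables.
#' @return named list of two `contingency_result`s: `vs_essential`,
#'   `vs_nonessential`.
#' @export
published_signature_overlap <- function(published, essential, nonessential,
                                        universe) {
  pub <- intersect(published, universe)
  list(vs_essential = overlap_stats(pub, intersect(essential, universe),
                                    universe),
       vs_nonessential = overlap_stats(pub, intersect(nonessential, universe),
                                       universe))
}
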