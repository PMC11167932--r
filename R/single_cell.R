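# Single-cell signature scoring: filter -> impute -> quantile-normalize ->
# log2 -> SD-from-median -> per-cell signature mean.

#' Filter genes by nonzero fraction across cells
#'
#' @param counts genes x cells non-negative count matrix.
#' @param min_nonzero_frac keep genes whose fraction of nonzero cells is
#'   strictly greater than this; default 0.10.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, min_nonzero_frac = 0.10) {
  .assert(all(counts >= 0), "counts must be non-negative")
  keep <- rowMeans(counts > 0) > min_nonzero_frac
  counts[keep, , drop = FALSE]
}

#' Impute zero counts with the gene's median
#'
#' Each zero entry is replaced by that gene's median across all cells,
#' computed on the pre-imputation values. The zero-inclusive median is
#' the default; `include_zeros = FALSE` computes the median over nonzero
#' cells only.
#'
#' @param counts genes x cells count matrix.
#' @param include_zeros include zeros when computing the gene median;
#'   default TRUE.
#' @return matrix with zeros imputed.
#' @export
impute_zeros <- function(counts, include_zeros = TRUE) {
  med <- if (include_zeros) .row_medians(counts) else
    apply(counts, 1L, function(x) if (any(x > 0)) median(x[x > 0]) else 0)
  idx <- which(counts == 0, arr.ind = TRUE)
  counts[idx] <- med[idx[, 1L]]
  counts
}

#' Score cells for a gene signature
#'
#' The full per-cell scoring recipe: filter genes by nonzero fraction,
#' impute zeros with gene medians, quantile-normalize cells, log2(x + 1),
#' standardize each gene to SD-from-median across cells, then average the
#' signature genes within each cell profile.
#'
#' @param counts genes x cells count matrix.
#' @param signature character vector of gene ids (>= 2 must survive
#'   filtering).
#' @param min_nonzero_frac,include_zeros passed to [filter_genes()] and
#'   [impute_zeros()].
#' @return named numeric vector: one score per cell (attribute
#'   `n_signature_used`).
#' @export
score_cells <- function(counts, signature, min_nonzero_frac = 0.10,
                        include_zeros = TRUE) {
  x <- filter_genes(counts, min_nonzero_frac)
  lost <- setdiff(intersect(signature, rownames(counts)), rownames(x))
  surviving <- intersect(signature, rownames(x))
  if (length(surviving) < 2L)
    stop("fewer than 2 signature genes survive filtering; lost: ",
         paste(head(lost, 10), collapse = ", "))
  x <- impute_zeros(x, include_zeros)
  x <- quantile_normalize(expression_matrix(x, "TPM"))
  x <- log2_transform(x, offset = 1)
  z <- suppressMessages(standardize_sd_from_median(x))
  surviving <- intersect(surviving, rownames(z))
  if (length(surviving) < 2L)
    stop("fewer than 2 signature genes with nonzero variance")
  scores <- colMeans(z[surviving, , drop = FALSE])
  attr(scores, "n_signature_used") <- length(surviving)
  scores
}

#' Summarize per-cell scores by cell type
#'
#' @param scores named per-cell scores (see [score_cells()]).
#' @param labels cell-type label per cell (same order/names as `scores`).
#' @return data.frame: `cell_type`, `n`, and the 5/25/50/75/95% quantiles
#'   (`q05`, `q25`, `q50`, `q75`, `q95`; type-7 interpolation).
#' @export
summarize_by_type <- function(scores, labels) {
  .assert(length(labels) == length(scores), "one label per cell")
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  out <- do.call(rbind, lapply(split(as.numeric(scores), labels),
    function(v) {
      q <- quantile(v, qs, type = 7, names = FALSE)
      data.frame(n = length(v), q05 = q[1], q25 = q[2], q50 = q[3],
                 q75 = q[4], q95 = q[5])
    }))
  data.frame(cell_type = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
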