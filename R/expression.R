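#' Construct an expression matrix with a units flag
#'
#' The universal carrier across pipeline stages: a numeric genes x samples
#' matrix whose `units` attribute records its provenance: `"TPM"` (linear
#' abundance), `"log2"` (log2-transformed), or `"sd"` (gene-wise standard
#' deviations from the median).
#'
#' @param x numeric matrix, genes as rows (unique rownames), samples as
#'   columns (unique colnames).
#' @param units one of `"TPM"`, `"log2"`, `"sd"`.
#' @return the matrix with its `units` attribute set.
#' @export
expression_matrix <- function(x, units = c("TPM", "log2", "sd")) {
  units <- match.arg(units)
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  .assert(!is.null(rownames(x)) && !anyDuplicated(rownames(x)),
          "gene ids (rownames) must be present and unique")
  .assert(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
          "sample ids (colnames) must be present and unique")
  .assert(all(is.finite(x) | is.na(x)), "values must be finite or NA")
  attr(x, "units") <- units
  x
}

#' Units flag of an expression matrix
#' @param x an expression matrix built by [expression_matrix()].
#' @return the units string, or `NULL` if unset.
#' @export
expr_units <- function(x) attr(x, "units")

.set_units <- function(x, units) { attr(x, "units") <- units; x }

.check_units <- function(x, allowed) {
  u <- expr_units(x)
  .assert(!is.null(u) && u %in% allowed,
          sprintf("expected units in {%s}, got '%s'",
                  paste(allowed, collapse = ", "),
                  if (is.null(u)) "unset" else u))
  invisible(u)
}

#' Quantile-normalize expression columns
#'
#' Forces every sample (column) to share the identical value distribution:
#' the reference distribution is the vector of row means of the
#' column-sorted matrix, and tied values within a column receive the mean
#' of the reference values they span (Bolstad-style tie handling, as in
#' limma).
#'
#' @param m expression matrix in TPM or log2 units with at least 2 samples.
#' @return expression matrix of the same shape and units.
#' @export
quantile_normalize <- function(m) {
  .check_units(m, c("TPM", "log2"))
  .assert(ncol(m) >= 2L, "quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  .set_units(out, expr_units(m))
}

#' Log2-transform TPM values
#'
#' @param m expression matrix in TPM units, all values >= 0.
#' @param offset non-negative pseudocount added before the log; defaults to
#'   1 (i.e. log2(TPM + 1)), which maps zero TPM to zero.
#' @return expression matrix in log2 units.
#' @export
log2_transform <- function(m, offset = 1) {
  .check_units(m, "TPM")
  .assert(is.numeric(offset) && length(offset) == 1L && offset >= 0,
          "offset must be a non-negative scalar")
  .assert(all(m >= 0, na.rm = TRUE), "TPM values must be non-negative")
  .set_units(log2(m + offset), "log2")
}

#' Inverse of the default log2 transform (2^x - 1, clipped at 0)
#' @param m expression matrix in log2 units.
#' @return expression matrix in TPM units.
#' @export
unlog2_transform <- function(m) {
  .check_units(m, "log2")
  .set_units(pmax(2^m - 1, 0), "TPM")
}

#' Standardize genes to SD-from-the-median
#'
#' Per gene: subtract the median across samples and divide by the sample
#' standard deviation (n - 1 denominator). Genes with zero SD carry no
#' information on this scale and are dropped; the number dropped is
#' reported via a message and stored in the `"dropped"` attribute.
#'
#' @param m expression matrix in log2 units with >= 2 samples.
#' @return expression matrix in sd units (per-gene median exactly 0, SD 1),
#'   possibly with fewer genes.
#' @export
standardize_sd_from_median <- function(m) {
  .check_units(m, "log2")
  .assert(ncol(m) >= 2L, "standardization needs >= 2 samples")
  med <- .row_medians(m)
  s <- .row_sds(m)
  keep <- is.finite(s) & s > 0
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with zero variance dropped")
  }
  out <- (m[keep, , drop = FALSE] - med[keep]) / s[keep]
  out <- .set_units(out, "sd")
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}
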