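#' Signature t-score of one expression profile
#'
#' The per-sample signature statistic: a two-sample t comparing the
#' profile's standardized values at the signature genes against all other
#' genes in the profile (or, for bidirectional signatures, the up genes
#' against the down genes). Positive when the signature genes sit higher
#' as a group. Welch (unequal-variance) by default; a pooled-variance
#' variant is available.
#'
#' @param profile named numeric vector: one sample's expression in SD
#'   units (see [standardize_sd_from_median()]).
#' @param signature character vector of gene ids (>= 2 must be present).
#' @param down_signature optional down gene set, disjoint from
#'   `signature`; when given, the comparison group is these genes instead
#'   of the whole background.
#' @param pooled use the pooled-variance t instead of Welch.
#' @return scalar t-score.
#' @export
t_score <- function(profile, signature, down_signature = NULL,
                    pooled = FALSE) {
  .assert(!is.null(names(profile)), "profile must be a named vector")
  up <- intersect(signature, names(profile))
  if (length(up) < 2L) stop("fewer than 2 usable signature genes")
  if (!is.null(down_signature)) {
    .assert(length(intersect(signature, down_signature)) == 0L,
            "up and down signatures must be disjoint")
    dn <- intersect(down_signature, names(profile))
    if (length(dn) < 2L) stop("fewer than 2 usable down-signature genes")
  } else {
    dn <- setdiff(names(profile), up)
    if (length(dn) < 2L) stop("fewer than 2 background genes")
  }
  .welch_t(profile[up], profile[dn], pooled = pooled)
}

#' Score every sample of a cohort for a signature
#'
#' Standardizes genes to SD-from-median across the cohort (unless the
#' matrix is already in SD units) and computes the [t_score()] of each
#' sample. Signature genes absent from the matrix are dropped with a
#' message.
#'
#' @param m expression matrix in log2 or SD units.
#' @param signature,down_signature,pooled as in [t_score()].
#' @return named numeric vector of per-sample scores (attribute
#'   `n_signature_used` records how many signature genes were present).
#' @export
score_cohort <- function(m, signature, down_signature = NULL,
                         pooled = FALSE) {
  u <- .check_units(m, c("log2", "sd"))
  z <- if (u == "log2") suppressMessages(standardize_sd_from_median(m)) else m
  up <- intersect(signature, rownames(z))
  miss <- length(setdiff(signature, rownames(z)))
  if (miss > 0)
    message(miss, " signature gene(s) absent from the matrix; dropped")
  if (length(up) < 2L) stop("fewer than 2 usable signature genes")
  scores <- vapply(seq_len(ncol(z)), function(j)
    t_score(z[, j], up, down_signature, pooled = pooled), numeric(1))
  names(scores) <- colnames(z)
  attr(scores, "n_signature_used") <- length(up)
  scores
}
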