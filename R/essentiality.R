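#' Count essential cell lines per gene
#'
#' A gene is called essential in a cell line when its gene-effect
#' (dependency) score is strictly below the threshold; strongly negative
#' Chronos-style scores mean the line depends on the gene for
#' proliferation. Missing entries are excluded from both the count and the
#' assayed-line denominator.
#'
#' @param scores genes x cell-lines numeric matrix of gene-effect scores
#'   (NA allowed).
#' @param threshold essentiality cutoff; default -0.75.
#' @return data.frame: `gene`, `n_essential` (lines strictly below the
#'   threshold), `n_assayed` (lines with a non-missing score).
#' @export
count_essential_lines <- function(scores, threshold = -0.75) {
  .assert(is.matrix(scores) && is.numeric(scores), "scores must be numeric matrix")
  .assert(is.finite(threshold), "threshold must be finite")
  data.frame(gene = rownames(scores),
             n_essential = rowSums(scores < threshold, na.rm = TRUE),
             n_assayed = rowSums(!is.na(scores)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition metastasis-high genes by essentiality
#'
#' Applies the dependency-screen partition to a set of metastasis-high
#' genes: `essential` when the fraction of assayed lines called essential
#' strictly exceeds `min_fraction`; `nonessential` when no line is called
#' essential; `intermediate` otherwise. The fraction denominator is the
#' number of lines actually assayed for that gene. Genes with zero assayed
#' lines are excluded (reported via message).
#'
#' @param higher_set character vector of metastasis-high gene ids.
#' @param counts result of [count_essential_lines()], covering
#'   `higher_set`.
#' @param min_fraction strict lower bound on the essential-line fraction
#'   for the `essential` class; default 0.10.
#' @param threshold the score threshold used to build `counts` (recorded
#'   in the output for provenance).
#' @return data.frame of class `essentiality_partition`: `gene`,
#'   `n_essential`, `n_assayed`, `fraction`, `class`; attributes
#'   `threshold` and `min_fraction`.
#' @export
classify_genes <- function(higher_set, counts, min_fraction = 0.10,
                           threshold = -0.75) {
  .assert(all(higher_set %in% counts$gene),
          "counts do not cover every gene in higher_set")
  x <- counts[match(unique(higher_set), counts$gene), ]
  drop <- x$n_assayed == 0
  if (any(drop)) {
    message(sum(drop), " gene(s) with zero assayed lines excluded")
    x <- x[!drop, ]
  }
  x$fraction <- x$n_essential / x$n_assayed
  x$class <- ifelse(x$fraction > min_fraction, "essential",
                    ifelse(x$n_essential == 0, "nonessential",
                           "intermediate"))
  rownames(x) <- NULL
  attr(x, "threshold") <- threshold
  attr(x, "min_fraction") <- min_fraction
  class(x) <- c("essentiality_partition", class(x))
  x
}

#' Genes of one essentiality class
#' @param partition result of [classify_genes()].
#' @param class one of `"essential"`, `"intermediate"`, `"nonessential"`.
#' @return character vector of gene ids.
#' @export
partition_genes <- function(partition,
                            class = c("essential", "intermediate",
                                      "nonessential")) {
  class <- match.arg(class)
  partition$gene[partition$class == class]
}
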