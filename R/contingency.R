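#' Overlap statistics for two gene sets in a universe
#'
#' Builds the 2x2 table (in A & in B, in A only, in B only, in neither)
#' over the stated gene universe and reports: the expected chance overlap
#' |A||B|/N (raw and rounded half-away-from-zero), the Pearson chi-square
#' statistic without continuity correction (df 1, two-sided p), the
#' one-sided Fisher exact p in the enrichment direction (hypergeometric
#' upper tail), and the odds ratio ad/bc (infinite when b or c is 0).
#'
#' @param setA,setB character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector: the gene universe N.
#' @return list of class `contingency_result` with elements `a`, `b`, `c`,
#'   `d`, `n_universe`, `size_a`, `size_b`, `expected`,
#'   `expected_rounded`, `chisq`, `chisq_p`, `fisher_p`, `odds_ratio`.
#' @export
overlap_stats <- function(setA, setB, universe) {
  .assert(length(universe) > 0, "empty universe")
  .assert(!anyDuplicated(universe), "universe has duplicate ids")
  setA <- unique(setA); setB <- unique(setB)
  .assert(all(setA %in% universe), "setA is not a subset of the universe")
  .assert(all(setB %in% universe), "setB is not a subset of the universe")
  N <- length(universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- N - a - b - c
  overlap_stats_counts(a, b, c, d)
}

#' Overlap statistics from 2x2 counts
#'
#' Same statistics as [overlap_stats()] but starting from the table cells
#' directly: `a` = in both sets, `b` = first set only, `c` = second set
#' only, `d` = in neither. Useful when only the published margins are
#' available.
#'
#' @param a,b,c,d non-negative table cells; `a + b + c + d` = universe size.
#' @return a `contingency_result` (see [overlap_stats()]).
#' @export
overlap_stats_counts <- function(a, b, c, d) {
  .assert(all(c(a, b, c, d) >= 0), "negative table cell")
  N <- a + b + c + d
  .assert(N > 0, "empty universe")
  sizeA <- a + b; sizeB <- a + c
  expected <- sizeA * sizeB / N
  # Pearson chi-square, df 1, no Yates correction
  exp_cells <- c(expected, sizeA - expected,
                 sizeB - expected, N - sizeA - sizeB + expected)
  obs <- c(a, b, c, d)
  chisq <- if (any(exp_cells == 0)) NA_real_ else
    sum((obs - exp_cells)^2 / exp_cells)
  chisq_p <- if (is.na(chisq)) NA_real_ else
    pchisq(chisq, df = 1, lower.tail = FALSE)
  # one-sided enrichment p: P(overlap >= a) under hypergeometric sampling
  fisher_p <- phyper(a - 1, sizeA, N - sizeA, sizeB, lower.tail = FALSE)
  or <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  structure(list(a = a, b = b, c = c, d = d, n_universe = N,
                 size_a = sizeA, size_b = sizeB,
                 expected = expected,
                 expected_rounded = .round_half_away(expected),
                 chisq = chisq, chisq_p = chisq_p,
                 fisher_p = fisher_p, odds_ratio = or),
            class = "contingency_result")
}

# round() in R rounds half to even; the reporting convention here is half
# away from zero.
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "2x2 overlap: a=%d (expected %.2f ~ %d), |A|=%d, |B|=%d, N=%d\n",
    x$a, x$expected, x$expected_rounded, x$size_a, x$size_b, x$n_universe))
  cat(sprintf("  chi-square (df 1) = %.3f, p = %.3g; one-sided Fisher p = %.3g; OR = %.3g\n",
              x$chisq, x$chisq_p, x$fisher_p, x$odds_ratio))
  invisible(x)
}

#' One-sided Fisher enrichment of a query set against a collection
#'
#' Hypergeometric upper-tail p for each named set in the collection:
#' P(overlap >= observed) when drawing |query| genes from the universe.
#' Sets are restricted to the universe before testing.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param collection named list of character vectors.
#' @param universe gene universe.
#' @return data.frame: `set`, `overlap`, `set_size` (within universe),
#'   `query_size`, `universe_size`, `expected`, `fisher_p`.
#' @export
fisher_enrichment <- function(query, collection, universe) {
  .assert(length(universe) > 0, "empty universe")
  query <- unique(query)
  .assert(all(query %in% universe), "query is not a subset of the universe")
  .assert(is.list(collection) && !is.null(names(collection)),
          "collection must be a named list of gene sets")
  N <- length(universe); q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(s, query))
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = q, universe_size = N,
               expected = length(s) * q / N,
               fisher_p = phyper(k - 1, length(s), N - length(s), q,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact membership regions of 2-4 gene sets
#'
#' Partitions the union of the sets into the 2^k - 1 disjoint membership
#' regions of a Venn diagram.
#'
#' @param sets named list of 2-4 character vectors.
#' @return named list mapping a region key (set names joined by `&`, with
#'   `only` semantics implied by exclusion) to the genes exactly in that
#'   combination of sets. Region counts sum to the size of the union.
#' @export
multiway_intersection <- function(sets) {
  .assert(is.list(sets) && length(sets) >= 2L && length(sets) <= 4L &&
            !is.null(names(sets)), "sets must be a named list of 2-4 sets")
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(b) paste(names(sets)[b], collapse = "&"))
  split(all_genes, key)
}
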