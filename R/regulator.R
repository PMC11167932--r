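# TF promoter-window target assignment and knockdown target sets.

# Validate a 0-based half-open interval table; returns list(ok, n_rejected).
.validate_intervals <- function(df, what) {
  bad <- !is.finite(df$start) | !is.finite(df$end) | df$start < 0 |
    df$end <= df$start | is.na(df$chrom)
  if (any(bad))
    message(sum(bad), " malformed ", what, " record(s) rejected")
  df[!bad, , drop = FALSE]
}

#' Assign TF targets by promoter-window binding
#'
#' A gene is a target of a TF when any of the TF's binding sites
#' intersects the gene's upstream window: for a + strand gene the window
#' is `[start - window, start)`, for a - strand gene `[end, end + window)`
#' (0-based half-open coordinates; windows clipped at 0). A strand-naive
#' mode (always `[start - window, start)`) is available for sensitivity
#' checks.
#'
#' @param sites data.frame of binding sites: `tf`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param loci data.frame of gene loci: `gene`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`).
#' @param window upstream window length in bp; default 2000.
#' @param strand_aware honor gene strand when placing the window;
#'   default TRUE.
#' @return named list: TF -> character vector of target gene ids.
#' @export
map_tf_targets <- function(sites, loci, window = 2000,
                           strand_aware = TRUE) {
  .assert(all(c("tf", "chrom", "start", "end") %in% names(sites)),
          "sites needs columns tf, chrom, start, end")
  .assert(all(c("gene", "chrom", "start", "end", "strand") %in% names(loci)),
          "loci needs columns gene, chrom, start, end, strand")
  sites <- .validate_intervals(sites, "binding-site")
  loci <- .validate_intervals(loci, "locus")
  .assert(all(loci$strand %in% c("+", "-")), "strand must be + or -")
  minus <- strand_aware & loci$strand == "-"
  win_start <- ifelse(minus, loci$end, pmax(loci$start - window, 0))
  win_end <- ifelse(minus, loci$end + window, loci$start)
  keep <- win_end > win_start
  # GRanges is 1-based closed; a half-open [s, e) becomes [s + 1, e]
  genes_gr <- GenomicRanges::GRanges(
    loci$chrom[keep],
    IRanges::IRanges(win_start[keep] + 1L, win_end[keep]))
  sites_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end))
  hits <- GenomicRanges::findOverlaps(sites_gr, genes_gr)
  tf_hit <- sites$tf[S4Vectors::queryHits(hits)]
  gene_hit <- loci$gene[keep][S4Vectors::subjectHits(hits)]
  out <- lapply(split(gene_hit, tf_hit), function(g) sort(unique(g)))
  # every TF present in the input appears, possibly with no targets
  all_tfs <- sort(unique(sites$tf))
  res <- setNames(vector("list", length(all_tfs)), all_tfs)
  for (tf in all_tfs) res[[tf]] <- out[[tf]] %||% character(0)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Knockdown target sets from a standardized knockdown matrix
#'
#' For each knockdown profile (column), the genes strictly below the
#' under-expression threshold are taken as that knockdown's downstream
#' targets.
#'
#' @param km genes x knockdown-profiles numeric matrix in SD-from-median
#'   units.
#' @param threshold strict cutoff; default -0.5.
#' @return named list: knockdown -> character vector of target gene ids.
#' @export
knockdown_targets <- function(km, threshold = -0.5) {
  .assert(is.matrix(km) && is.numeric(km), "km must be a numeric matrix")
  lapply(setNames(seq_len(ncol(km)), colnames(km)), function(j)
    rownames(km)[!is.na(km[, j]) & km[, j] < threshold])
}
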