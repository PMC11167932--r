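#' Build centered subtype centroids from a labeled reference
#'
#' For each gene: the per-subtype mean expression, centered on the mean
#' centroid (the unweighted mean of the subtype means), so each gene's
#' row of the model sums to zero across subtypes.
#'
#' @param reference expression matrix (log2 units) of subtype-labeled
#'   samples.
#' @param labels character vector of subtype labels, one per reference
#'   column (>= 2 subtypes, each with >= 2 samples).
#' @return genes x subtypes matrix of class `centroid_model`.
#' @export
build_centroids <- function(reference, labels) {
  .check_units(reference, "log2")
  .assert(length(labels) == ncol(reference), "one label per sample")
  tab <- table(labels)
  .assert(length(tab) >= 2L, "need >= 2 subtypes")
  .assert(all(tab >= 2L), "every subtype needs >= 2 reference samples")
  subtypes <- sort(names(tab))
  means <- vapply(subtypes, function(st)
    rowMeans(reference[, labels == st, drop = FALSE]),
    numeric(nrow(reference)))
  model <- means - rowMeans(means)
  structure(model, class = c("centroid_model", class(model)))
}

#' Assign molecular subtypes by nearest centroid
#'
#' Within each block of the partition (e.g. study x metastasis/primary
#' role), genes are standardized to SD-from-median across the block's
#' samples; each sample is then assigned the subtype whose centered
#' centroid has the highest Pearson correlation with the sample's
#' standardized profile over genes common to model and data. Ties are
#' broken by the model's fixed subtype order with a warning.
#'
#' @param profiles expression matrix (log2 units).
#' @param model a [build_centroids()] model.
#' @param blocks optional character vector (one per sample) partitioning
#'   samples into normalization blocks; default: one block.
#' @return data.frame: `sample`, `block`, `subtype`, plus one correlation
#'   column per subtype (`cor_<subtype>`).
#' @export
assign_subtype <- function(profiles, model, blocks = NULL) {
  .check_units(profiles, "log2")
  if (is.null(blocks)) blocks <- rep("all", ncol(profiles))
  .assert(length(blocks) == ncol(profiles), "one block label per sample")
  subtypes <- colnames(model)
  out <- vector("list", length(unique(blocks)))
  names(out) <- unique(blocks)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    z <- suppressMessages(standardize_sd_from_median(
      .set_units(profiles[, cols, drop = FALSE], "log2")))
    common <- intersect(rownames(z), rownames(model))
    .assert(length(common) >= 3L, "fewer than 3 genes common to model and profiles")
    r <- cor(z[common, , drop = FALSE],
             unclass(model)[common, , drop = FALSE])
    best <- apply(r, 1L, function(v) which(v == max(v))[1L])
    nties <- sum(apply(r, 1L, function(v) sum(v == max(v))) > 1L)
    if (nties > 0)
      warning(nties, " sample(s) with tied centroid correlations; ",
              "first subtype in model order assigned")
    df <- data.frame(sample = colnames(profiles)[cols], block = b,
                     subtype = subtypes[best], stringsAsFactors = FALSE)
    colnames(r) <- paste0("cor_", subtypes)
    out[[b]] <- cbind(df, as.data.frame(r, row.names = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(colnames(profiles), res$sample), , drop = FALSE]
}
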