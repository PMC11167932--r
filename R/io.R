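# Plain-text readers and writers: expression TSV (genes as rows), GMT
# gene sets, 6-column BED (0-based half-open), survival CSV.

#' Write / read an expression matrix as TSV
#'
#' Genes as rows; the first column (`gene`) carries the gene id. Units
#' are not stored in the file: the reader takes them as an argument.
#' Duplicate gene ids on ingest are collapsed to the row with the
#' highest mean value (with a message).
#'
#' @param m expression matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param units units flag for the matrix read back.
#' @export
read_expression_tsv <- function(path, units = c("TPM", "log2", "sd")) {
  units <- match.arg(units)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(names(df)[1L] == "gene", "first column must be 'gene'")
  x <- as.matrix(df[, -1L, drop = FALSE])
  ids <- df$gene
  if (anyDuplicated(ids)) {
    message(sum(duplicated(ids)),
            " duplicate gene id row(s) collapsed to highest-mean row")
    means <- rowMeans(x, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(ids), ids),
                          function(i) i[which.max(means[i])]))
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(x) <- ids
  expression_matrix(x, units)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional per-set description (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  .assert(is.list(sets) && !is.null(names(sets)), "sets must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(bad, collapse = ", "))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1L))
}

#' Write / read 6-column BED (0-based, half-open, strand in column 6)
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (score may be ".").
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  .assert(all(need %in% names(df)), "BED needs chrom,start,end,name,score,strand")
  write.table(df[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 6L, "expected 6 BED columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  bad <- !is.finite(df$start) | !is.finite(df$end) | df$end <= df$start
  if (any(bad))
    message(sum(bad), " BED record(s) with end <= start rejected")
  df[!bad, 1:6]
}

#' Write / read a survival table as CSV
#' @param surv a [survival_table()].
#' @param path file path.
#' @export
write_survival_csv <- function(surv, path) {
  write.table(surv, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  .assert(all(c("sample", "time", "event") %in% names(df)),
          "survival CSV needs sample, time, event columns")
  extra <- df[, setdiff(names(df), c("sample", "time", "event")),
              drop = FALSE]
  survival_table(df$sample, df$time, df$event,
                 if (ncol(extra)) extra else NULL)
}
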