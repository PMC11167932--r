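# Internal numeric helpers shared across modules.

# Row-wise mean/sd with NA removal, keeping names.
.row_means <- function(x) rowMeans(x, na.rm = TRUE)

.row_sds <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums(x * x, na.rm = TRUE) - n * m^2
  # guard tiny negative values from floating cancellation
  out <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
  out[n < 2] <- NA_real_
  out
}

.row_medians <- function(x) apply(x, 1L, median, na.rm = TRUE)

# Vectorized Welch two-sample t over rows: group1 vs group2 column sets.
# Returns data.frame(t, df, p); two-sided p.
.row_welch <- function(x, cols1, cols2) {
  x1 <- x[, cols1, drop = FALSE]
  x2 <- x[, cols2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- .row_sds(x1)^2; v2 <- .row_sds(x2)^2
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  data.frame(t = tstat, df = df, p = p, mean1 = m1, mean2 = m2)
}

# Scalar Welch t for two numeric vectors (used by t_score); pooled variant
# available for sensitivity checks.
.welch_t <- function(a, b, pooled = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group for a t-statistic")
  if (pooled) {
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    (mean(a) - mean(b)) / sqrt(var(a) / n1 + var(b) / n2)
  }
}

# Deterministic named substream seed derived from a master seed, so each
# synthetic output has its own reproducible RNG stream. Kept below 2^31.
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
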