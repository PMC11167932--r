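# Shared fixtures: small configurations and independent oracles.

# A small, fast simulation for unit tests (the full default config is
# exercised in the acceptance suite).
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 800, n_patients = 24, n_survival = 200,
               n_tissue_samples = 25, n_cells_per_type = 50,
               n_subtype_genes = 120, n_tfs = 3, targets_per_tf = 30,
               n_knockdowns = 4, targets_per_knockdown = 25, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Independent hypergeometric upper-tail oracle built from choose() only:
# P(overlap >= a) for |A| = sizeA, |B| = sizeB drawn from N genes.
enum_fisher_p <- function(a, sizeA, sizeB, N) {
  ks <- max(0, sizeA + sizeB - N):min(sizeA, sizeB)
  probs <- choose(sizeA, ks) * choose(N - sizeA, sizeB - ks) / choose(N, sizeB)
  sum(probs[ks >= a])
}

# Brute-force Welch t for two vectors (textbook formula, scalar code).
brute_welch_t <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(sum((a - mean(a))^2) / (length(a) - 1) / length(a) +
         sum((b - mean(b))^2) / (length(b) - 1) / length(b))
}

# A deterministic tiny expression matrix.
tiny_expr <- function(values, units = "log2", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
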