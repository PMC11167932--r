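# Survival association of signature scores, plus the random-signature null.

#' Construct a survival table
#'
#' @param sample sample ids (matching the scored cohort).
#' @param time positive follow-up times (e.g. months).
#' @param event 0/1 event indicator.
#' @param covariates optional data.frame of extra per-sample covariates.
#' @return data.frame with columns `sample`, `time`, `event` (+ covariates).
#' @export
survival_table <- function(sample, time, event, covariates = NULL) {
  .assert(all(time > 0), "times must be positive")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  out <- data.frame(sample = as.character(sample), time = time,
                    event = event, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  out
}

.align_scores <- function(scores, surv) {
  .assert(all(surv$sample %in% names(scores)),
          "survival table references unscored samples")
  as.numeric(scores[surv$sample])
}

#' Univariate Cox regression on a continuous signature score
#'
#' Proportional-hazards fit with the score as the sole covariate (Efron
#' tie handling); reports the coefficient (log hazard ratio per unit
#' score), the hazard ratio, and the Wald p.
#'
#' @param scores named per-sample scores (see [score_cohort()]).
#' @param surv a [survival_table()].
#' @return list: `coef`, `hr`, `se`, `p`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(scores, surv) {
  s <- .align_scores(scores, surv)
  .assert(sum(surv$event) >= 10, "need >= 10 events for a stable Cox fit")
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ s,
                         ties = "efron")
  sm <- summary(fit)
  list(coef = unname(coef(fit)[1L]),
       hr = unname(sm$conf.int[1L, "exp(coef)"]),
       se = unname(sqrt(fit$var[1L, 1L])),
       p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
       n = fit$n, n_events = fit$nevent,
       converged = fit$info["convergence"] %in% c(0, NA) ||
         is.null(fit$info))
}

#' Log-rank test on low/intermediate/high score groups
#'
#' Splits samples at the stated score quantiles (tertiles by default) and
#' runs the k-sample log-rank test.
#'
#' @param scores named per-sample scores.
#' @param surv a [survival_table()].
#' @param cutpoints two quantiles in (0, 1) delimiting low/intermediate/
#'   high; default tertiles.
#' @return list: `groups` (factor low/intermediate/high per sample, named),
#'   `chisq`, `df`, `p`.
#' @export
logrank_groups <- function(scores, surv, cutpoints = c(1, 2) / 3) {
  s <- .align_scores(scores, surv)
  .assert(length(cutpoints) == 2L && all(cutpoints > 0 & cutpoints < 1) &&
            cutpoints[1] < cutpoints[2], "cutpoints must be two quantiles in (0,1)")
  q <- quantile(s, cutpoints, type = 7)
  g <- cut(s, c(-Inf, q, Inf), labels = c("low", "intermediate", "high"))
  if (any(table(g) == 0))
    stop("a score group is empty; choose different cutpoints")
  sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- length(sd_$n) - 1L
  names(g) <- surv$sample
  list(groups = g, chisq = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox with the signature score and covariates
#'
#' Joint proportional-hazards fit of the signature score with additional
#' covariates (e.g. a proliferation-marker expression value or other
#' signature scores), asking whether the signature retains significance.
#'
#' @param scores named per-sample scores.
#' @param covariates data.frame of per-sample covariates (rownames or a
#'   `sample` column matching the survival table).
#' @param surv a [survival_table()].
#' @return data.frame: `term`, `coef`, `hr`, `se`, `p` (first row is the
#'   signature score).
#' @export
cox_multivariate <- function(scores, covariates, surv) {
  s <- .align_scores(scores, surv)
  cov <- covariates
  if ("sample" %in% names(cov)) {
    cov <- cov[match(surv$sample, cov$sample), setdiff(names(cov), "sample"),
               drop = FALSE]
  } else if (!is.null(rownames(cov))) {
    cov <- cov[surv$sample, , drop = FALSE]
  }
  dat <- data.frame(score = s, cov)
  fit <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ ., data = dat, ties = "efron")
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), coef = sm[, "coef"],
             hr = sm[, "exp(coef)"], se = sm[, "se(coef)"],
             p = sm[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Fast batch t-scores: all samples at once for one signature on an
# SD-units matrix (Welch, background = all non-signature genes).
.batch_tscore <- function(z, sig_rows) {
  n1 <- length(sig_rows); n2 <- nrow(z) - n1
  zs <- z[sig_rows, , drop = FALSE]
  m1 <- colMeans(zs); ss1 <- colSums(zs^2)
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  tot <- colSums(z); tot2 <- colSums(z^2)
  m2 <- (tot - n1 * m1) / n2
  v2 <- (tot2 - ss1 - n2 * m2^2) / (n2 - 1)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' Random-signature null for coordination and prognosis
#'
#' Draws `n` uniformly random gene sets of the same size as the signature
#' from the matrix's gene universe, scores the cohort with each, and
#' records two null distributions: the SD of the scores across samples
#' (coordinate expression) and the univariate Cox p (prognostic value).
#' Reports the actual signature's rank on both axes (rank 1 = most
#' extreme: highest score-SD, smallest Cox p).
#'
#' @param m expression matrix (log2 or SD units).
#' @param signature the actual signature.
#' @param surv a [survival_table()].
#' @param n number of random signatures; default 100.
#' @param seed RNG seed for the draws.
#' @return list: `actual_sd`, `actual_cox_p`, `random_sd` (length n),
#'   `random_cox_p` (length n), `rank_sd`, `rank_cox_p`,
#'   `n_random_smaller_cox_p`, `n`, `seed`.
#' @export
random_signature_null <- function(m, signature, surv, n = 100, seed = 1) {
  .assert(n >= 1, "n must be >= 1")
  u <- .check_units(m, c("log2", "sd"))
  z <- if (u == "log2") suppressMessages(standardize_sd_from_median(m)) else m
  sig <- intersect(signature, rownames(z))
  .assert(length(sig) >= 2, "fewer than 2 usable signature genes")
  .assert(length(sig) <= nrow(z), "signature larger than gene universe")
  actual <- .batch_tscore(z, match(sig, rownames(z)))
  names(actual) <- colnames(z)
  actual_sd <- sd(actual)
  actual_p <- cox_univariate(actual, surv)$p
  draws <- withr::with_seed(seed, replicate(
    n, sample.int(nrow(z), length(sig)), simplify = FALSE))
  rnd <- lapply(draws, function(rows) {
    sc <- .batch_tscore(z, rows)
    names(sc) <- colnames(z)
    c(sd = sd(sc), p = cox_univariate(sc, surv)$p)
  })
  rnd_sd <- vapply(rnd, `[[`, numeric(1), "sd")
  rnd_p <- vapply(rnd, `[[`, numeric(1), "p")
  list(actual_sd = actual_sd, actual_cox_p = actual_p,
       random_sd = rnd_sd, random_cox_p = rnd_p,
       rank_sd = 1L + sum(rnd_sd > actual_sd),
       rank_cox_p = 1L + sum(rnd_p < actual_p),
       n_random_smaller_cox_p = sum(rnd_p < actual_p),
       n = n, seed = seed)
}

#' Overlap of per-gene prognostic genes with a signature
#'
#' Fits a univariate Cox model per gene on standardized expression; the
#' worse-prognosis set is {p < alpha, coefficient > 0} (and the
#' better-prognosis set its negative-coefficient mirror). Each is tested
#' for one-sided Fisher overlap with the signature over the matrix's gene
#' universe.
#'
#' @param m expression matrix (log2 or SD units).
#' @param surv a [survival_table()].
#' @param signature gene set to test.
#' @param alpha per-gene threshold; default 0.01.
#' @return list: `per_gene` (gene, coef, p), `worse`, `better` (gene
#'   sets), `overlap_worse`, `overlap_better` (`contingency_result`s).
#' @export
prognosis_gene_overlap <- function(m, surv, signature, alpha = 0.01) {
  u <- .check_units(m, c("log2", "sd"))
  z <- if (u == "log2") suppressMessages(standardize_sd_from_median(m)) else m
  z <- z[, surv$sample, drop = FALSE]
  y <- survival::Surv(surv$time, surv$event)
  res <- t(apply(z, 1L, function(x) {
    fit <- survival::coxph(y ~ x, ties = "efron")
    c(coef(fit)[1L], summary(fit)$coefficients[1L, "Pr(>|z|)"])
  }))
  per_gene <- data.frame(gene = rownames(z), coef = res[, 1L], p = res[, 2L],
                         row.names = NULL, stringsAsFactors = FALSE)
  worse <- per_gene$gene[per_gene$p < alpha & per_gene$coef > 0]
  better <- per_gene$gene[per_gene$p < alpha & per_gene$coef < 0]
  sig <- intersect(signature, rownames(z))
  list(per_gene = per_gene, worse = worse, better = better,
       overlap_worse = overlap_stats(sig, worse, rownames(z)),
       overlap_better = overlap_stats(sig, better, rownames(z)))
}
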