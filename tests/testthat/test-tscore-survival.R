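test_that("t-score matches the brute-force Welch formula", {
  prof <- c(a = 2.0, b = 1.0, c = 0.0, d = -1.0, e = 1.0)
  got <- t_score(prof, c("a", "b"))
  expect_equal(got, brute_welch_t(c(2, 1), c(0, -1, 1)), tolerance = 1e-12)
  # up-vs-down variant
  got2 <- t_score(prof, c("a", "b"), down_signature = c("c", "d"))
  expect_equal(got2, brute_welch_t(c(2, 1), c(0, -1)), tolerance = 1e-12)
  # direction: planted-high signature scores positive
  expect_gt(got, 0)
  expect_error(t_score(prof, "a"), "fewer than 2")
  expect_error(t_score(prof, c("a", "b"), down_signature = c("b", "c")),
               "disjoint")
  # invariance to background permutation
  perm <- prof[c(1, 2, 5, 3, 4)]
  expect_equal(t_score(perm, c("a", "b")), got, tolerance = 1e-12)
})

test_that("random signatures score near zero on exchangeable profiles", {
  set.seed(31)
  prof <- rnorm(400)
  names(prof) <- sprintf("g%03d", 1:400)
  draws <- replicate(200, t_score(prof, sample(names(prof), 20)))
  expect_lt(abs(mean(draws)), 0.15)
})

test_that("cohort scoring standardizes, ranks planted samples, and is equivariant", {
  cfg <- small_config(seed = 14)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  intrinsic <- names(truth$gene_role)[truth$gene_role == "intrinsic_met"]
  sc <- score_cohort(sv$expr, intrinsic)
  # scores track the planted activity tightly
  expect_gt(cor(sc, sv$planted_score[names(sc)]), 0.8)
  # permuting sample order permutes scores identically
  perm <- sample(ncol(sv$expr))
  x2 <- sv$expr[, perm]
  x2 <- expression_matrix(x2, "log2")
  sc2 <- score_cohort(x2, intrinsic)
  expect_equal(as.numeric(sc2), as.numeric(sc[perm]), tolerance = 1e-10)
  # missing signature genes are dropped with a message
  expect_message(score_cohort(sv$expr, c(intrinsic, "missing_gene")),
                 "absent")
  # batch scorer equals the per-sample scorer
  z <- standardize_sd_from_median(sv$expr)
  batch <- metsig:::.batch_tscore(z, match(intersect(intrinsic, rownames(z)),
                                           rownames(z)))
  expect_equal(as.numeric(batch), as.numeric(sc), tolerance = 1e-10)
})

test_that("univariate Cox agrees with coxph and respects PH invariances", {
  cfg <- small_config(seed = 15, n_survival = 300)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  sc <- sv$planted_score
  got <- cox_univariate(sc, sv$surv)
  ref <- survival::coxph(survival::Surv(sv$surv$time, sv$surv$event) ~ sc,
                         ties = "efron")
  expect_equal(got$coef, unname(coef(ref)), tolerance = 1e-12)
  # doubling all times leaves the coefficient unchanged
  surv2 <- sv$surv; surv2$time <- surv2$time * 2
  expect_equal(cox_univariate(sc, surv2)$coef, got$coef, tolerance = 1e-8)
  expect_error(cox_univariate(sc, within(sv$surv, event <- 0 * event)),
               "events")
})

test_that("log-rank grouping splits at tertiles and detects planted hazard", {
  cfg <- small_config(seed = 16, n_survival = 400)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  lr <- logrank_groups(sv$planted_score, sv$surv)
  expect_equal(sort(unique(as.character(lr$groups))),
               c("high", "intermediate", "low"))
  tab <- table(lr$groups)
  expect_true(max(tab) - min(tab) <= 2)
  expect_lt(lr$p, 0.01)
  ref <- survival::survdiff(
    survival::Surv(sv$surv$time, sv$surv$event) ~ lr$groups)
  expect_equal(lr$chisq, ref$chisq, tolerance = 1e-12)
})

test_that("multivariate Cox reduces to univariate without covariates and handles collinearity", {
  cfg <- small_config(seed = 17, n_survival = 300)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  sc <- sv$planted_score
  uni <- cox_univariate(sc, sv$surv)
  # an independent noise covariate barely moves the signature coefficient
  set.seed(2)
  noise <- data.frame(sample = sv$surv$sample,
                      z = rnorm(nrow(sv$surv)))
  mv <- cox_multivariate(sc, noise, sv$surv)
  expect_equal(mv$coef[mv$term == "score"], uni$coef, tolerance = 0.05)
  # a covariate duplicating the score (plus tiny jitter) confounds it
  dup <- data.frame(sample = sv$surv$sample,
                    z = as.numeric(sc[sv$surv$sample]) + rnorm(nrow(sv$surv), 0, 1e-3))
  mv2 <- suppressWarnings(cox_multivariate(sc, dup, sv$surv))
  expect_gt(mv2$p[mv2$term == "score"], uni$p)
})

test_that("the random-signature null ranks a coordinated signature first", {
  cfg <- small_config(seed = 18, n_survival = 300)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  intrinsic <- names(truth$gene_role)[truth$gene_role == "intrinsic_met"]
  null <- random_signature_null(sv$expr, intrinsic, sv$surv, n = 30,
                                seed = 99)
  expect_equal(null$rank_sd, 1L)
  expect_lte(null$n_random_smaller_cox_p, 1L)
  # fixed seed reproduces the null exactly
  null2 <- random_signature_null(sv$expr, intrinsic, sv$surv, n = 30,
                                 seed = 99)
  expect_identical(null$random_sd, null2$random_sd)
  expect_identical(null$random_cox_p, null2$random_cox_p)
})

test_that("per-gene prognosis overlaps find the planted signature-hazard coupling", {
  cfg <- small_config(seed = 19, n_genes = 300, n_survival = 250)
  truth <- make_truth(cfg)
  sv <- generate_survival_cohort(truth, cfg)
  intrinsic <- names(truth$gene_role)[truth$gene_role == "intrinsic_met"]
  res <- prognosis_gene_overlap(sv$expr, sv$surv, intrinsic, alpha = 0.01)
  expect_lt(res$overlap_worse$fisher_p, 1e-4)
  # better-prognosis genes are depleted of the signature
  expect_lt(res$overlap_better$a, res$overlap_better$expected + 1)
})
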