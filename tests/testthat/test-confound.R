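test_that("tissue contrast matches the Welch t.test oracle and is antisymmetric", {
  set.seed(21)
  panel <- tiny_expr(matrix(rnorm(20 * 12), 20, 12), units = "log2")
  tissue <- rep(c("breast", "other"), each = 6)
  tc <- tissue_contrast(panel, tissue, "breast", alpha = 0.05)
  for (i in c(1, 7, 20)) {
    tt <- t.test(panel[i, 1:6], panel[i, 7:12])
    expect_equal(tc$stats$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tc$stats$p[i], tt$p.value, tolerance = 1e-12)
  }
  rev <- tissue_contrast(panel, tissue, "other", alpha = 0.05)
  expect_setequal(rev$high_in_target, tc$low_in_target)
  expect_setequal(rev$low_in_target, tc$high_in_target)
  # identical groups select nothing
  same <- tiny_expr(cbind(matrix(1:40, 20, 2), matrix(1:40, 20, 2)) +
                      matrix(rnorm(80, 0, 1e-9), 20, 4), units = "log2")
  tc0 <- tissue_contrast(same, c("a", "a", "b", "b"), "a", alpha = 1e-6)
  expect_length(tc0$high_in_target, 0)
  expect_error(tissue_contrast(panel, rep("breast", 12), "breast"),
               "groups")
})

test_that("planted tissue structure is recovered from the synthetic panel", {
  cfg <- small_config(seed = 2)
  truth <- make_truth(cfg)
  panel <- generate_normal_tissue_panel(truth, cfg)
  tc <- tissue_contrast(panel$panel, panel$tissue, "breast", alpha = 1e-4)
  breast_markers <- names(truth$gene_role)[truth$gene_role == "breast_marker"]
  confounders <- names(truth$gene_role)[truth$gene_role == "site_confounder"]
  expect_gt(mean(breast_markers %in% tc$high_in_target), 0.9)
  expect_gt(mean(confounders %in% tc$low_in_target), 0.9)
  # neutral genes stay out of both sets
  neutral <- names(truth$gene_role)[truth$gene_role == "neutral"]
  expect_lt(mean(neutral %in% c(tc$high_in_target, tc$low_in_target)), 0.01)
})

test_that("cross-tabulation mirrors the confound pattern on synthetic data", {
  cfg <- small_config(seed = 3)
  gen <- generate_paired_cohort(cfg)
  cohort <- gen$cohort; truth <- gen$truth
  lg <- cohort; lg$expr <- log2_transform(cohort$expr, 1)
  de <- paired_differential(lg)
  sel <- select_differential(de, 0.001, "both")
  panel <- generate_normal_tissue_panel(truth, cfg)
  tc <- tissue_contrast(panel$panel, panel$tissue, "breast", alpha = 1e-4)
  xt <- crosstab_sets(sel$higher, sel$lower, tc$high_in_target,
                      tc$low_in_target, de$gene)
  # met-high genes are enriched for breast-low (site tissue) genes,
  # and met-low genes for breast-high (breast marker) genes
  expect_lt(xt$met_high_x_tissue_low$fisher_p, 1e-4)
  expect_lt(xt$met_low_x_tissue_high$fisher_p, 1e-4)
  # the essential class carries no tissue signal
  scores <- generate_effect_scores(truth, cfg)
  part <- classify_genes(sel$higher, count_essential_lines(scores), 0.10)
  ess <- partition_genes(part, "essential")
  non <- partition_genes(part, "nonessential")
  ess_ov <- overlap_stats(ess, intersect(tc$low_in_target, de$gene), de$gene)
  non_ov <- overlap_stats(non, intersect(tc$low_in_target, de$gene), de$gene)
  expect_gt(ess_ov$fisher_p, 0.01)
  expect_lt(non_ov$fisher_p, 1e-4)
})

test_that("immune infiltrate scores are linear and tested against zero", {
  cfg <- small_config(seed = 4)
  gen <- generate_paired_cohort(cfg)
  lg <- gen$cohort; lg$expr <- log2_transform(gen$cohort$expr, 1)
  truth <- gen$truth
  breast_markers <- names(truth$gene_role)[truth$gene_role == "breast_marker"]
  neutral <- sample(names(truth$gene_role)[truth$gene_role == "neutral"], 40)
  res <- immune_infiltrate_score(lg, list(dropping = breast_markers,
                                          flat = neutral))
  # breast markers are planted lower in metastases
  drop_row <- res$tests[res$tests$set == "dropping", ]
  expect_lt(drop_row$mean, -0.5)
  expect_lt(drop_row$p, 0.01)
  flat_row <- res$tests[res$tests$set == "flat", ]
  expect_gt(flat_row$p, 0.001)
  expect_error(immune_infiltrate_score(lg, list(empty = c("nope"))),
               "empty")
  # all-zero differences: score 0, p = 1
  half <- matrix(rnorm(40 * 4, 5), 40, 4)
  x <- cbind(half, half)
  dimnames(x) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:8))
  samples <- data.frame(sample = colnames(x),
                        patient = rep(sprintf("p%d", 1:4), 2),
                        role = rep(c("metastasis", "primary"), each = 4),
                        stringsAsFactors = FALSE)
  same <- paired_cohort(expression_matrix(x, "log2"), samples)
  res0 <- immune_infiltrate_score(same, list(any = rownames(x)[1:10]))
  expect_true(all(res0$scores == 0))
  expect_equal(res0$tests$p, 1)
})

test_that("site fold-change summaries expose the dominant-site confound", {
  cfg <- small_config(seed = 6)
  gen <- generate_paired_cohort(cfg)
  lg <- gen$cohort; lg$expr <- log2_transform(gen$cohort$expr, 1)
  truth <- gen$truth
  confounders <- names(truth$gene_role)[truth$gene_role == "site_confounder"]
  intrinsic <- names(truth$gene_role)[truth$gene_role == "intrinsic_met"]
  s_conf <- site_foldchange_summary(lg, confounders)
  s_intr <- site_foldchange_summary(lg, intrinsic)
  # dominant-site (liver) median exceeds all other site medians for the
  # confounder set; the intrinsic set is homogeneous across sites
  conf_med <- setNames(s_conf$by_site$q50, s_conf$by_site$site)
  expect_true(all(conf_med["liver"] > conf_med[names(conf_med) != "liver"]))
  expect_gt(var(s_conf$by_site$q50), 4 * var(s_intr$by_site$q50))
  # single-sample site: all quantiles equal that sample's value
  sub <- lg
  sub$pairs <- lg$pairs[1, , drop = FALSE]
  sub$samples <- lg$samples[lg$samples$patient == lg$pairs$patient[1], ]
  s1 <- site_foldchange_summary(sub, confounders)
  expect_equal(unname(unlist(s1$by_site[1, c("q05", "q25", "q50", "q75", "q95")])),
               rep(s1$per_sample$mean_fold_change[1], 5))
})
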