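test_that("essential line counts use a strict threshold and skip NA", {
  m <- rbind(g1 = c(-1.2, -0.8, -0.5, 0.1),
             g2 = c(0, 0.2, -0.1, 0.3),
             g3 = c(-0.75, -0.76, NA, -1))
  colnames(m) <- paste0("l", 1:4)
  cnt <- count_essential_lines(m, -0.75)
  expect_equal(cnt$n_essential, c(2L, 0L, 2L))  # -0.75 itself not counted
  expect_equal(cnt$n_assayed, c(4L, 4L, 3L))
})

test_that("partition classes follow the strict fraction rule", {
  counts <- data.frame(gene = c("a", "b", "c", "d"),
                       n_essential = c(5L, 4L, 0L, 46L),
                       n_assayed = c(46L, 46L, 46L, 46L))
  part <- classify_genes(c("a", "b", "c", "d"), counts, 0.10)
  expect_equal(part$class, c("essential", "intermediate", "nonessential",
                             "essential"))
  expect_equal(part$fraction[1], 5 / 46)
  # boundary: fraction exactly 0.10 is not essential
  b <- classify_genes("x", data.frame(gene = "x", n_essential = 1L,
                                      n_assayed = 10L), 0.10)
  expect_equal(b$class, "intermediate")
  # zero assayed lines excluded with a message
  expect_message(
    z <- classify_genes(c("a", "z"),
                        rbind(counts,
                              data.frame(gene = "z", n_essential = 0L,
                                         n_assayed = 0L)), 0.10),
    "zero assayed")
  expect_equal(z$gene, "a")
})

test_that("overlap statistics reproduce hand-built 2x2 tables", {
  universe <- sprintf("g%03d", 1:100)
  A <- universe[1:30]; B <- universe[21:60]
  ov <- overlap_stats(A, B, universe)
  expect_equal(ov$a, 10); expect_equal(ov$b, 20)
  expect_equal(ov$c, 30); expect_equal(ov$d, 40)
  expect_equal(ov$expected, 30 * 40 / 100)
  # chi-square agrees with the stats::chisq.test reference (no correction)
  ref <- chisq.test(matrix(c(10, 20, 30, 40), 2), correct = FALSE)
  expect_equal(ov$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ov$chisq_p, ref$p.value, tolerance = 1e-12)
  # one-sided Fisher agrees with fisher.test
  ft <- fisher.test(matrix(c(10, 20, 30, 40), 2), alternative = "greater")
  expect_equal(ov$fisher_p, ft$p.value, tolerance = 1e-10)
  expect_equal(ov$odds_ratio, (10 * 40) / (20 * 30))
  expect_error(overlap_stats(c("zzz"), B, universe), "subset")
  expect_error(overlap_stats(A, B, character(0)), "empty universe")
})

test_that("chi-square is symmetric in the two sets", {
  universe <- sprintf("g%03d", 1:80)
  A <- universe[1:25]; B <- universe[10:40]
  expect_equal(overlap_stats(A, B, universe)$chisq,
               overlap_stats(B, A, universe)$chisq, tolerance = 1e-12)
})

test_that("one-sided Fisher equals exhaustive enumeration for all small tables", {
  # every 2x2 table with N <= 12 in unit tests (the N <= 30 sweep runs in
  # the acceptance suite)
  for (N in c(4, 8, 12)) {
    for (sa in 0:N) for (sb in 0:N) {
      if (sa + sb > 2 * N) next
      for (a in max(0, sa + sb - N):min(sa, sb)) {
        got <- overlap_stats_counts(a, sa - a, sb - a, N - sa - sb + a)
        expect_equal(got$fisher_p, enum_fisher_p(a, sa, sb, N),
                     tolerance = 1e-12)
      }
    }
  }
  # disjoint singletons in N = 4: P(X >= 0) = 1 exactly
  expect_equal(overlap_stats_counts(0, 1, 1, 2)$fisher_p, 1)
})

test_that("noise-free scores recover the planted partition exactly", {
  cfg <- small_config(seed = 5, essential_noise_frac = 0,
                      essential_fraction = 0.6)
  truth <- make_truth(cfg)
  scores <- generate_effect_scores(truth, cfg)
  counts <- count_essential_lines(scores, -0.75)
  # zero-noise: no site_confounder / breast_marker / neutral gene has any
  # essential line
  nonplanted <- names(truth$gene_role)[
    !truth$gene_role %in% c("intrinsic_met", "cell_cycle")]
  expect_true(all(counts$n_essential[match(nonplanted, counts$gene)] == 0))
  # metastasis-high universe: all intrinsic + confounder genes
  met_high <- names(truth$gene_role)[
    truth$gene_role %in% c("intrinsic_met", "site_confounder")]
  part <- classify_genes(met_high, counts, 0.10)
  got_ess <- partition_genes(part, "essential")
  expect_setequal(got_ess,
                  names(truth$gene_role)[truth$gene_role == "intrinsic_met"])
  expect_setequal(partition_genes(part, "nonessential"),
                  names(truth$gene_role)[truth$gene_role == "site_confounder"])
})

test_that("planted essential fraction matches the binomial expectation", {
  hits <- vapply(1:8, function(s) {
    cfg <- small_config(seed = s, essential_fraction = 0.9)
    truth <- make_truth(cfg)
    scores <- generate_effect_scores(truth, cfg)
    intr <- names(truth$gene_role)[truth$gene_role == "intrinsic_met"]
    mean(rowSums(scores[intr, ] < -0.75))
  }, numeric(1))
  # expectation 0.9 * 46 = 41.4 lines per gene
  expect_equal(mean(hits), 41.4, tolerance = 0.02)
})
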