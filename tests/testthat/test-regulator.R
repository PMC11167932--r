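test_that("promoter-window assignment follows half-open interval arithmetic", {
  loci <- data.frame(gene = c("plus", "minus"),
                     chrom = "chr1",
                     start = c(10000L, 3000L),
                     end = c(11000L, 5000L),
                     strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  sites <- data.frame(
    tf = c("T1", "T1", "T2", "T2", "T3"),
    chrom = "chr1",
    start = c(8500L, 7900L, 6900L, 7000L, 9990L),
    end = c(8600L, 8000L, 7100L, 7200L, 10005L),
    stringsAsFactors = FALSE)
  res <- map_tf_targets(sites, loci, window = 2000)
  # + strand window [8000, 10000): site [8500,8600) inside; [7900,8000)
  # touches the boundary only -> excluded (half-open)
  expect_equal(res$T1, "plus")
  # - strand window [5000, 7000): [6900,7100) overlaps; [7000,7200) does not
  expect_equal(res$T2, "minus")
  # a site straddling the window end [9990,10005) still intersects
  expect_equal(res$T3, "plus")
  # strand-naive mode uses [start - w, start) for the minus gene too
  naive <- map_tf_targets(sites, loci, window = 2000, strand_aware = FALSE)
  expect_false("minus" %in% naive$T2)
  # order invariance
  res2 <- map_tf_targets(sites[sample(nrow(sites)), ],
                         loci[c(2, 1), ], window = 2000)
  expect_equal(res2[order(names(res2))], res[order(names(res))])
  # malformed records are rejected per-record, not fatally
  bad <- rbind(sites, data.frame(tf = "T1", chrom = "chr1",
                                 start = 500L, end = 400L))
  expect_message(res3 <- map_tf_targets(bad, loci, window = 2000),
                 "rejected")
  expect_equal(res3$T1, "plus")
})

test_that("planted TF targets are recovered exactly from synthetic loci", {
  cfg <- small_config(seed = 25)
  truth <- make_truth(cfg)
  rd <- generate_regulator_data(truth, cfg)
  res <- map_tf_targets(rd$sites, rd$loci, window = 2000)
  for (tf in names(truth$tf_targets)) {
    expect_setequal(res[[tf]], truth$tf_targets[[tf]])
  }
})

test_that("knockdown target sets use a strict threshold and recover truth", {
  km <- rbind(a = c(-0.6, 0), b = c(-0.5, -1), c = c(0.2, -0.51))
  colnames(km) <- c("k1", "k2")
  res <- knockdown_targets(km, -0.5)
  expect_equal(res$k1, "a")           # -0.5 exactly is excluded
  expect_setequal(res$k2, c("b", "c"))
  cfg <- small_config(seed = 26)
  truth <- make_truth(cfg)
  rd <- generate_regulator_data(truth, cfg)
  got <- knockdown_targets(rd$knockdown, -0.5)
  for (k in names(truth$kd_targets)) {
    expect_setequal(got[[k]], truth$kd_targets[[k]])
  }
})

test_that("set-collection enrichment agrees with enumeration and is monotone", {
  universe <- sprintf("g%02d", 1:25)
  query <- universe[1:8]
  coll <- list(inside = universe[1:8], straddle = universe[5:14],
               outside = universe[15:25])
  rep_ <- fisher_enrichment(query, coll, universe)
  for (i in seq_len(nrow(rep_))) {
    expect_equal(rep_$fisher_p[i],
                 enum_fisher_p(rep_$overlap[i], rep_$set_size[i],
                               rep_$query_size[i], 25),
                 tolerance = 1e-12)
  }
  # query identical to a set: p is the point mass of full overlap
  expect_equal(rep_$fisher_p[rep_$set == "inside"],
               enum_fisher_p(8, 8, 8, 25), tolerance = 1e-12)
  # disjoint set: p = 1
  expect_equal(rep_$fisher_p[rep_$set == "outside"], 1)
  # monotonicity: larger overlap at fixed margins -> smaller or equal p
  ps <- vapply(0:8, function(a) enum_fisher_p(a, 8, 8, 25), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("multiway intersections partition the union exactly", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"),
               C = c("z", "q"))
  reg <- multiway_intersection(sets)
  expect_setequal(unlist(reg), unique(unlist(sets)))
  expect_equal(sum(lengths(reg)), length(unique(unlist(sets))))
  expect_equal(sort(reg[["A&B&C"]]), "z")
  expect_equal(sort(reg[["A&B"]]), "y")
  # identical sets: only the all-in region
  same <- multiway_intersection(list(P = c("a", "b"), Q = c("a", "b")))
  expect_equal(names(same), "P&Q")
  # pairwise disjoint: only singleton regions
  disj <- multiway_intersection(list(P = "a", Q = "b", R = "c"))
  expect_setequal(names(disj), c("P", "Q", "R"))
  # brute-force tabulation on random sets
  set.seed(4)
  rs <- lapply(setNames(1:4, c("s1", "s2", "s3", "s4")),
               function(i) sample(letters, 10))
  reg2 <- multiway_intersection(rs)
  for (g in unique(unlist(rs))) {
    key <- paste(names(rs)[vapply(rs, function(s) g %in% s, logical(1))],
                 collapse = "&")
    expect_true(g %in% reg2[[key]])
  }
})
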