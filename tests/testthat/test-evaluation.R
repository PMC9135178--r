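# Metric closed forms, dataset I/O, Top-N curves and the rank-distribution
# comparison.

test_that("metric closed forms are exact", {
  expect_identical(cs_score(1, 1), 100)
  expect_identical(cs_score(0, 0.7), 0)
  expect_identical(cs_score(0.5, 0.5), 25)
  expect_identical(coverage(578, 850), 0.68)
  expect_identical(coverage(0, 10), 0)
  expect_identical(coverage(14, 14), 1)
  expect_equal(sorting_ability(c(1, 2, 4)), (1 + 0.5 + 0.25) / 3)
  expect_identical(sorting_ability(c(1, 1, 1)), 1)
  expect_identical(sorting_ability(50), 0.02)
  expect_error(coverage(1, 0))
  expect_error(sorting_ability(integer()))
  expect_error(cs_score(1.2, 0.5))
})

test_that("pair CSVs load with validation and line-number reporting", {
  good <- data.frame(substrate_id = c("a", "b"),
                     substrate_smiles = c("CCO", "CCOC(C)=O"),
                     metabolite_smiles = c("CC(=O)O", "CCO"))
  p <- tempfile(fileext = ".csv")
  write.csv(good, p, row.names = FALSE)
  ds <- load_pairs(p)
  expect_s3_class(ds, "pair_dataset")
  expect_identical(nrow(ds), 2L)

  bad <- rbind(good, data.frame(substrate_id = "c", substrate_smiles = "C(",
                                metabolite_smiles = "CCO"))
  write.csv(bad, p, row.names = FALSE)
  err <- tryCatch(load_pairs(p), error = identity)
  expect_s3_class(err, "pair_file_error")
  expect_match(conditionMessage(err), "line 4")  # header + 3 data rows
  expect_warning(ds2 <- load_pairs(p, strict = FALSE), "dropped")
  expect_identical(nrow(ds2), 2L)

  same <- data.frame(substrate_id = "x", substrate_smiles = "CCO",
                     metabolite_smiles = "OCC")
  write.csv(same, p, row.names = FALSE)
  expect_error(load_pairs(p), class = "pair_file_error")

  write.csv(good[, 1:2], p, row.names = FALSE)
  expect_error(load_pairs(p), class = "pair_file_error")
})

test_that("evaluate_pairs recovers planted metabolites and scores them", {
  ds <- small_mixed_pairs()
  ev <- evaluate_pairs(ds)
  expect_identical(ev$n_total, 5L)
  expect_identical(ev$C, 1)
  expect_true(all(ev$hit_ranks <= 50L))
  expect_equal(ev$CS, cs_score(ev$C, ev$S))
  # misses give zero scores
  miss <- pair_dataset(data.frame(
    substrate_id = "m", substrate_smiles = "CCOC(C)=O",
    metabolite_smiles = "c1ccncc1"), source = "miss")
  ev0 <- evaluate_pairs(miss)
  expect_identical(ev0$n_hit, 0L)
  expect_identical(ev0$CS, 0)
})

test_that("evaluation is invariant under dataset duplication", {
  ds <- small_mixed_pairs()
  twice <- pair_dataset(rbind(as.data.frame(ds), as.data.frame(ds)),
                        source = "twice")
  ev1 <- evaluate_pairs(ds)
  ev2 <- evaluate_pairs(twice)
  expect_identical(ev2$C, ev1$C)
  expect_identical(ev2$S, ev1$S)
  expect_identical(ev2$CS, ev1$CS)
})

test_that("the s-denominator convention switches between hits and all", {
  ev_hits <- score_rank_list(c(1, 4, NA, NA), s_denominator = "hits")
  ev_all <- score_rank_list(c(1, 4, NA, NA), s_denominator = "all")
  expect_equal(ev_hits$S, (1 + 0.25) / 2)
  expect_equal(ev_all$S, (1 + 0.25) / 4)
  expect_equal(ev_hits$C, 0.5)
  expect_equal(ev_all$C, 0.5)
})

test_that("published per-compound ranks score as expected under the hits convention", {
  # nine hits at ranks {1,1,1,1,1,1,2,3,7} among 14 known metabolites
  ranks <- c(1, 1, 1, 1, 1, 1, 2, 3, 7, NA, NA, NA, NA, NA)
  ev <- score_rank_list(ranks)
  expect_equal(ev$C, 9 / 14)
  expect_equal(ev$S, (6 + 1 / 2 + 1 / 3 + 1 / 7) / 9)
  expect_equal(ev$CS, 100 * (9 / 14) * ((6 + 1 / 2 + 1 / 3 + 1 / 7) / 9),
               tolerance = 1e-12)
  expect_identical(unname(ev$topn_counts["1"]), 6L)
})

test_that("hits outside the cutoff count as misses and coverage grows with top_k", {
  ev10 <- score_rank_list(c(1, 8, 30), top_k = 10L)
  ev50 <- score_rank_list(c(1, 8, 30), top_k = 50L)
  expect_identical(ev10$n_hit, 2L)
  expect_identical(ev50$n_hit, 3L)
  expect_gte(ev50$C, ev10$C)
  expect_identical(unname(ev50$topn_counts[as.character(50)]), ev50$n_hit)
})

test_that("topn_curve accumulates coverage correctly", {
  ev <- score_rank_list(c(1, 3, NA, NA))
  curve <- topn_curve(ev)
  expect_identical(curve$cumulative_coverage[curve$N == 1], 0.25)
  expect_identical(curve$cumulative_coverage[curve$N == 3], 0.5)
  expect_identical(curve$cumulative_coverage[curve$N == 50], 0.5)
  expect_true(all(diff(curve$cumulative_coverage) >= 0))
  # all hits at rank 1: flat curve; no hits: identically zero
  flat <- topn_curve(score_rank_list(c(1, 1)))
  expect_true(all(flat$cumulative_coverage == 1))
  zero <- topn_curve(score_rank_list(c(NA, NA)))
  expect_true(all(zero$cumulative_coverage == 0))
})

test_that("external rank lists score through the same metric", {
  pairs <- pair_dataset(data.frame(
    substrate_id = c("s1", "s2"),
    substrate_smiles = c("CCOC(C)=O", "COc1ccccc1"),
    metabolite_smiles = c("CC(=O)O", "Oc1ccccc1")),
    source = "external")
  rl <- data.frame(
    substrate_id = c("s1", "s1", "s2", "s2"),
    rank = c(1L, 2L, 1L, 2L),
    candidate_smiles = c("CCO", "OC(C)=O", "c1ccccc1", "Oc1ccccc1"))
  ev <- evaluate_rank_list(rl, pairs)
  expect_identical(ev$n_hit, 2L)
  expect_identical(sort(ev$hit_ranks), c(2L, 2L))
})

test_that("rank-distribution comparison behaves at the extremes", {
  same <- compare_rank_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_gte(same$p_value, 0.99)
  far <- compare_rank_distributions(rep(1, 100), rep(50, 100))
  expect_lt(far$p_value, 0.05)
  expect_true(far$degenerate)  # both samples constant
  mixed <- compare_rank_distributions(c(1, 1, 2, 3, NA), c(20, 30, NA, NA, NA))
  expect_lt(mixed$p_value, 0.05)
})

test_that("the t-based comparison agrees with an exhaustive permutation oracle", {
  separated <- list(a = c(1, 1, 2, 1, 3), b = c(25, NA, 40, NA, 30))
  similar <- list(a = c(2, 5, 10, 3, 8), b = c(3, 6, 9, 4, 7))
  p_t_sep <- compare_rank_distributions(separated$a, separated$b)$p_value
  p_perm_sep <- perm_test_mean_diff(separated$a, separated$b)
  p_t_sim <- compare_rank_distributions(similar$a, similar$b)$p_value
  p_perm_sim <- perm_test_mean_diff(similar$a, similar$b)
  # both oracles call the separated case significant and the similar one not
  expect_lt(p_t_sep, 0.05); expect_lt(p_perm_sep, 0.05)
  expect_gt(p_t_sim, 0.2); expect_gt(p_perm_sim, 0.2)
  # and they order the two cases identically
  expect_true((p_t_sep < p_t_sim) == (p_perm_sep < p_perm_sim))
})
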