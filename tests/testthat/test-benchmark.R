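# GDT_TS combination, binned ranking, selection rules, Wilcoxon comparisons.

test_that("gdt_ts averages its four cutoffs and enforces monotonicity", {
  expect_equal(gdt_ts(100, 100, 100, 100), 100)
  expect_equal(gdt_ts(40, 60, 80, 100), 70)
  expect_equal(gdt_ts(0, 0, 0, 0), 0)
  expect_error(gdt_ts(50, 40, 80, 100), "inconsistent cutoff")
  expect_error(gdt_ts(-1, 0, 0, 0), "\\[0, 100\\]")
})

test_that("assign_ranks bins from the set maximum in 2.5-unit steps", {
  s <- decoy_set("t", c("a", "b", "c"), c(82.0, 80.1, 79.0))
  r <- assign_ranks(s)
  expect_identical(unname(r[c("a", "b", "c")]), c(1L, 1L, 2L))

  with_nat <- decoy_set("t", c("nat", "m"), c(100, 65), c(TRUE, FALSE))
  rn <- assign_ranks(with_nat)
  expect_identical(unname(rn["nat"]), 1L)
  expect_identical(unname(rn["m"]), 15L)  # separated by 14 bins

  flat <- decoy_set("t", letters[1:4], rep(50, 4))
  expect_true(all(assign_ranks(flat) == 1L))
})

test_that("assign_ranks is translation-invariant with the documented extremes", {
  set.seed(23)
  for (k in 1:20) {
    g <- runif(8, 30, 90)
    s <- decoy_set("t", paste0("m", 1:8), g)
    s2 <- decoy_set("t", paste0("m", 1:8), pmin(g + 7.3, 100))
    if (max(g) + 7.3 <= 100) {
      expect_identical(assign_ranks(s), assign_ranks(s2))
    }
    r <- assign_ranks(s)
    expect_identical(min(r), 1L)
    expect_identical(max(r), 1L + as.integer(floor((max(g) - min(g)) / 2.5 + 1e-9)))
  }
})

test_that("rank_of_selection implements the native-present rank-2 rule", {
  s <- decoy_set("t", c("nat", "m70", "m50"), c(100, 70, 50),
                 c(TRUE, FALSE, FALSE))
  e_nat <- c(nat = -5, m70 = 0, m50 = 1)
  expect_identical(rank_of_selection(s, e_nat, "with_native"), 1L)
  e_best <- c(nat = 0, m70 = -5, m50 = 1)
  expect_identical(rank_of_selection(s, e_best, "with_native"), 2L)
  # selected model is NOT the best non-native: 1 + its rank among non-natives
  e_worse <- c(nat = 0, m70 = 1, m50 = -5)
  expect_identical(rank_of_selection(s, e_worse, "with_native"),
                   1L + 1L + as.integer(floor((70 - 50) / 2.5)))
  expect_error(rank_of_selection(decoy_set("t", "m", 50), c(m = 1), "with_native"),
               "requires a native")
  expect_error(rank_of_selection(s, c(nat = 0, m70 = 1), "with_native"),
               "missing")
})

test_that("without_native selection is monotone-transform invariant and matches enumeration", {
  g <- c(72, 70, 61, 55, 40)
  s <- decoy_set("t", paste0("m", 1:5), g)
  # energies perfectly anti-correlated with quality pick the worst model
  e <- stats::setNames(g, paste0("m", 1:5))
  expect_identical(rank_of_selection(s, e, "without_native"),
                   unname(assign_ranks(s)["m5"]))
  # invariance under strictly monotone transforms of the energies
  set.seed(31)
  for (k in 1:20) {
    e_r <- stats::setNames(rnorm(5), paste0("m", 1:5))
    r1 <- rank_of_selection(s, e_r, "without_native")
    r2 <- rank_of_selection(s, exp(e_r) + 3, "without_native")
    expect_identical(r1, r2)
  }
  # energy ties break by lexicographic model id
  e_tie <- stats::setNames(c(0, 0, 1, 1, 1), paste0("m", 1:5))
  expect_identical(rank_of_selection(s, e_tie, "without_native"),
                   unname(assign_ranks(s)["m1"]))
})

test_that("summaries match oracle, anti-oracle and exhaustive random expectation", {
  set.seed(37)
  bench <- generate_decoy_benchmark(10, 8, rho = 1, seed = 41)
  su <- summarize_ranks(bench$sets, bench$energies, "without_native")
  expect_equal(su$average_rank, 1)
  expect_identical(su$ranked_1_count, 10L)

  # worst-case scorer: average equals the mean of each set's maximum rank
  worst <- bench$energies
  worst$energy <- vapply(seq_len(nrow(worst)), function(i) {
    s <- bench$sets[[match(worst$target_id[i], vapply(bench$sets, `[[`, "", "target_id"))]]
    s$records$gdt_ts[match(worst$model_id[i], s$records$model_id)]
  }, 0)
  su_w <- summarize_ranks(bench$sets, worst, "without_native")
  expect_equal(su_w$average_rank,
               mean(vapply(bench$sets, function(s) max(assign_ranks(s)), 1L)))

  # random scorer: expected rank equals the mean rank of the set (argmin is
  # uniform over models); verified by exhaustive enumeration on <= 4 models
  small <- generate_decoy_benchmark(6, 4, rho = 0, seed = 43)
  exp_rank <- mean(vapply(small$sets, function(s) mean(assign_ranks(s)), 0))
  orders <- perms_of(1:4)
  mc <- mean(vapply(small$sets, function(s) {
    mean(vapply(orders, function(p) {
      e <- stats::setNames(p, s$records$model_id)
      rank_of_selection(s, e, "without_native")
    }, 1L))
  }, 0))
  expect_equal(mc, exp_rank, tolerance = 1e-12)
})

test_that("with_native ranked_1 counts native selections only", {
  bench <- generate_decoy_benchmark(8, 6, rho = 1, seed = 47, include_native = TRUE)
  su <- summarize_ranks(bench$sets, bench$energies, "with_native")
  # rho = 1 energies rank the native (GDT 100) lowest in every set
  expect_equal(su$average_rank, 1)
  expect_identical(su$ranked_1_count, 8L)
})

test_that("wilcoxon matches exact enumeration and stats::wilcox.test", {
  # n = 6, uniform one-unit wins: p = 1/64 by 2^6 enumeration
  res <- wilcoxon_one_tailed(rep(1, 6), rep(2, 6))
  expect_equal(res$p_value, 1 / 64)
  expect_identical(res$n_effective, 6L)
  # identical samples degenerate to p = 1 with a warning
  expect_warning(res0 <- wilcoxon_one_tailed(1:5, 1:5), "zero")
  expect_equal(res0$p_value, 1)
  # agreement with the independent implementation in stats (no ties)
  set.seed(53)
  for (k in 1:8) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(
      wilcoxon_one_tailed(a, b)$p_value,
      stats::wilcox.test(a, b, paired = TRUE, alternative = "less",
                         exact = TRUE)$p.value,
      tolerance = 1e-12
    )
  }
  # normal-approximation branch agrees with stats above the exact cutoff
  a <- rnorm(40); b <- a + rnorm(40, 0.2)
  expect_equal(
    wilcoxon_one_tailed(a, b)$p_value,
    stats::wilcox.test(a, b, paired = TRUE, alternative = "less",
                       exact = FALSE, correct = TRUE)$p.value,
    tolerance = 1e-12
  )
})

test_that("wilcoxon p-values respond correctly to shifts and swaps", {
  set.seed(59)
  a <- rnorm(10); b <- rnorm(10)
  p0 <- wilcoxon_one_tailed(a, b)$p_value
  p_shift <- wilcoxon_one_tailed(a - 5, b)$p_value
  expect_lte(p_shift, p0)  # shifting a down can only strengthen "a lower"
  # swap consistency: the two one-sided p-values overlap exactly at the atom
  # of the observed statistic (no ties here, so ranks are 1..10 and W+ is
  # integer; stats::dsignrank supplies the independent atom probability)
  res_ab <- wilcoxon_one_tailed(a, b)
  res_ba <- wilcoxon_one_tailed(b, a)
  atom <- stats::dsignrank(res_ab$statistic, 10)
  expect_equal(res_ab$p_value + res_ba$p_value, 1 + atom, tolerance = 1e-12)
})

test_that("select_decoys applies the four selection rules", {
  cand <- data.frame(
    model_id = paste0("m", 1:10),
    gdt_ts = c(64.9, seq(40, 62, length.out = 9)),
    length = rep(100L, 10)
  )
  res <- select_decoys(cand, seed = 1, target_id = "t")
  expect_true(res$rejected)
  expect_identical(res$reason, "best_model_below_threshold")

  cand2 <- data.frame(
    model_id = paste0("m", 1:10),
    gdt_ts = c(66, 67, 70, 71, 74, 75, 78, 79, 66.5, 70.5),
    length = rep(80L, 10)
  )
  res2 <- select_decoys(cand2, seed = 1, target_id = "t")
  expect_false(res2$rejected)
  # bins floor(g/2.5): 66->26, 67->26, 70->28, ... exactly 4 occupied bins
  expect_identical(length(unique(floor(cand2$gdt_ts / 2.5))),
                   nrow(res2$set$records))

  cand3 <- rbind(
    data.frame(model_id = paste0("a", 1:7), gdt_ts = 70, length = 120L),
    data.frame(model_id = paste0("b", 1:3), gdt_ts = 80, length = 90L)
  )
  res3 <- select_decoys(cand3, seed = 1, target_id = "t")
  expect_true(all(startsWith(res3$set$records$model_id, "a")))

  # all-atom flag filter and determinism under a fixed seed
  cand4 <- cand2
  cand4$all_atom <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  r41 <- select_decoys(cand4, seed = 7, target_id = "t")
  r42 <- select_decoys(cand4, seed = 7, target_id = "t")
  expect_identical(r41$set$records, r42$set$records)
  expect_false("m4" %in% r41$set$records$model_id)
})

test_that("manifests and score files round-trip", {
  bench <- generate_decoy_benchmark(3, 5, rho = 0.5, seed = 61,
                                    include_native = TRUE)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_decoy_manifest(bench$sets, mpath)
  sets2 <- read_decoy_manifest(mpath)
  expect_identical(names(sets2), c("T001", "T002", "T003"))
  for (k in 1:3) {
    expect_equal(sets2[[k]]$records$gdt_ts, bench$sets[[k]]$records$gdt_ts)
    expect_identical(sets2[[k]]$records$is_native, bench$sets[[k]]$records$is_native)
  }
  write_score_file(bench$energies[c("model_id", "energy")], spath)
  sc <- read_score_file(spath)
  expect_equal(sc$energy, bench$energies$energy)
})

test_that("significance matrix blanks sub-threshold p-values in its display copy", {
  set.seed(67)
  rl <- list(good = rep(1, 12) + rpois(12, 0.2),
             bad = rep(4, 12) + rpois(12, 2),
             alsobad = rep(4, 12) + rpois(12, 2))
  p <- significance_matrix(rl)
  expect_true(is.na(p["good", "good"]))
  expect_lt(p["good", "bad"], 0.05)
  disp <- attr(p, "display")
  expect_identical(disp["good", "bad"], "")
  expect_true(disp["bad", "good"] != "")
})
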