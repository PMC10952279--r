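test_that("auc_mwu reproduces hand-counted AUCs and orientations", {
  expect_equal(auc_mwu(c(5, 6), c(1, 2), "greater")$auc, 1)
  expect_equal(auc_mwu(c(3, 1), c(2, 0), "greater")$auc, 0.75)
  expect_equal(auc_mwu(c(1, 2), c(5, 6), "less")$auc, 1)
  expect_error(auc_mwu(numeric(0), c(1)), "non-empty")
})

test_that("auc_mwu AUC is antisymmetric under group swap, ties included", {
  set.seed(101)
  for (k in 1:30) {
    x <- round(runif(sample(2:10, 1), 0, 4), 1)
    y <- round(runif(sample(2:10, 1), 0, 4), 1)
    expect_equal(auc_mwu(x, y, "greater")$auc,
                 1 - auc_mwu(y, x, "greater")$auc)
  }
})

test_that("auc_mwu shares its kernel with drs on identical score sets", {
  set.seed(111)
  z_res <- runif(8, 0, 5); z_spa <- runif(11, 0, 5)
  abn <- make_abn(c(z_res, z_spa))
  mask <- make_mask(c(rep("resected", 8), rep("spared", 11)))
  expect_equal(auc_mwu(z_spa, z_res, "greater")$auc, drs(abn, mask))
})

test_that("auc_mwu exact p agrees with wilcox.test on tie-free small samples", {
  set.seed(121)
  for (k in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    ours <- auc_mwu(x, y, "greater")
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("auc_mwu exact p under ties matches brute-force permutation", {
  perm_p <- function(x, y) {         # enumerate all group assignments
    r <- rank(c(x, y)); nx <- length(x)
    obs <- sum(r[seq_len(nx)])
    combos <- combn(length(r), nx)
    mean(apply(combos, 2, function(idx) sum(r[idx])) >= obs - 1e-9)
  }
  set.seed(131)
  for (k in 1:10) {
    x <- sample(0:3, sample(3:6, 1), replace = TRUE)
    y <- sample(0:3, sample(3:6, 1), replace = TRUE)
    expect_equal(auc_mwu(x, y, "greater")$p, perm_p(x, y))
  }
})

test_that("one-tailed MWU test keeps its nominal size under the null", {
  set.seed(141)
  rej <- replicate(1000, {
    auc_mwu(rnorm(8), rnorm(8), "greater")$p <= 0.05
  })
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
  set.seed(151)
  aucs <- replicate(400, auc_mwu(rnorm(12), rnorm(12), "greater")$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("wilcoxon_one_sample reproduces enumerated exact p-values", {
  r1 <- wilcoxon_one_sample(c(3, 4, 5), 2.6, "greater")
  expect_equal(r1$W, 6)
  expect_equal(r1$p, 1 / 8)          # 2^3 sign patterns, only +++ gives W = 6
  r2 <- wilcoxon_one_sample(c(0.1, 0.2, 0.1, 0.3, 0.1), 0.5, "less")
  expect_equal(r2$W, 0)
  expect_equal(r2$p, 1 / 32)         # all-negative is the only W = 0 pattern
  expect_error(wilcoxon_one_sample(c(2, 2), 2), "zero")
})

test_that("wilcoxon_one_sample agrees with wilcox.test when tie-free", {
  set.seed(161)
  for (k in 1:20) {
    v <- rnorm(sample(4:20, 1), 0.3)
    ours <- wilcoxon_one_sample(v, 0, "greater")
    ref <- wilcox.test(v, mu = 0, alternative = "greater", exact = TRUE)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$W, unname(ref$statistic))
  }
})

test_that("wilcoxon_one_sample p is near one half under a symmetric null", {
  set.seed(171)
  ps <- replicate(500, wilcoxon_one_sample(rnorm(15), 0, "less")$p)
  expect_lt(abs(mean(ps) - 0.5), 0.05)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("simulated healthy max-|z| threshold matches the closed form", {
  t5 <- max_abs_z_threshold_exact(5, 0.05)
  expect_equal((2 * pnorm(t5) - 1)^5, 0.95, tolerance = 1e-12)
  expect_equal(round(t5, 1), 2.6)
  sim <- simulate_max_abs_z_threshold(5, 100000, 0.05, seed = 7)
  expect_lt(abs(sim - t5), 0.05)
  expect_equal(max_abs_z_threshold_exact(1, 0.05), qnorm(0.975))
  sim1 <- simulate_max_abs_z_threshold(1, 50000, 0.05, seed = 7)
  expect_lt(abs(sim1 - 1.96), 0.05)
  expect_identical(simulate_max_abs_z_threshold(seed = 3),
                   simulate_max_abs_z_threshold(seed = 3))
  expect_error(simulate_max_abs_z_threshold(alpha = 1.2), "alpha")
})

test_that("optimal_threshold separates the textbook cases", {
  th <- optimal_threshold(c(1, 2, 5, 6), c("bad", "bad", "good", "good"),
                          "low")
  expect_equal(th$threshold, 3.5)
  expect_equal(th$J, 1)
  flat <- optimal_threshold(rep(2, 6), rep(c("good", "bad"), 3), "low")
  expect_equal(flat$threshold, -Inf)   # nobody flagged when J is flat at 0
  expect_equal(flat$J, 0)
  expect_error(optimal_threshold(1:3, rep("good", 3), "low"), "both outcome")
})

test_that("optimal_threshold attains the exhaustive-scan maximum J", {
  set.seed(181)
  for (k in 1:60) {
    n <- sample(6:20, 1)
    v <- round(runif(n, 0, 10), sample(0:1, 1))
    o <- sample(c("good", "bad"), n, replace = TRUE)
    if (!any(o == "good")) o[1] <- "good"
    if (!any(o == "bad")) o[2] <- "bad"
    dirn <- sample(c("low", "high"), 1)
    got <- optimal_threshold(v, o, dirn)
    expect_equal(got$J, oracle_best_J(v, o, dirn), tolerance = 1e-12)
  }
})

test_that("flag logic uses strict inequalities per mechanism", {
  ths <- threshold_set(3.35, 0.34, 9.58)
  cohort <- cohort_table(c("s1", "s2", "s3", "s4"),
                         MA_R = c(1.16, 3.35, 5, 5),
                         D_RS = c(0.2, 0.73, 0.34, 0.1),
                         AC_R = c(19, 12, 9.58, 5),
                         outcome = c("bad", "bad", "good", "good"))
  fl <- flag_failures(cohort, ths)
  expect_equal(fl$mech1, c(TRUE, FALSE, FALSE, FALSE))   # boundary 3.35 no flag
  expect_equal(fl$mech2, c(FALSE, TRUE, FALSE, FALSE))   # boundary 0.34 no flag
  expect_equal(fl$mech3, c(FALSE, FALSE, FALSE, TRUE))   # boundary 9.58 no flag
  expect_equal(fl$n_flags, c(1, 1, 0, 1))
  # monotonicity: raising the MA_R threshold never clears a mechanism-1 flag
  fl2 <- flag_failures(cohort, threshold_set(5.5, 0.34, 9.58))
  expect_true(all(fl2$mech1 >= fl$mech1))
})

test_that("unified analysis flags a fully separated synthetic cohort", {
  cohort <- cohort_table(
    sprintf("s%02d", 1:12),
    MA_R = c(rep(6, 6), rep(1, 6)),
    D_RS = c(rep(0.1, 6), rep(0.8, 6)),
    AC_R = c(rep(20, 6), rep(3, 6)),
    outcome = c(rep("good", 6), rep("bad", 6)))
  rep_ <- unified_outcome_analysis(cohort)
  expect_true(all(rep_$marker_stats$auc == 1))
  expect_equal(rep_$n_flags_auc, 1)
  expect_equal(unname(rep_$flag_rates["bad", "ge1"]), 1)
  expect_equal(unname(rep_$flag_rates["good", "none"]), 1)
})

test_that("unified analysis is null-calibrated when markers carry no signal", {
  set.seed(191)
  aucs <- replicate(200, {
    cohort <- cohort_table(sprintf("s%02d", 1:16),
                           MA_R = runif(16, 0, 6), D_RS = runif(16),
                           AC_R = runif(16, 0, 30),
                           outcome = rep(c("good", "bad"), 8))
    unified_outcome_analysis(cohort)$marker_stats$auc
  })
  expect_lt(max(abs(rowMeans(aucs) - 0.5)), 0.05)
})
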