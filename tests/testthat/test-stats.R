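test_that("recovery rates and quartile/median grouping", {
  expect_equal(compute_recovery_rate(300, 300), 100)
  expect_equal(compute_recovery_rate(0, 300), 0)
  expect_error(compute_recovery_rate(100, 0), "must be positive")

  g <- assign_recovery_groups(c(0, 10, 30, 49, 60, 80, 25, 50, 75))
  expect_equal(g$quartile_group, c(1, 1, 2, 2, 3, 4, 2, 3, 4))  # boundaries go up
  expect_equal(attr(g, "median_pct"), 49)
  expect_equal(g$above_median, c(0, 10, 30, 49, 60, 80, 25, 50, 75) > 49)

  g30 <- assign_recovery_groups(c(10, 40), median_value = 30)
  expect_equal(g30$above_median, c(FALSE, TRUE))
  expect_error(assign_recovery_groups(c(-1, 10)), "nonnegative")
})

test_that("Pearson association: exact lines, hand oracle, degenerate input", {
  expect_equal(pearson_assoc(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_assoc(1:3, c(3, 2, 1))$r, -1)

  x <- c(1.2, -0.7, 3.1, 0.4, 2.2)
  y <- c(0.3, 1.9, -1.2, 0.8, 0.1)
  res <- pearson_assoc(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), 3), tolerance = 1e-12)

  # undefined feature values are removed pairwise
  res2 <- pearson_assoc(c(x, NA), c(y, 5))
  expect_equal(res2$n, 5)
  expect_equal(res2$n_dropped, 1)
  expect_equal(res2$r, r_hand)

  expect_error(pearson_assoc(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_assoc(1:2, 2:3), "at least 3")
})

test_that("one-way ANOVA matches the brute-force SS decomposition", {
  groups <- list(c(4.1, 5.2, 6.0, 5.5), c(6.8, 7.7, 7.1), c(9.4, 8.8, 10.1, 9.0))
  an <- one_way_anova(groups)
  or <- anova_oracle(groups)
  expect_equal(an$F, or$F, tolerance = 1e-12)
  expect_equal(an$p_value, or$p, tolerance = 1e-12)
  expect_equal(an$ss_between, or$ss_between, tolerance = 1e-12)
  expect_equal(an$ss_within, or$ss_within, tolerance = 1e-12)
  expect_equal(an$ss_total, or$ss_total, tolerance = 1e-12)

  expect_error(one_way_anova(list(rep(5, 4), rep(5, 3))), "degenerate")
  expect_error(one_way_anova(list(1:3, numeric(0))), "non-empty")
  expect_error(one_way_anova(list(1:3, 4)), "n >= 2")

  # two-group ANOVA is the squared pooled t test
  set.seed(51)
  a <- rnorm(10); b <- rnorm(12, mean = 0.5)
  an2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an2$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("studentized maximum modulus reduces to the t distribution at k = 1", {
  for (q in c(0.5, 1.3, 2.7)) {
    for (nu in c(3.4, 8, 25)) {
      expect_equal(psmm(q, 1, nu), stats::pt(q, nu) - stats::pt(-q, nu),
                   tolerance = 1e-7)
    }
  }
  expect_equal(psmm(0, 3, 10), 0)
  expect_gt(psmm(10, 5, 30), 0.9999)
})

test_that("Dunnett T3: identical groups, antisymmetry, Welch reduction, monotonicity", {
  g <- c(1.2, 1.9, 0.7, 1.5)
  res <- dunnett_t3(list(g, g))
  expect_equal(res$mean_difference, 0)
  expect_gt(res$p_value, 0.999)

  set.seed(52)
  a <- rnorm(8); b <- rnorm(6, 1); c_ <- rnorm(7, 2, 2)
  r3 <- dunnett_t3(list(a, b, c_))
  r3_swap <- dunnett_t3(list(b, a, c_))
  ij <- r3$group_i == "1" & r3$group_j == "2"
  ji <- r3_swap$group_i == "1" & r3_swap$group_j == "2"
  expect_equal(r3$mean_difference[ij], -r3_swap$mean_difference[ji])

  # a single comparison is exactly a Welch t test
  r1 <- dunnett_t3(list(a, b))
  expect_equal(r1$p_value, welch_p_oracle(a, b), tolerance = 1e-6)

  # adjusted p-values never fall below the unadjusted Welch p-values
  welch_ps <- c(welch_p_oracle(a, b), welch_p_oracle(a, c_), welch_p_oracle(b, c_))
  expect_true(all(r3$p_value >= welch_ps - 1e-10))

  # zero variance in both groups of a pair is flagged degenerate
  rd <- dunnett_t3(list(rep(1, 3), rep(2, 3), rnorm(4)))
  expect_true(rd$degenerate[rd$group_i == "1" & rd$group_j == "2"])
})

test_that("ROC: separation, tiny worked set, AUC identity, permuted labels", {
  # perfectly separated classes
  r <- roc_analysis(c(1, 2, 3, 4, 5, 6), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_gt(r$cut_off, 3); expect_lte(r$cut_off, 4)
  expect_equal(r$sensitivity, 1); expect_equal(r$one_minus_specificity, 0)

  # tiny worked set {pos: 3, 4; neg: 1, 2}: exhaustive enumeration gives
  # AUC 1 and a Youden cut-off in (2, 3]
  r2 <- roc_analysis(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 1)
  expect_gt(r2$cut_off, 2); expect_lte(r2$cut_off, 3)

  # trapezoid AUC equals normalized Mann-Whitney U on 100 random instances
  set.seed(53)
  for (i in 1:100) {
    f <- sample(1:8, 30, replace = TRUE) + rnorm(30, sd = 0.01 * (i %% 2))
    lab <- runif(30) < 0.4
    if (!any(lab) || all(lab)) lab[c(1, 2)] <- c(TRUE, FALSE)
    expect_equal(roc_analysis(f, lab)$auc, auc_mw_oracle(f, lab),
                 tolerance = 1e-12)
  }

  # label-permuted data: AUC near one half on average
  set.seed(54)
  aucs <- replicate(200, {
    f <- rnorm(80)
    roc_analysis(f, sample(rep(c(TRUE, FALSE), 40)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "non-empty")

  # Hanley-McNeil standard error at a known operating point
  set.seed(55)
  f <- c(rnorm(25, 1), rnorm(25))
  lab <- rep(c(TRUE, FALSE), each = 25)
  r4 <- roc_analysis(f, lab)
  A <- r4$auc; q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + 24 * (q1 - A^2) + 24 * (q2 - A^2)) / 625)
  expect_equal(r4$standard_error, se, tolerance = 1e-12)
})

test_that("ROC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(56)
  f <- rnorm(60)
  lab <- f + rnorm(60) > 0.3
  if (!any(lab) || all(lab)) lab[1:2] <- c(TRUE, FALSE)
  ours <- roc_analysis(f, lab)
  theirs <- pROC::roc(response = as.integer(lab), predictor = f, quiet = TRUE,
                      levels = c(0, 1), direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("build_report ranks features, writes tables, and is deterministic", {
  set.seed(57)
  n <- 60
  r_true <- runif(n)
  features <- data.frame(
    subject = "S1", session = "BLS-1", epoch_time_s = seq_len(n),
    magnitude = 30 * r_true + rnorm(n, sd = 1),
    synch_fast_slow = rnorm(n),
    beta_r = rnorm(n), delta_r = rnorm(n),
    alpha_pr = runif(n), beta_pr = runif(n), delta_pr = runif(n),
    theta_pr = runif(n), bg_alpha_plus = runif(n),
    log_energy_entropy = 2000 * r_true + rnorm(n, sd = 80),
    renyi_entropy = 5 * r_true + rnorm(n, sd = 0.3))
  recovery <- assign_recovery_groups(100 * r_true + rnorm(n, sd = 1))

  dir <- withr::local_tempdir()
  rep1 <- build_report(features, recovery, out_dir = dir)
  expect_setequal(rep1$log$selected_features,
                  c("magnitude", "log_energy_entropy", "renyi_entropy"))
  expect_true(all(file.exists(file.path(dir, c("correlations.csv",
                                               "anova_posthoc.csv", "roc.csv")))))
  expect_equal(nrow(rep1$correlations), 11)
  expect_true(all(abs(rep1$correlations$r) <= 1))

  dir2 <- withr::local_tempdir()
  rep2 <- build_report(features, recovery, out_dir = dir2)
  for (f in c("correlations.csv", "anova_posthoc.csv", "roc.csv"))
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))

  expect_error(build_report(features[0, ], recovery[0, ]), "empty feature table")
})
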