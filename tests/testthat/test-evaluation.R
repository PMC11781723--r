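test_that("mean absolute error behaves on elementary cases", {
  expect_equal(bp_mae(c(120, 80), c(120, 80)), 0)
  expect_equal(bp_mae(c(120, 80) + 5, c(120, 80)), 5)
  expect_equal(bp_mae(c(118, 122), c(120, 120)), 2)
})

test_that("Bland-Altman statistics match direct recomputation", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$mean_diff, 0)
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$loa_high, 0)
  ba <- bland_altman(c(100, 110, 120) - 4, c(100, 110, 120))
  expect_equal(ba$mean_diff, 4)

  set.seed(91)
  pred <- rnorm(200, 120, 15); truth <- pred + rnorm(200, 2, 5)
  ba2 <- bland_altman(pred, truth)
  # independent arithmetic oracle
  d <- truth - pred
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  expect_equal(ba2$mean_diff, m, tolerance = 1e-12)
  expect_equal(ba2$loa_low, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba2$loa_high, m + 1.96 * s, tolerance = 1e-12)
})

test_that("intraclass correlation matches a variance-components oracle", {
  set.seed(42)
  truth <- rnorm(80, 120, 15)
  pred <- truth + rnorm(80, 1, 4)
  got <- icc_agreement(pred, truth)

  # brute-force two-way mean squares from explicit sums
  n <- 80; k <- 2
  mat <- cbind(pred, truth)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("intraclass correlation hits its anchors and symmetry", {
  x <- c(100, 110, 125, 140, 90)
  expect_equal(icc_agreement(x, x), 1)
  expect_equal(icc_agreement(x, x + 0), icc_agreement(x + 0, x))
  set.seed(7)
  a <- rnorm(600); b <- rnorm(600)  # statistically independent raters
  expect_lt(abs(icc_agreement(a, b)), 0.15)
  set.seed(8)
  p <- rnorm(50); q <- p + rnorm(50, 0, 0.5)
  expect_equal(icc_agreement(p, q), icc_agreement(q, p), tolerance = 1e-12)
})

test_that("the KS test flags separation and ignores monotone relabelling", {
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  set.seed(17)
  a <- rnorm(200); b <- rnorm(200, 3)
  res <- ks_two_sample(a, b)
  expect_lt(res$p_value, 0.05)
  # a common strictly monotone transform leaves the statistic unchanged
  f <- function(z) exp(z) + z
  expect_equal(ks_two_sample(f(a), f(b))$statistic, res$statistic)
})

test_that("variant comparison reproduces the demographic-vs-fixed separation", {
  coh <- generate_cohort(400, seed = 23)
  par_d <- build_parameters("demographic", demo = coh, geometry = coh$L_cm)
  par_f <- build_parameters("fixed", n = nrow(coh))
  est_d <- estimate_bp(list(ptt_s = coh$ptt_s, ptt_d = coh$ptt_d), par_d)
  est_f <- estimate_bp(list(ptt_s = coh$ptt_s, ptt_d = coh$ptt_d), par_f)
  res <- tibble::tibble(
    country = coh$country, gender = coh$gender,
    sbp_true = coh$true_sbp_mmHg, dbp_true = coh$true_dbp_mmHg,
    sbp_demographic = est_d$sbp_mmHg, dbp_demographic = est_d$dbp_mmHg,
    sbp_fixed = est_f$sbp_mmHg, dbp_fixed = est_f$dbp_mmHg)
  grid <- compare_variants(res)

  all_sbp <- grid[grid$group == "all" & grid$measure == "sbp", ]
  demo_row <- all_sbp[all_sbp$comparison == "demographic_vs_truth", ]
  fixed_row <- all_sbp[all_sbp$comparison == "fixed_vs_truth", ]
  expect_gt(demo_row$ks_p, 0.05)    # fails to reject: matches truth
  expect_lt(fixed_row$ks_p, 0.05)   # rejects: fixed parameters disagree
  expect_lt(demo_row$mae, 1e-6)
  expect_gt(fixed_row$mae, 5)
  # per-country and between-country rows are present
  expect_true("India" %in% grid$group)
  expect_true(any(grepl("between_groups", grid$comparison)))
})

test_that("identical variants collapse to perfect agreement", {
  set.seed(2)
  truth <- rnorm(50, 120, 15)
  res <- tibble::tibble(
    sbp_true = truth, dbp_true = truth - 40,
    sbp_demographic = truth, dbp_demographic = truth - 40,
    sbp_fixed = truth, dbp_fixed = truth - 40)
  grid <- compare_variants(res, group_vars = character(0))
  expect_true(all(grid$group == "all"))
  expect_true(all(grid$mae == 0))
  expect_true(all(grid$ks_p == 1))
})

test_that("plots build without evaluation", {
  set.seed(3)
  pred <- rnorm(30, 120, 10); truth <- pred + rnorm(30)
  p1 <- plot_bland_altman(pred, truth)
  expect_s3_class(p1, "ggplot")
  pair <- generate_ppg_pair(signal_spec(duration_s = 10, seed = 1))
  expect_s3_class(plot_ppg_pair(pair$face, pair$hand), "ggplot")
  expect_s3_class(ggplot2::autoplot(pair$face), "ggplot")
})
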