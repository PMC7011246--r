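test_that("Pearson association matches the closed form and a covariance oracle", {
  x <- 1:10
  r1 <- pearson_assoc(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)

  # t = r * sqrt((n-2) / (1-r^2)): the r = 0.78, n = 16 structure check
  r <- 0.78; n <- 16
  expect_equal(r * sqrt((n - 2) / (1 - r^2)), 4.6638, tolerance = 1e-4)

  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    got <- pearson_assoc(a, b)
    # from-scratch covariance oracle
    r_or <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r_or, tolerance = 1e-12)
    expect_equal(got$t_stat, r_or * sqrt(28 / (1 - r_or^2)), tolerance = 1e-10)
    expect_equal(got$p, 2 * pt(-abs(got$t_stat), 28), tolerance = 1e-12)
  }

  expect_error(pearson_assoc(rep(1, 5), rnorm(5)),
               class = "radiotex_undefined_correlation")
  expect_error(pearson_assoc(1:2, 1:2), class = "radiotex_config_error")
})

test_that("null correlations produce uniform p-values", {
  set.seed(2)
  ps <- purrr::map_dbl(1:400, ~ pearson_assoc(rnorm(20), rnorm(20))$p)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("group comparison: identical groups, raw-vs-summary consistency", {
  v <- c(rnorm(8), rnorm(8))
  g <- rep(c("c", "t"), each = 8)
  same <- group_compare(rep(v[1:8], 2), g)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p, 1)
  expect_equal(same$cohens_d, 0)

  set.seed(3)
  v2 <- rnorm(16, mean = ifelse(g == "c", 0, 1))
  gc <- group_compare(v2, g)
  tt <- t.test(v2[g == "c"], v2[g == "t"], var.equal = TRUE)
  expect_equal(gc$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(gc$p, tt$p.value, tolerance = 1e-12)
  # equal n: the n-weighted and equal-weight pooled SDs coincide
  summ <- cohens_d_from_summary(mean(v2[g == "c"]), sd(v2[g == "c"]),
                                mean(v2[g == "t"]), sd(v2[g == "t"]))
  expect_equal(gc$cohens_d, summ$cohens_d, tolerance = 1e-12)
})

test_that("summary-statistics Cohen's d reproduces the published group contrasts", {
  # printed mean +/- SD pairs with their published absolute effect sizes
  expect_equal(cohens_d_from_summary(19.98, 13.2, -12.10, 5.63)$cohens_d,
               3.162, tolerance = 1e-3)
  expect_equal(cohens_d_from_summary(19.77, 9.84, -10.42, 4.33)$cohens_d,
               3.971, tolerance = 1e-3)
  expect_equal(cohens_d_from_summary(0.06, 0.02, 0.18, 0.08)$cohens_d,
               2.058, tolerance = 1e-3)
  expect_equal(cohens_d_from_summary(0.52, 0.13, 0.30, 0.05)$cohens_d,
               2.233, tolerance = 1e-3)
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$curves$survival, c(2 / 3, 1 / 3, 0))

  # censoring: [1, 2+, 3] -> S(1) = 2/3, S(3) = 0, risk set at 3 is 1
  kmc <- km_estimate(c(1, 2, 3), events = c(TRUE, FALSE, TRUE))
  ev <- kmc$curves[kmc$curves$n_event > 0, ]
  expect_equal(ev$survival[ev$time == 1], 2 / 3)
  expect_equal(ev$survival[ev$time == 3], 0)
  expect_equal(ev$n_risk[ev$time == 3], 1)

  # no censoring: KM equals the empirical survival function
  set.seed(4)
  tm <- sort(sample(1:100, 12))
  km2 <- km_estimate(tm)
  expect_equal(km2$curves$survival,
               1 - seq_along(tm) / length(tm), tolerance = 1e-12)

  two <- km_estimate(rep(c(1, 2, 3), 2), groups = rep(c("a", "b"), each = 3))
  expect_equal(two$logrank_chi2, 0, tolerance = 1e-9)
  expect_equal(two$logrank_p, 1, tolerance = 1e-9)
  expect_s3_class(autoplot(two), "ggplot")
  expect_error(km_estimate(c(0, 1, 2)), class = "radiotex_config_error")
})

test_that("survival screen ranks by |r|, flags p < 0.05, supports BH", {
  set.seed(5)
  n <- 24
  surv <- rnorm(n, 50, 10)
  tbl <- tibble::tibble(
    linked = surv * 0.8 + rnorm(n, sd = 3),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  sc <- feature_survival_screen(tbl, surv)
  expect_equal(sc$feature[1], "linked")
  expect_true(sc$significant[1])
  expect_equal(sc$r, sc$r[order(abs(sc$r), decreasing = TRUE)])
  bh <- feature_survival_screen(tbl, surv, adjust = "BH")
  expect_true("p_adjusted" %in% names(bh))
  expect_true(all(bh$p_adjusted >= bh$p))

  dup <- tibble::tibble(f = rep(2, 8))
  expect_error(feature_survival_screen(dup, rnorm(8)),
               class = "radiotex_undefined_correlation")
})

test_that("screen false-positive rate is nominal under a null target", {
  set.seed(6)
  tbl <- tibble::as_tibble(matrix(rnorm(16 * 50), 16, 50),
                           .name_repair = ~ sprintf("f%02d", 1:50))
  fp <- purrr::map_dbl(1:40, function(i) {
    mean(feature_survival_screen(tbl, rnorm(16))$significant)
  })
  expect_lt(abs(mean(fp) - 0.05), 0.03)
})
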