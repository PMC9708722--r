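test_that("pooled t reproduces the published group statistics from summaries", {
  moca <- t_from_summary(26.38, 1.60, 77, 16.10, 4.93, 79)
  expect_equal(moca$t, 17.42, tolerance = 0.005)
  expect_equal(moca$df, 154)
  fsrp <- t_from_summary(6.69, 3.65, 77, 10.46, 4.30, 79)
  expect_equal(fsrp$t, -5.90, tolerance = 0.01)
  age <- t_from_summary(60.48, 4.51, 77, 61.65, 5.35, 79)
  expect_equal(age$t, -1.47, tolerance = 0.01)
  ident <- t_from_summary(5, 1, 20, 5, 1, 20)
  expect_equal(ident$t, 0)
  expect_error(t_from_summary(1, 0, 10, 2, 0, 10), "zero")
})

test_that("uncorrected Pearson chi-square reproduces the published 2x2 statistics", {
  hyp <- chi2_2x2(56, 23, 32, 45)  # VCI row first: OR of hypertension for VCI
  expect_equal(hyp$chi2, 13.64, tolerance = 0.005)
  expect_equal(hyp$odds_ratio, (56 * 45) / (23 * 32))
  expect_equal(chi2_2x2(32, 45, 56, 23)$odds_ratio, 1 / hyp$odds_ratio)
  expect_equal(chi2_2x2(25, 52, 47, 32)$chi2, 11.46, tolerance = 0.005)
  expect_equal(chi2_2x2(46, 31, 32, 47)$chi2, 5.77, tolerance = 0.005)
  expect_equal(chi2_2x2(22, 55, 35, 44)$chi2, 4.16, tolerance = 0.005)
  expect_equal(chi2_2x2(25, 52, 20, 59)$chi2, 0.97, tolerance = 0.005)

  bal <- chi2_2x2(10, 10, 10, 10)
  expect_equal(bal$chi2, 0)
  expect_equal(bal$odds_ratio, 1)
  expect_error(chi2_2x2(0, 0, 5, 5), "margin")

  # invariance under transposition and joint label swaps
  x <- chi2_2x2(7, 13, 22, 5)
  expect_equal(chi2_2x2(7, 22, 13, 5)$chi2, x$chi2)
  expect_equal(chi2_2x2(5, 22, 13, 7)$chi2, x$chi2)
})

test_that("Mann-Whitney matches a brute-force pair-counting oracle with ties", {
  idt <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idt$Z, 0)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6, 7))
  expect_equal(sep$U, 0)

  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  r <- mann_whitney(x, y)
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(r$U, u_oracle)
  # tie-corrected variance computed independently
  N <- 8; n1 <- 4; n2 <- 4
  tie <- table(rank(c(x, y)))
  var_o <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  expect_equal(r$Z, (u_oracle - n1 * n2 / 2) / sqrt(var_o))

  expect_warning(allt <- mann_whitney(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(allt$Z, 0)
})

test_that("correlations hit their closed forms and a covariance oracle", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, 2 * x + 1)$p, 0)
  expect_equal(correlate(x, rev(x) + stats::rnorm(10, 0, 1e-9), "spearman")$r, -1)
  expect_error(correlate(rep(1, 5), 1:5), "variance")

  co <- simulate_cohort(cohort_params(n = c(NC = 20L, VCI = 20L), seed = 12))
  r <- correlate(co$mean_alps, co$Eg)$r
  cx <- co$mean_alps - mean(co$mean_alps); cy <- co$Eg - mean(co$Eg)
  r_oracle <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)
})

test_that("logistic regression matches the saturated odds ratio and recovers parameters", {
  # expand the hypertension 2x2 into subject-level data
  X <- data.frame(exposed = c(rep(1, 77), rep(0, 79)))
  y <- c(rep(1, 32), rep(0, 45), rep(1, 56), rep(0, 23))
  # exposed group = NC here; OR of NC vs VCI for hypertension
  fit <- logistic_fit(X, y)
  or_closed <- (32 * 23) / (45 * 56)
  expect_equal(fit$OR[fit$term == "exposed"], or_closed, tolerance = 1e-8)

  expect_error(logistic_fit(data.frame(k = rep(1, 20)), rep(c(0, 1), 10)),
               "rank-deficient")
  expect_error(logistic_fit(data.frame(x = c(rep(0, 10), rep(1, 10))),
                            c(rep(0, 10), rep(1, 10))), "separation")

  set.seed(21)
  n <- 5000
  alps <- stats::rnorm(n, 1.875, 0.15)
  eta <- 18.75 - 0.10 * (100 * alps)
  yy <- stats::rbinom(n, 1, stats::plogis(eta))
  f <- logistic_fit(data.frame(alps = alps), yy, percent = "alps")
  est <- f$estimate[f$term == "alps"]
  se <- (log(f$ci_hi) - log(f$OR))[f$term == "alps"] / stats::qnorm(0.975)
  expect_lt(abs(est - (-0.10)), 3 * se)
})

test_that("standardized regression reports correct VIFs", {
  n <- 400
  X <- data.frame(x1 = rep(c(-1, 1), n / 2), x2 = rep(c(-1, 1), each = n / 2))
  y <- stats::rnorm(n)
  f <- linear_fit_standardized(X, y)
  expect_equal(f$VIF, c(1, 1), tolerance = 1e-10)

  expect_error(linear_fit_standardized(data.frame(a = stats::rnorm(20),
                                                  b = 1:20, b2 = 1:20),
                                       stats::rnorm(20)), "collinearity")

  set.seed(33)
  n <- 10000
  x1 <- stats::rnorm(n)
  x2 <- x1 + stats::rnorm(n, 0, sqrt(1 / 3))   # R^2 = 0.75 -> VIF = 4
  f2 <- linear_fit_standardized(data.frame(x1 = x1, x2 = x2),
                                x1 + x2 + stats::rnorm(n))
  expect_equal(f2$VIF[1], 4, tolerance = 0.25)
  expect_equal(f2$VIF[2], 4, tolerance = 0.25)
})

test_that("group comparison table routes tests and detects the ALPS deficit", {
  co <- simulate_cohort(cohort_params(n = c(NC = 2000L, VCI = 2000L), seed = 2))
  tab <- group_compare_table(co)
  expect_lt(tab$p[tab$variable == "mean_alps"], 0.001)
  expect_equal(tab$test[tab$variable == "hypertension"], "chi2")
  expect_equal(tab$test[tab$variable == "lacune"], "mann_whitney")
  one <- co[co$group == "NC", ]
  expect_error(group_compare_table(one), "2 groups")
})

test_that("comparison tests hold their nominal type-I error", {
  rates <- calibrate_type1(n_sims = 500L, seed = 17)
  for (r in rates) {
    expect_gt(r, 0.025)
    expect_lt(r, 0.08)
  }
})
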