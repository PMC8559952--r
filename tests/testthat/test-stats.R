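test_that("signed-rank exact path matches full enumeration", {
  # all-positive n = 8, one-tailed: only the extreme assignment is as large
  x <- c(1.2, 0.8, 2.1, 0.4, 1.7, 0.9, 1.1, 0.5)
  res <- wilcoxon_signed(x, alternative = "greater", ci_reps = 0, bf = FALSE)
  expect_equal(res$p_value, 1 / 2^8)
  expect_equal(res$effect, 1)  # every rank positive
  # random small samples against the 2^n oracle, both tails
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    y <- rnorm(n, 0.3)  # continuous: tie-free, the exact path applies
    for (alt in c("greater", "less", "two.sided")) {
      got <- wilcoxon_signed(y, alternative = alt, ci_reps = 0,
                             bf = FALSE)$p_value
      expect_equal(got, enum_wilcoxon_p(y, alt), tolerance = 1e-12)
    }
  }
  # symmetric pairs: two-tailed p = 1
  sym <- c(-2, 2, -1, 1, -3, 3)
  expect_equal(wilcoxon_signed(sym, alternative = "two.sided", ci_reps = 0,
                               bf = FALSE)$p_value, 1)
})

test_that("signed-rank effect-size CI covers the analytic rank-biserial", {
  # population matched rank-biserial under a N(delta, 1) shift via Walsh
  # pair probabilities
  delta <- 0.3; n <- 60
  p1 <- pnorm(delta); p2 <- pnorm(delta * sqrt(2))
  et_pos <- n * p1 + n * (n - 1) / 2 * p2
  r_true <- 2 * et_pos / (n * (n + 1) / 2) - 1
  set.seed(8)
  cover <- vapply(1:400, function(i) {
    x <- rnorm(n, delta)
    ci <- wilcoxon_signed(x, ci_reps = 400, bf = FALSE,
                          seed = i)$effect_ci
    ci[1] <= r_true && r_true <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("Kruskal-Wallis H matches hand rank arithmetic and is label-invariant", {
  vals <- c(2.1, 3.4, 1.2, 5.6, 7.8, 2.2, 9.1, 4.4, 0.3, 6.6, 8.8, 1.1)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- kruskal_with_posthoc(vals, g, ci_reps = 0)
  # textbook formula, no ties
  rk <- rank(vals); n <- 12
  h <- 12 / (n * (n + 1)) * sum(tapply(rk, g, sum)^2 / 4) - 3 * (n + 1)
  expect_equal(unname(res$statistic), h, tolerance = 1e-12)
  expect_equal(res$effect, h / (n - 1))
  # relabelling equal-sized groups leaves H unchanged
  relab <- c(a = "b", b = "c", c = "a")[g]
  expect_equal(unname(kruskal_with_posthoc(vals, relab,
                                           ci_reps = 0)$statistic),
               unname(res$statistic), tolerance = 1e-12)
  # a hugely shifted group is detected
  set.seed(3)
  shifted <- c(rnorm(30), rnorm(30), rnorm(30, 100))
  gg <- rep(1:3, each = 30)
  big <- kruskal_with_posthoc(shifted, gg, ci_reps = 0)
  expect_lt(big$p_value, 0.001)
  expect_equal(nrow(big$posthoc), 3)
  expect_true(all(big$posthoc$p_adj >= big$posthoc$p - 1e-15))
})

test_that("Spearman association handles monotone and tied data", {
  x <- 1:20
  expect_equal(spearman_assoc(x, x + 3, ci_reps = 0)$effect, 1)
  expect_equal(spearman_assoc(x, -2 * x, ci_reps = 0)$effect, -1)
  # ties: against explicit average-rank computation
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  expect_equal(spearman_assoc(xt, yt, ci_reps = 0)$effect,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ci <- spearman_assoc(rnorm(40), rnorm(40), ci_reps = 300, seed = 2)$effect_ci
  expect_true(ci[1] <= ci[2])
})

test_that("Spearman bootstrap CI covers the bivariate-normal truth", {
  rho <- 0.5
  rho_s <- 6 / pi * asin(rho / 2)
  set.seed(5)
  cover <- vapply(1:400, function(i) {
    x <- rnorm(60)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(60)
    ci <- spearman_assoc(x, y, ci_reps = 400, seed = i)$effect_ci
    ci[1] <= rho_s && rho_s <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("Huber regression resists outliers and reduces to least squares", {
  set.seed(10)
  x <- seq(0, 1, length.out = 50)
  # exact linear, noise-free
  d0 <- data.frame(x = x, y = 2 + 3 * x)
  r0 <- robust_linreg(y ~ x, d0)
  expect_equal(unname(r0$coefficients$estimate), c(2, 3), tolerance = 1e-8)
  # one gross outlier: closer to truth than OLS
  y <- 2 + 3 * x + rnorm(50, 0, 0.2)
  y[25] <- 40
  dc <- data.frame(x = x, y = y)
  rob <- robust_linreg(y ~ x, dc)
  ols <- lm(y ~ x, dc)
  expect_lt(abs(rob$coefficients$estimate[2] - 3),
            abs(coef(ols)[2] - 3))
  # clean Gaussian data: matches least squares closely
  d1 <- data.frame(x = x, y = 2 + 3 * x + rnorm(50, 0, 0.1))
  r1 <- robust_linreg(y ~ x, d1)
  expect_equal(unname(r1$coefficients$estimate), unname(coef(lm(y ~ x, d1))),
               tolerance = 1e-2)
  # nested deviance test detects a real slope and respects df
  dt <- robust_linreg(y ~ x, d1, y ~ 1)$deviance_test
  expect_lt(dt$p_value, 0.001)
  expect_equal(dt$df, 1)
})

test_that("JZS Bayes factor behaves like a Bayes factor", {
  # t = 0: null favoured
  expect_lt(jzs_bf_t(0, 30)$bf, 1)
  # monotone in |t|
  bfs <- vapply(seq(0, 5, 0.5), function(t) jzs_bf_t(t, 25)$bf, 0)
  expect_true(all(diff(bfs) > 0))
  # matches an independent fine-grid trapezoid integration
  set.seed(6)
  for (rep in 1:20) {
    t <- runif(1, -4, 4); n <- sample(10:80, 1); r <- runif(1, 0.3, 2)
    got <- jzs_bf_t(t, n, rscale = r)$bf
    delta <- seq(-12 * r, 12 * r, length.out = 40001)
    f <- suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r)
    trap <- sum((f[-1] + f[-length(f)]) / 2 * diff(delta)) / dt(t, n - 1)
    expect_lt(abs(got - trap) / trap, 1e-4)
  }
  # directional version splits the two-sided prior
  x <- rnorm(30, 0.5)
  two <- jzs_bayes_factor(x)$bf
  gt <- jzs_bayes_factor(x, alternative = "greater")$bf
  lt <- jzs_bayes_factor(x, alternative = "less")$bf
  expect_equal((gt + lt) / 2, two, tolerance = 1e-6)
})

test_that("power analysis finds the smallest adequate sample", {
  expect_equal(required_sample_size(0.35, 0.05, 0.95, "one_sample", "one"),
               90)
  # floor of 2 for huge effects; just above the floor the search is minimal
  expect_equal(required_sample_size(20, 0.05, 0.95, "one_sample", "one"), 2)
  expect_equal(required_sample_size(5, 0.05, 0.95, "one_sample", "one"), 3)
  # two-sample result agrees with the base-R power routine
  n2 <- required_sample_size(0.35, 0.05, 0.95, "two_sample", "two")
  ref <- ceiling(power.t.test(delta = 0.35, sd = 1, sig.level = 0.05,
                              power = 0.95, type = "two.sample")$n)
  expect_lte(abs(n2 - ref), 1)
  # and with the normal approximation within the expected slack
  approx_n <- 2 * ((qnorm(0.975) + qnorm(0.95)) / 0.35)^2
  expect_lte(abs(n2 - approx_n), 2.5)
  # the returned n achieves the power and n - 1 does not
  ach <- function(n) {
    crit <- qt(1 - 0.05, n - 1)
    pt(crit, n - 1, 0.35 * sqrt(n), lower.tail = FALSE)
  }
  expect_gte(ach(90), 0.95)
  expect_lt(ach(89), 0.95)
})

test_that("norm battery flags constructed differences and not identical data", {
  probes <- norm_probes(12)
  n_per <- 20
  # identical rating vectors in both groups: nothing significant
  r0 <- simulate_norm_ratings(1, probes, 0, 1)
  bat0 <- norm_rating_battery(rep(r0, 2 * n_per),
                              rep(c("pro", "anti"), each = n_per * 12),
                              rep(1:12, 2 * n_per))
  expect_true(all(bat0$p_adj == 1))
  # zero-noise opposite groups: everything significant before correction
  r_pro <- unlist(lapply(1:n_per, function(i)
    simulate_norm_ratings(1, probes, 0, i)))
  r_anti <- unlist(lapply(1:n_per, function(i)
    simulate_norm_ratings(-1, probes, 0, i)))
  # Bayes factors need within-group variation: add ordinal noise
  rn_pro <- unlist(lapply(1:n_per, function(i)
    simulate_norm_ratings(1, probes, 0.5, 1000 + i)))
  rn_anti <- unlist(lapply(1:n_per, function(i)
    simulate_norm_ratings(-1, probes, 0.5, 2000 + i)))
  ratings <- c(r_pro, r_anti)
  grp <- rep(c("pro", "anti"), each = n_per * 12)
  alc <- rep(rep(1:12, n_per), 2)
  bat <- norm_rating_battery(ratings, grp, alc)
  informative <- tapply(ratings, alc, function(v) length(unique(v)) > 1)
  expect_true(all(bat$p[informative] < 0.05))
  batn <- norm_rating_battery(c(rn_pro, rn_anti), grp, alc)
  expect_gt(attr(batn, "n_favour_alt"), attr(batn, "n_favour_null"))
})
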