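new_test_result <- function(test, statistic, p_value, alternative, n,
                            effect_name = NULL, effect = NULL,
                            effect_ci = c(NA, NA), bf = NULL, extra = list()) {
  out <- c(list(test = test, statistic = statistic, p_value = p_value,
                alternative = alternative, n = n,
                effect_name = effect_name, effect = effect,
                effect_ci = effect_ci, bf = bf), extra)
  class(out) <- "svo_test"
  out
}

#' @export
print.svo_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (%s), n = %s\n", x$test,
              names(x$statistic)[1], x$statistic[1], x$p_value,
              x$alternative, paste(x$n, collapse = "/")))
  if (!is.null(x$effect))
    cat(sprintf("  %s = %.3f [%.3f, %.3f]\n", x$effect_name, x$effect,
                x$effect_ci[1], x$effect_ci[2]))
  if (!is.null(x$bf)) cat(sprintf("  BF10 = %.4g\n", x$bf))
  invisible(x)
}

percentile_ci <- function(stats, level = 0.95) {
  stats <- stats[is.finite(stats)]
  if (length(stats) < 10) return(c(NA_real_, NA_real_))
  stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}

rank_biserial_signed <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(NA_real_)
  rk <- rank(abs(x))
  2 * sum(rk[x > 0]) / sum(rk) - 1
}

#' One-sample Wilcoxon signed-rank test with effect size
#'
#' Exact p-value for n <= 25 after dropping zeros (falls back to the normal
#' approximation when ties in absolute values preclude the exact
#' distribution), otherwise the normal approximation with continuity
#' correction. Reports the matched rank-biserial correlation with a seeded
#' percentile-bootstrap CI, the natural log of the signed-rank statistic V
#' (the reporting convention for this test), and, when requested, a JZS
#' Bayes factor over the same contrast.
#'
#' @param values numeric sample.
#' @param mu0 null location (default 0).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param ci_reps bootstrap replicates for the effect-size CI (0 skips it).
#' @param bf also compute the JZS Bayes factor.
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @param seed seed for the bootstrap.
#' @return an `svo_test` result.
#' @export
wilcoxon_signed <- function(values, mu0 = 0,
                            alternative = c("greater", "less", "two.sided"),
                            ci_reps = 2000, bf = TRUE,
                            rscale = sqrt(2) / 2, seed = 1L) {
  alternative <- match.arg(alternative)
  x <- values - mu0
  nz <- x[x != 0]
  n <- length(nz)
  stopifnot(n >= 5)
  wt <- suppressWarnings(stats::wilcox.test(
    x, alternative = alternative, exact = n <= 25, correct = TRUE))
  r <- rank_biserial_signed(x)
  ci <- c(NA_real_, NA_real_)
  if (ci_reps > 0) {
    boots <- withr_seed(seed, vapply(seq_len(ci_reps), function(b)
      rank_biserial_signed(sample(x, replace = TRUE)), 0))
    ci <- percentile_ci(boots)
  }
  bf10 <- if (bf) jzs_bayes_factor(values, mu0 = mu0, rscale = rscale,
                                   alternative = alternative)$bf
          else NULL
  new_test_result("Wilcoxon signed-rank", c(V = unname(wt$statistic)),
                  wt$p.value, alternative, n,
                  "rank-biserial r", r, ci, bf10,
                  extra = list(log_V = log(unname(wt$statistic))))
}

kw_epsilon_sq <- function(h, n) h / (n - 1)

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected H statistic with chi-square p-value and the epsilon-squared
#' effect size (H / (n - 1)) with a stratified-bootstrap CI, followed by
#' Dunn-type pairwise z tests on mean ranks with a multiplicity correction.
#'
#' @param values numeric responses.
#' @param groups group labels (coerced to factor, >= 2 levels, each n >= 3).
#' @param correction method for [stats::p.adjust()] (default `"holm"`).
#' @param ci_reps bootstrap replicates for the effect-size CI (0 skips).
#' @param seed bootstrap seed.
#' @return an `svo_test` with an extra `posthoc` data frame (pairwise z,
#'   raw and adjusted p).
#' @export
kruskal_with_posthoc <- function(values, groups, correction = "holm",
                                 ci_reps = 2000, seed = 1L) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 3))
  kt <- stats::kruskal.test(values, groups)
  n <- length(values)
  eps2 <- kw_epsilon_sq(unname(kt$statistic), n)
  ci <- c(NA_real_, NA_real_)
  if (ci_reps > 0) {
    idx_by_g <- split(seq_along(values), groups)
    boots <- withr_seed(seed, vapply(seq_len(ci_reps), function(b) {
      take <- unlist(lapply(idx_by_g, function(ix)
        sample(ix, replace = TRUE)), use.names = FALSE)
      kw_epsilon_sq(unname(stats::kruskal.test(values[take],
                                               groups[take])$statistic), n)
    }, 0))
    ci <- percentile_ci(boots)
  }
  # Dunn z tests on mean ranks with tie correction
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- sum(groups == a); nb <- sum(groups == b)
    z <- (mean(rk[groups == a]) - mean(rk[groups == b])) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  ph$p_adj <- stats::p.adjust(ph$p, method = correction)
  new_test_result("Kruskal-Wallis", c(chi_squared = unname(kt$statistic)),
                  kt$p.value, "two.sided", n, "epsilon squared", eps2, ci,
                  extra = list(df = unname(kt$parameter), posthoc = ph,
                               correction = correction))
}

#' Spearman rank correlation with bootstrap CI
#'
#' Tie-aware rho (average ranks) with the p-value from
#' [stats::cor.test()] and a seeded pairs-bootstrap percentile CI.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @param alternative passed to [stats::cor.test()].
#' @param ci_reps bootstrap replicates (0 skips).
#' @param seed bootstrap seed.
#' @export
spearman_assoc <- function(x, y, alternative = "two.sided", ci_reps = 2000,
                           seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = alternative))
  ci <- c(NA_real_, NA_real_)
  if (ci_reps > 0) {
    n <- length(x)
    boots <- withr_seed(seed, vapply(seq_len(ci_reps), function(b) {
      ix <- sample.int(n, replace = TRUE)
      stats::cor(x[ix], y[ix], method = "spearman")
    }, 0))
    ci <- percentile_ci(boots)
  }
  new_test_result("Spearman rank correlation",
                  c(rho = unname(ct$estimate)), ct$p.value, alternative,
                  length(x), "rho", unname(ct$estimate), ci)
}

huber_rho <- function(u, k) ifelse(abs(u) <= k, u^2 / 2, k * abs(u) - k^2 / 2)
huber_psi <- function(u, k) pmax(pmin(u, k), -k)

#' Robust (Huber M-estimation) linear regression with a nested-model test
#'
#' Iteratively reweighted Huber regression (tuning constant 1.345, 95%
#' Gaussian efficiency) via [MASS::rlm()], with per-coefficient t tests and,
#' when a nested null formula is supplied, a robust quasi-likelihood-ratio
#' (tau) test: `2 * (sum rho_0 - sum rho_1)` rescaled by `mean(psi') /
#' mean(psi^2)` at the full-model residuals, referred (divided by the
#' parameter-count difference q) to an F(q, n - p) distribution, the
#' small-sample reference that the Gaussian likelihood-ratio test reduces
#' to.
#'
#' @param formula model formula for the full model.
#' @param data data frame.
#' @param null_formula optional nested formula for the deviance comparison.
#' @param k Huber tuning constant.
#' @return list of class `svo_robust_fit`: `fit` (the `rlm` object),
#'   `coefficients` table (estimate, se, t, p, 95% CI), `adj_r_squared`, and
#'   `deviance_test` (an `svo_test`) when `null_formula` is given.
#' @export
robust_linreg <- function(formula, data, null_formula = NULL, k = 1.345) {
  fit <- MASS::rlm(formula, data = data, psi = MASS::psi.huber, k = k,
                   maxit = 200)
  n <- length(fit$residuals)
  p <- length(stats::coef(fit))
  sm <- summary(fit)$coefficients
  tval <- sm[, "t value"]
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  crit <- stats::qt(0.975, n - p)
  coefs <- data.frame(estimate = sm[, "Value"], se = sm[, "Std. Error"],
                      t = tval, p = pval,
                      lower = sm[, "Value"] - crit * sm[, "Std. Error"],
                      upper = sm[, "Value"] + crit * sm[, "Std. Error"])
  w <- fit$w
  y <- fit$residuals + fit$fitted.values
  r2 <- 1 - sum(w * fit$residuals^2) /
    sum(w * (y - stats::weighted.mean(y, w))^2)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  dev_test <- NULL
  if (!is.null(null_formula)) {
    fit0 <- MASS::rlm(null_formula, data = data, psi = MASS::psi.huber,
                      k = k, maxit = 200)
    p0 <- length(stats::coef(fit0))
    stopifnot(p > p0)
    s <- fit$s
    u1 <- fit$residuals / s
    u0 <- fit0$residuals / s
    lam <- mean(huber_psi(u1, k)^2) / mean(abs(u1) <= k)
    stat <- 2 * (sum(huber_rho(u0, k)) - sum(huber_rho(u1, k))) / lam
    stat <- max(stat, 0)
    q <- p - p0
    dev_test <- new_test_result(
      "robust nested-model deviance", c(deviance = stat),
      stats::pf(stat / q, q, n - p, lower.tail = FALSE), "two.sided", n,
      extra = list(df = q, df_resid = n - p))
  }
  structure(list(fit = fit, coefficients = coefs, adj_r_squared = adj_r2,
                 deviance_test = dev_test, n = n),
            class = "svo_robust_fit")
}

#' @export
print.svo_robust_fit <- function(x, ...) {
  cat("Robust (Huber) linear regression, n =", x$n, "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("adjusted R^2 = %.3f\n", x$adj_r_squared))
  if (!is.null(x$deviance_test)) print(x$deviance_test)
  invisible(x)
}

#' JZS Bayes factor from a t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor for a one- or two-sample t contrast:
#' the alternative places a Cauchy prior (scale `rscale`) on the
#' standardised effect size, and the Bayes factor is the ratio of the
#' marginal likelihood of the observed t (non-central t integrated over the
#' prior by adaptive quadrature) to its density under the null. Directional
#' alternatives use the half-Cauchy on the corresponding side.
#'
#' @param t observed t statistic.
#' @param n1 sample size (first sample).
#' @param n2 second sample size (NULL for one-sample/paired).
#' @param rscale Cauchy prior scale (default sqrt(2)/2, "medium").
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (direction of
#'   the effect under H1).
#' @return list with `bf` (BF of the alternative over the null) and
#'   `error` (quadrature error estimate).
#' @export
jzs_bf_t <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(n2)) {
    neff <- n1; nu <- n1 - 1
  } else {
    neff <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  }
  stopifnot(nu >= 2, rscale > 0)
  integrand <- function(delta)
    suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(neff))) *
      stats::dcauchy(delta, 0, rscale)
  null_dens <- stats::dt(t, nu)
  lims <- switch(alternative,
                 two.sided = c(-Inf, Inf),
                 greater = c(0, Inf),
                 less = c(-Inf, 0))
  scale_prior <- if (alternative == "two.sided") 1 else 2
  q <- stats::integrate(integrand, lims[1], lims[2], rel.tol = 1e-8,
                        stop.on.error = FALSE)
  list(bf = scale_prior * q$value / null_dens,
       error = scale_prior * q$abs.error / null_dens)
}

#' JZS Bayes factor for a sample or a pair of samples
#'
#' Computes the t statistic from the data and delegates to [jzs_bf_t()].
#'
#' @param x numeric sample (or within-pair differences).
#' @param y optional second sample for the independent two-sample case.
#' @param mu0 null value for the one-sample case.
#' @param rscale Cauchy prior scale; the norm-rating comparisons use the
#'   wide prior `rscale = 2`.
#' @param alternative direction of the effect under the alternative.
#' @export
jzs_bayes_factor <- function(x, y = NULL, mu0 = 0, rscale = sqrt(2) / 2,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (is.null(y)) {
    n1 <- length(x)
    t <- (mean(x) - mu0) / (stats::sd(x) / sqrt(n1))
    jzs_bf_t(t, n1, NULL, rscale, alternative)
  } else {
    n1 <- length(x); n2 <- length(y)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    t <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
    jzs_bf_t(t, n1, n2, rscale, alternative)
  }
}

#' Sample size for a target power under the noncentral t distribution
#'
#' Smallest integer n (per group for the two-sample test) whose achieved
#' power meets the target, with a floor of n = 2.
#'
#' @param effect_d Cohen's d (> 0).
#' @param alpha type-I rate.
#' @param power target power.
#' @param test `"one_sample"` or `"two_sample"`.
#' @param tails `"one"` or `"two"`.
#' @export
required_sample_size <- function(effect_d, alpha = 0.05, power = 0.95,
                                 test = c("one_sample", "two_sample"),
                                 tails = c("one", "two")) {
  test <- match.arg(test); tails <- match.arg(tails)
  stopifnot(effect_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  ach <- function(n) {
    if (test == "one_sample") {
      df <- n - 1; ncp <- effect_d * sqrt(n)
    } else {
      df <- 2 * n - 2; ncp <- effect_d * sqrt(n / 2)
    }
    a <- if (tails == "one") alpha else alpha / 2
    crit <- stats::qt(1 - a, df)
    pw <- stats::pt(crit, df, ncp, lower.tail = FALSE)
    if (tails == "two")
      pw <- pw + stats::pt(-crit, df, ncp)
    pw
  }
  n <- 2
  while (ach(n) < power) n <- n + 1
  n
}

#' Per-allocation norm-rating comparisons
#'
#' Runs one Kruskal-Wallis test per probed allocation comparing rating
#' distributions across groups, applies a family-wise correction across
#' allocations, and (for two groups) a JZS Bayes factor with a wide Cauchy
#' prior. Summarises how many tests favour the null (BF < 1) and the
#' alternative.
#'
#' @param ratings integer ratings 1-4.
#' @param groups group label per rating.
#' @param allocation allocation id per rating.
#' @param correction family-wise correction across allocations.
#' @param rscale Cauchy prior scale for the Bayes factors (default 2, the
#'   wide prior).
#' @return data frame of class `svo_norm_battery`, one row per allocation
#'   (`chi_squared`, `p`, `p_adj`, `bf`), with summary counts in
#'   attributes.
#' @export
norm_rating_battery <- function(ratings, groups, allocation,
                                correction = "holm", rscale = 2) {
  stopifnot(all(ratings %in% 1:4))
  groups <- factor(groups)
  allocation <- factor(allocation)
  rows <- do.call(rbind, lapply(levels(allocation), function(a) {
    sel <- allocation == a
    r <- ratings[sel]; g <- droplevels(groups[sel])
    kt <- if (length(unique(r)) == 1)  # constant ratings carry no signal
      list(statistic = c(chi = 0), parameter = c(df = nlevels(g) - 1),
           p.value = 1)
    else stats::kruskal.test(r, g)
    bf <- if (nlevels(g) == 2) {
      sp <- split(r, g)
      if (stats::sd(sp[[1]]) == 0 && stats::sd(sp[[2]]) == 0) NA_real_
      else jzs_bayes_factor(sp[[1]], sp[[2]], rscale = rscale)$bf
    } else NA_real_
    data.frame(allocation = a, chi_squared = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value, bf = bf)
  }))
  rows$p_adj <- pmin(stats::p.adjust(rows$p, method = correction), 1)
  attr(rows, "n_favour_null") <- sum(rows$bf < 1, na.rm = TRUE)
  attr(rows, "n_favour_alt") <- sum(rows$bf >= 1, na.rm = TRUE)
  attr(rows, "n_significant_adj") <- sum(rows$p_adj < 0.05)
  class(rows) <- c("svo_norm_battery", "data.frame")
  rows
}

#' @export
print.svo_norm_battery <- function(x, ...) {
  cat("Norm-rating battery:", nrow(x), "allocations\n")
  print.data.frame(cbind(data.frame(x)["allocation"],
                         round(data.frame(x)[c("chi_squared", "p", "p_adj",
                                               "bf")], 4)))
  cat(sprintf("significant after correction: %d; BF favouring null: %d/%d\n",
              attr(x, "n_significant_adj"), attr(x, "n_favour_null"),
              attr(x, "n_favour_null") + attr(x, "n_favour_alt")))
  invisible(x)
}
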