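test_that("utility and default value follow the SVO exchange rate", {
  expect_equal(utility(100, 50, 0), 100)
  expect_equal(utility(50, 100, 45), 150)
  # at 30 degrees one other-point is worth ~0.58 own points
  expect_equal(round(utility(0, 1, 30), 2), 0.58)
  expect_equal(default_value(0, 0), 100)
  expect_equal(default_value(45, 0), 150)
  expect_equal(default_value(0, 10), 90)
  expect_error(utility(10, 10, 90), "within")
  expect_error(default_value(-95), "within")
})

test_that("threshold attitude equalises default and alternative values", {
  expect_equal(threshold_alpha(50, 100, 0), 45)
  expect_equal(threshold_alpha(50, 0, 0), -45)
  expect_equal(threshold_alpha(50, 100, 10), atan(-40 / -50) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(round(threshold_alpha(50, 100, 10), 2), 38.66)
  expect_error(threshold_alpha(105, 50), "undefined|attitude-independent")
  # V_A(T) == V_D(T) across the whole generated set, with and without bias
  alls <- generate_allocation_set()
  for (kap in c(0, 7)) {
    ta <- threshold_alpha(alls$pi_self, alls$pi_other, kap)
    va <- alls$pi_self + tan(ta * pi / 180) * alls$pi_other
    vd <- 100 + tan(ta * pi / 180) * 50 - kap
    expect_lt(max(abs(va - vd)), 1e-9)
  }
})

test_that("stable-family choice probabilities follow the softmax rule", {
  expect_equal(p_default_stable(50, 100, 45, 25, 0), 0.5)
  expect_equal(p_default_stable(50, 100, 0, 25, 0), plogis(50 / 25))
  expect_equal(round(p_default_stable(50, 100, 0, 25, 0), 4), 0.8808)
  expect_equal(p_default_stable(50, 100, 0, 1e-9, 0), 1)  # step limit
  # degenerate trial: attitude cancels exactly
  expect_equal(p_default_stable(105, 50, 10, 20, 0),
               p_default_stable(105, 50, -60, 20, 0))
})

test_that("variable-family probabilities equal the attitude mass rule", {
  # centred threshold
  expect_equal(p_default_variable(50, 100, 45, 14, 0), 0.5)
  p <- p_default_variable(50, 100, 20, 14, 0)
  expect_equal(p, pnorm(25 / 14))
  expect_equal(round(p, 4), 0.9629)
  # degenerate trials: 0/1 step of the self-payoff advantage
  expect_equal(p_default_variable(105, 50, 20, 14, 0), 0)
  expect_equal(p_default_variable(105, 50, 20, 14, -10), 1)
  expect_equal(p_default_variable(105, 50, 20, 14, -5), 0.5)
})

test_that("variable-family probability matches Monte-Carlo attitude sampling", {
  trials <- ring_trials(8)
  set.seed(31)
  for (i in seq_len(nrow(trials))) {
    mu <- runif(1, -40, 40); sig <- runif(1, 3, 20); kap <- runif(1, -5, 10)
    p <- p_default_variable(trials$pi_self[i], trials$pi_other[i], mu, sig,
                            kap)
    a <- rnorm(1e5, mu, sig)
    ta <- threshold_alpha(trials$pi_self[i], trials$pi_other[i], kap)
    p_mc <- if (trials$pi_other[i] > 50) mean(a <= ta) else mean(a >= ta)
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(p - p_mc), 3 * se + 1e-12)
  }
})

test_that("lapse mixing shrinks probabilities towards one half", {
  expect_equal(apply_lapse(0.9, 0.1), 0.86)
  expect_equal(apply_lapse(0.37, 0), 0.37)
  expect_equal(apply_lapse(0.9, 1), 0.5)
  p <- seq(0, 1, 0.1)
  expect_true(all(apply_lapse(p, 0.2) >= 0.1 & apply_lapse(p, 0.2) <= 0.9))
  expect_error(apply_lapse(1.2, 0.1))
})

test_that("choice probabilities are monotone in attitude and bias", {
  mus <- seq(-60, 60, 5)
  p_pro <- p_default_variable(55, 95, mus, 20, 0)
  p_anti <- p_default_variable(55, 5, mus, 20, 0)
  expect_true(all(diff(p_pro) < 0))   # prosocial trial: higher mu, less default
  expect_true(all(diff(p_anti) > 0))
  kaps <- seq(-10, 20, 2)
  for (fam in c("stable", "variable")) {
    f <- if (fam == "stable") p_default_stable else p_default_variable
    expect_true(all(diff(f(rep(55, length(kaps)), 95, 10, 8, kaps)) <= 0))
    expect_true(all(diff(f(rep(55, length(kaps)), 5, 10, 8, kaps)) <= 0))
  }
})

test_that("log-likelihood equals per-trial scalar recomputation", {
  trials <- ring_trials(40)
  set.seed(7)
  for (fam in c("stable", "variable")) {
    pb <- list(attitude = runif(1, -40, 40), variability = runif(1, 4, 25),
               bias_kappa = runif(1, -5, 10),
               lapse_epsilon = runif(1, 0, 0.3))
    pa <- list(attitude = runif(1, -40, 40), variability = runif(1, 4, 25),
               bias_kappa = runif(1, -5, 10),
               lapse_epsilon = runif(1, 0, 0.3))
    rec <- sim_subject_records(pb, pa, trials, fam, seed = 5)
    ll <- log_likelihood(rec, list(before = pb, after = pa),
                         model_spec(fam, "full"))
    # independent scalar recomputation
    brute <- 0
    for (r in seq_len(nrow(rec))) {
      p <- if (rec$phase[r] == "before") pb else pa
      t_alpha <- tan(p$attitude * pi / 180)
      vd <- 100 + t_alpha * 50 - p$bias_kappa
      va <- rec$pi_self[r] + t_alpha * rec$pi_other[r]
      pd <- if (fam == "stable") {
        1 / (1 + exp(-(vd - va) / p$variability))
      } else if (rec$pi_other[r] == 50) {
        adv <- rec$pi_self[r] - 100 + p$bias_kappa
        if (adv > 0) 0 else if (adv < 0) 1 else 0.5
      } else {
        ta <- atan((rec$pi_self[r] - 100 + p$bias_kappa) /
                     (50 - rec$pi_other[r])) * 180 / pi
        z <- (ta - p$attitude) / p$variability
        pnorm(if (rec$pi_other[r] > 50) z else -z)
      }
      pd <- (1 - p$lapse_epsilon) * pd + p$lapse_epsilon / 2
      brute <- brute + log(if (rec$choice[r] == 0) pd else 1 - pd)
    }
    expect_equal(ll, brute, tolerance = 1e-12)
  }
})

test_that("log-likelihood honours lapse-only, missing and tied-scheme contracts", {
  trials <- ring_trials(30)
  p1 <- list(attitude = 10, variability = 8, bias_kappa = 0,
             lapse_epsilon = 1)
  rec <- sim_subject_records(p1, p1, trials, seed = 2)
  expect_equal(log_likelihood(rec, list(before = p1, after = p1)),
               nrow(rec) * log(0.5))
  rec_na <- rec
  rec_na$choice <- NA
  expect_warning(ll0 <- log_likelihood(rec_na, list(before = p1, after = p1)),
                 "no non-missing")
  expect_equal(ll0, 0)
  # partial missing: missing rows contribute nothing
  rec_mix <- rec
  rec_mix$choice[1:10] <- NA
  expect_equal(log_likelihood(rec_mix, list(before = p1, after = p1)),
               (nrow(rec) - 10) * log(0.5))
  # tied attitude must actually be tied
  p2 <- within(p1, attitude <- 20)
  expect_error(log_likelihood(rec, list(before = p1, after = p2),
                              model_spec("variable", "shared_attitude")),
               "ties")
})
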