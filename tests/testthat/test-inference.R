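fake_fit <- function(draws_vec) {
  # minimal svo_fit shell around a single marginal, for MAP extraction
  k <- length(draws_vec)
  draws <- array(draws_vec, c(k, 8, 1, 1),
                 dimnames = list(NULL, c("attitude_before", "attitude_after",
                                         "variability_before",
                                         "variability_after", "kappa_before",
                                         "kappa_after", "epsilon_before",
                                         "epsilon_after"), "s1", NULL))
  structure(list(draws = draws, participants = "s1",
                 spec = model_spec("variable", "full")),
            class = "svo_fit")
}

test_that("MAP is the kernel-density mode of the marginal", {
  expect_equal(map_estimate(fake_fit(rep(3.7, 100)), "attitude", 1), 3.7)
  set.seed(4)
  expect_lt(abs(map_estimate(fake_fit(rnorm(1e4, 10, 1)), "attitude", 1) -
                  10), 0.2)
  bim <- c(rnorm(6000, -5, 0.8), rnorm(4000, 5, 0.8))
  expect_lt(abs(map_estimate(fake_fit(bim), "attitude", 1) - (-5)), 1)
})

test_that("DIC follows the Spiegelhalter decomposition", {
  d0 <- dic_from_deviance(rep(123.4, 50), 123.4)
  expect_equal(d0$dic, 123.4)
  expect_equal(d0$p_d, 0)
  dev <- c(100, 104, 98, 102, 101)
  plug <- 97.5
  d <- dic_from_deviance(dev, plug)
  expect_equal(d$mean_deviance, 101)
  expect_equal(d$p_d, 101 - 97.5)
  expect_equal(d$dic, 101 + 3.5)
  shifted <- dic_from_deviance(dev + 10, plug + 10)
  expect_equal(shifted$dic, d$dic + 10)
})

test_that("fitting recovers a single subject's parameters", {
  p <- list(attitude = 30, variability = 5, bias_kappa = 0,
            lapse_epsilon = 0.02)
  rec <- sim_subject_records(p, p, ring_trials(100), seed = 11)
  fit <- suppressWarnings(fit_attitude_model(
    rec, mcmc = mcmc_control(chains = 2, iterations = 1500, burn_in = 400,
                             seed = 3)))
  expect_lt(abs(map_estimate(fit, "attitude", 1, "before") - 30), 4)
  expect_lt(abs(map_estimate(fit, "attitude", 1, "after") - 30), 4)
  # draw-count contract
  expect_equal(dim(fit$draws)[1], (1500 - 400) / 1)
  expect_equal(dim(fit$draws)[4], 2)
  # doubling iterations under the same seed family barely moves the MAP
  fit2 <- suppressWarnings(fit_attitude_model(
    rec, mcmc = mcmc_control(chains = 2, iterations = 3000, burn_in = 400,
                             seed = 3)))
  expect_lt(abs(map_estimate(fit, "attitude", 1, "before") -
                  map_estimate(fit2, "attitude", 1, "before")), 1)
})

test_that("with no attitude information the posterior returns the prior", {
  deg <- data.frame(pi_self = rep(c(101, 105, 108), 20), pi_other = 50,
                    choice = rep(c(1L, 1L, 0L), 20))
  rec <- rbind(cbind(deg, phase = "before"), cbind(deg, phase = "after"))
  rec$participant_id <- "s1"
  fit <- suppressWarnings(fit_attitude_model(
    rec, mcmc = mcmc_control(chains = 2, iterations = 3000, burn_in = 500,
                             seed = 5)))
  post <- as.numeric(fit$draws[, "attitude_before", 1, ])
  pri <- withr::with_seed(9, draw_prior_marginal(default_priors(),
                                                 "attitude", 4000))
  ks <- suppressWarnings(stats::ks.test(post, pri)$statistic)
  expect_lt(ks, 0.1)
})

test_that("attitude posteriors contract as trials accumulate", {
  sds <- vapply(c(13, 50, 200), function(nt) {
    mean(vapply(1:2, function(s) {
      p <- list(attitude = 20, variability = 10, bias_kappa = 0,
                lapse_epsilon = 0.03)
      rec <- sim_subject_records(p, p, ring_trials(nt), seed = 100 * s)
      fit <- suppressWarnings(fit_attitude_model(
        rec, mcmc = mcmc_control(chains = 2, iterations = 1200,
                                 burn_in = 400, seed = s)))
      sd(as.numeric(fit$draws[, "attitude_before", 1, ]))
    }, 0))
  }, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("the fitting likelihood equals the reference implementation", {
  trials <- ring_trials(60)
  set.seed(23)
  for (rep in 1:100) {
    fam <- if (rep %% 2) "stable" else "variable"
    p <- list(attitude = runif(1, -80, 80), variability = runif(1, 0.5, 40),
              bias_kappa = runif(1, -15, 15),
              lapse_epsilon = runif(1, 0, 0.5))
    rec <- sim_subject_records(p, p, trials, fam, seed = 400 + rep)
    b <- rec[rec$phase == "before", ]
    r_ll <- log_likelihood(b, list(before = p), model_spec(fam, "full"))
    c_ll <- phase_loglik_cpp(b$pi_self, b$pi_other, b$choice, p$attitude,
                             p$variability, p$bias_kappa, p$lapse_epsilon,
                             if (fam == "stable") 1L else 2L)
    expect_equal(r_ll, c_ll, tolerance = 1e-6)
  }
})

test_that("tied schemes estimate the tied parameter once", {
  rec <- sim_cohort_full(4, ring_trials(40), seed = 3)
  for (sch in c("shared_attitude", "shared_variability")) {
    fit <- suppressWarnings(fit_attitude_model(
      rec, model_spec("variable", sch), mcmc = tiny_mcmc(2)))
    par <- if (sch == "shared_attitude") "attitude" else "variability"
    expect_equal(fit$draws[, paste0(par, "_before"), , ],
                 fit$draws[, paste0(par, "_after"), , ])
    cf <- coef(fit)
    expect_false(paste0(par, "_after") %in% colnames(cf))
  }
})

test_that("fit serialisation writes draws and diagnostics", {
  rec <- sim_cohort_full(2, ring_trials(25), seed = 5)
  fit <- suppressWarnings(fit_attitude_model(rec, mcmc = tiny_mcmc(4)))
  dir <- tempfile()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("draws.csv", "dic.json",
                                               "diagnostics.json")))))
  dr <- utils::read.csv(file.path(dir, "draws.csv"))
  expect_equal(nrow(dr), prod(dim(fit$draws)))
  expect_setequal(unique(dr$phase), c("before", "after"))
  dic <- jsonlite::read_json(file.path(dir, "dic.json"))
  expect_equal(dic$dic, fit$dic$dic, tolerance = 1e-8)
})
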