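# shared fixtures, all generated in code

ring_trials <- function(n = 100) {
  alls <- generate_allocation_set()
  alls[round(seq(1, nrow(alls), length.out = n)), ]
}

# records for one simulated participant, both phases
sim_subject_records <- function(params_before, params_after = params_before,
                                trials = ring_trials(100),
                                family = "variable", seed = 1L,
                                id = "s01") {
  rb <- simulate_choices(params_before, trials, family, seed)
  ra <- simulate_choices(params_after, trials, family, seed + 1L)
  rec <- rbind(cbind(rb, phase = "before"), cbind(ra, phase = "after"))
  rec$participant_id <- id
  rec
}

# cohort whose phases are independent draws from the population ranges:
# a genuine full-model generating process, used for model identification
sim_cohort_full <- function(n_subj, trials = ring_trials(100), seed = 1L,
                            family = "variable") {
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    set.seed(seed * 1000L + i)
    mk <- function() {
      pro <- stats::runif(1) < 0.75
      a <- if (pro) stats::rnorm(1, 20, 14) else stats::rnorm(1, -22, 20)
      v <- if (family == "variable") stats::rlnorm(1, log(12), 0.4)
           else stats::rlnorm(1, log(25), 0.5)
      list(attitude = max(min(a, 85), -85), variability = v,
           bias_kappa = stats::rnorm(1, 2, 4),
           lapse_epsilon = stats::rbeta(1, 2, 38))
    }
    sim_subject_records(mk(), mk(), trials, family, seed * 77L + i,
                        sprintf("s%03d", i))
  }))
}

# brute-force exact one-sample signed-rank p by enumeration over all 2^n
# sign assignments (n <= 12)
enum_wilcoxon_p <- function(x, alternative = "greater") {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n <= 12)
  rk <- rank(abs(x))
  v_obs <- sum(rk[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs),
                                    mean(v_all <= v_obs))))
}

# tiny MCMC settings for fast structural tests
tiny_mcmc <- function(seed = 1L)
  mcmc_control(chains = 2, iterations = 600, burn_in = 200, seed = seed)
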