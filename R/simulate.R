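#' Configuration of the synthetic participant population
#'
#' Defaults reproduce the study's design and the reported population
#' structure: four between-subjects conditions with the study's sample
#' sizes; a 75/25 prosocial/antisocial attitude mixture with means 20 / -22
#' degrees (SD 14 / 20); a 17% compliant subpopulation whose default-penalty
#' bias centres at 11.48 points against 1.14 for the rest; and
#' condition-dependent attitude shifts towards the observed agent (0 / 4 / 6
#' / 5 degrees for baseline / computer / individual / group). By default the
#' shift applies to everyone in the treatment conditions, and behaviourally
#' compliant participants (compliance index at or above 25%) receive an
#' extra shift in the computer condition, mirroring the finding that the
#' computer-condition effect is partly demand-driven and concentrated in the
#' compliant subgroup.
#'
#' @param n_per_condition named counts for baseline, computer, individual,
#'   group.
#' @param prosocial_fraction probability of a prosocial attitude.
#' @param attitude_mean_pro,attitude_sd_pro,attitude_mean_anti,attitude_sd_anti
#'   attitude mixture parameters, degrees.
#' @param compliant_fraction probability of the compliant subtype.
#' @param kappa_mean_compliant,kappa_sd_compliant,kappa_mean_noncompliant,kappa_sd_noncompliant
#'   bias mixture parameters, points.
#' @param convergence_shift named per-condition shift towards the agent,
#'   degrees.
#' @param shift_applies named per-condition subgroup the base shift applies
#'   to: `"all"`, `"compliant"`, `"noncompliant"` or `"none"` (compliance
#'   judged behaviourally from the simulated before-phase choices).
#' @param compliant_extra_shift named per-condition additional shift (in
#'   degrees, towards the agent) for behaviourally compliant participants.
#' @param attitude_jitter_sd SD of the after-phase attitude jitter, degrees.
#' @param sigma_logmean,sigma_logsd log-normal parameters of the before
#'   phase choice variability, degrees.
#' @param consistency_shrink_logmean,consistency_shrink_logsd log-normal
#'   multiplicative shrink of sigma after the manipulation phase (< 1 means
#'   participants get more consistent, as observed in every condition).
#' @param epsilon_shape1,epsilon_shape2 Beta parameters of the lapse rate.
#' @param agent_sigma,agent_epsilon consistency of the observed agents
#'   (small: agents were calibrated to be easily predictable).
#' @param prediction_accuracy probability of a correct prediction in the
#'   manipulation phase.
#' @param norm_noise_sd SD of the latent noise in norm ratings.
#' @param trials_per_phase subsample each phase's trial set to this many
#'   allocations (angle-stratified); NULL for the full sets.
#' @param include_selfish append the 9 self-advantageous trials to each
#'   phase.
#' @param seed master seed; every participant derives a substream from it.
#' @export
population_config <- function(
    n_per_condition = c(baseline = 132, computer = 74, individual = 66,
                        group = 97),
    prosocial_fraction = 0.75,
    attitude_mean_pro = 20, attitude_sd_pro = 14,
    attitude_mean_anti = -22, attitude_sd_anti = 20,
    compliant_fraction = 0.17,
    kappa_mean_compliant = 11.48, kappa_sd_compliant = 11,
    kappa_mean_noncompliant = 1.14, kappa_sd_noncompliant = 2.6,
    convergence_shift = c(baseline = 0, computer = 4, individual = 6,
                          group = 5),
    shift_applies = c(baseline = "none", computer = "all",
                      individual = "all", group = "all"),
    compliant_extra_shift = c(baseline = 0, computer = 5, individual = 0,
                              group = 0),
    attitude_jitter_sd = 3,
    sigma_logmean = log(12), sigma_logsd = 0.4,
    consistency_shrink_logmean = log(0.85), consistency_shrink_logsd = 0.15,
    epsilon_shape1 = 2, epsilon_shape2 = 38,
    agent_sigma = 2, agent_epsilon = 0.01,
    prediction_accuracy = 0.93,
    norm_noise_sd = 0.75,
    trials_per_phase = NULL,
    include_selfish = TRUE,
    seed = 1L) {
  cfg <- as.list(environment())
  conds <- c("baseline", "computer", "individual", "group")
  stopifnot(all(conds %in% names(cfg$n_per_condition)),
            all(cfg$n_per_condition >= 0),
            cfg$prosocial_fraction >= 0, cfg$prosocial_fraction <= 1,
            cfg$compliant_fraction >= 0, cfg$compliant_fraction <= 1,
            cfg$attitude_sd_pro > 0, cfg$attitude_sd_anti > 0,
            cfg$sigma_logsd > 0, cfg$attitude_jitter_sd >= 0,
            all(cfg$shift_applies %in% c("all", "compliant", "noncompliant",
                                         "none")))
  class(cfg) <- "population_config"
  cfg
}

rnorm_trunc <- function(n, mean, sd, lo = -85, hi = 85) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# angle-stratified subsample: every k-th allocation in angle order
stratify_trials <- function(trials, n) {
  if (is.null(n) || n >= nrow(trials)) return(trials)
  ord <- order(trials$angle)
  pick <- ord[round(seq(1, nrow(trials), length.out = n))]
  trials[sort(pick), , drop = FALSE]
}

#' Simulate one phase of choices for a participant
#'
#' Draws one choice per trial from the family's lapse-mixed default
#' probability; reproducible under the seed.
#'
#' @param params named list with `attitude`, `variability`, `bias_kappa`,
#'   `lapse_epsilon`.
#' @param trials data frame with `pi_self`, `pi_other`.
#' @param family `"variable"` or `"stable"`.
#' @param seed integer seed.
#' @return data frame `pi_self`, `pi_other`, `choice` (0 default, 1
#'   alternative).
#' @export
simulate_choices <- function(params, trials, family = "variable",
                             seed = 1L) {
  p_def <- choice_prob_default(trials$pi_self, trials$pi_other, params,
                               family)
  choice <- withr_seed(seed,
                       as.integer(stats::runif(nrow(trials)) > p_def))
  data.frame(pi_self = trials$pi_self, pi_other = trials$pi_other,
             choice = choice)
}

#' Assign the observed agent's attitude from before-phase behaviour
#'
#' Participants classified prosocial (model-free score >= 0) observe an
#' extremely prosocial agent (+45 degrees: one point for the other equals
#' one own point); antisocial participants observe a -45 degree agent.
#'
#' @param before_records before-phase choice records.
#' @return +45 or -45 (degrees).
#' @export
assign_agent <- function(before_records) {
  if (classify_attitude(before_records)$class == "prosocial") 45 else -45
}

#' Majority choices of a five-member group agent
#'
#' Each member's choices are simulated independently; the agent's displayed
#' choice on each trial is the modal response. An odd member count rules out
#' ties.
#'
#' @param members list of parameter sets (as in [simulate_choices()]), odd
#'   length.
#' @param trials data frame with `pi_self`, `pi_other`.
#' @param family,seed as in [simulate_choices()].
#' @return integer vector of majority choices (0 default, 1 alternative).
#' @export
simulate_group_agent <- function(members, trials, family = "variable",
                                 seed = 1L) {
  stopifnot(length(members) %% 2 == 1)
  ch <- vapply(seq_along(members), function(i)
    simulate_choices(members[[i]], trials, family, seed + i)$choice,
    integer(nrow(trials)))
  ch <- matrix(ch, nrow = nrow(trials))
  as.integer(rowMeans(ch) > 0.5)
}

#' Simulate 4-point appropriateness ratings
#'
#' Ordinal ratings of how socially appropriate choosing each probe
#' allocation over the default is. The latent appropriateness is
#' proportional to the recipient's payoff advantage, with the sign of the
#' participant's attitude (prosocial participants find giving appropriate
#' and taking inappropriate; antisocial participants the opposite), plus
#' Gaussian noise, cut into four ordered categories.
#'
#' @param attitude_sign +1 (prosocial) or -1 (antisocial).
#' @param probes data frame with `pi_other` (should span prosocial and
#'   antisocial allocations).
#' @param noise_sd latent noise SD; 0 gives deterministic monotone ratings.
#' @param seed integer seed.
#' @return integer ratings 1-4, one per probe.
#' @export
simulate_norm_ratings <- function(attitude_sign, probes, noise_sd = 0.75,
                                  seed = 1L) {
  stopifnot(attitude_sign %in% c(-1, 1),
            any(probes$pi_other > 50), any(probes$pi_other < 50))
  latent <- attitude_sign * (probes$pi_other - 50) / 25
  latent <- latent + withr_seed(seed,
                                stats::rnorm(nrow(probes), 0, noise_sd))
  as.integer(cut(latent, c(-Inf, -1, 0, 1, Inf), labels = FALSE))
}

#' Default norm-elicitation probe allocations
#'
#' Twelve circle-band allocations evenly spaced in angle, half prosocial and
#' half antisocial.
#'
#' @param n number of probes.
#' @export
norm_probes <- function(n = 12) {
  alls <- generate_allocation_set()
  stratify_trials(alls, n)
}

#' Simulate a full participant population
#'
#' Generates the task design (406 circle-band allocations partitioned into
#' four angle-balanced subsets; the two 102-trial subsets serve the baseline
#' condition's before/after phases and the 101-trial subsets the other
#' conditions, plus the self-advantageous catch trials), then draws each
#' participant's true parameters from the configured mixtures, simulates
#' before-phase choices under the variable-attitude model, assigns the
#' extreme agent from the model-free classification, applies the
#' condition-dependent attitude shift towards the agent (capped at the
#' agent's attitude, plus jitter), simulates after-phase choices,
#' manipulation-phase predictions, and norm ratings.
#'
#' @param config a [population_config()].
#' @return list of class `svo_population`; each element holds `id`,
#'   `condition`, `prosocial`, `compliant` (generator ground truth),
#'   `true_params_before`, `true_params_after`, `agent_attitude`, `records`
#'   (both phases), `prediction_records`, `norm_ratings`.
#' @export
sample_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  design <- partition_subsets(generate_allocation_set())
  selfish <- if (config$include_selfish) make_selfish_trials(seed = config$seed)
             else NULL
  phase_sets <- list(
    baseline = list(before = design[design$subset_id == 1, ],
                    after = design[design$subset_id == 2, ]),
    other = list(before = design[design$subset_id == 3, ],
                 after = design[design$subset_id == 4, ]))
  manip_pool <- design[design$subset_id %in% 1:2, ]  # held out in non-baseline
  manip <- stratify_trials(manip_pool, 63)
  probes <- norm_probes()
  conds <- rep(names(config$n_per_condition), config$n_per_condition)
  n <- length(conds)
  master <- withr_seed(config$seed, {
    data.frame(
      prosocial = stats::runif(n) < config$prosocial_fraction,
      compliant = stats::runif(n) < config$compliant_fraction,
      sub_seed = sample.int(2^30, n))
  })

  pop <- lapply(seq_len(n), function(i) {
    cond <- conds[i]
    info <- master[i, ]
    set.seed(info$sub_seed)
    mu_b <- if (info$prosocial)
      rnorm_trunc(1, config$attitude_mean_pro, config$attitude_sd_pro)
    else
      rnorm_trunc(1, config$attitude_mean_anti, config$attitude_sd_anti)
    kap <- if (info$compliant)
      stats::rnorm(1, config$kappa_mean_compliant, config$kappa_sd_compliant)
    else
      stats::rnorm(1, config$kappa_mean_noncompliant,
                   config$kappa_sd_noncompliant)
    sig_b <- stats::rlnorm(1, config$sigma_logmean, config$sigma_logsd)
    sig_a <- sig_b * stats::rlnorm(1, config$consistency_shrink_logmean,
                                   config$consistency_shrink_logsd)
    eps <- stats::rbeta(1, config$epsilon_shape1, config$epsilon_shape2)
    pb <- list(attitude = mu_b, variability = sig_b, bias_kappa = kap,
               lapse_epsilon = eps)
    sets <- if (cond == "baseline") phase_sets$baseline else phase_sets$other
    t_b <- stratify_trials(sets$before, config$trials_per_phase)
    t_a <- stratify_trials(sets$after, config$trials_per_phase)
    if (!is.null(selfish)) {
      t_b <- rbind(t_b[c("pi_self", "pi_other")],
                   selfish[c("pi_self", "pi_other")])
      t_a <- rbind(t_a[c("pi_self", "pi_other")],
                   selfish[c("pi_self", "pi_other")])
    }
    rec_b <- simulate_choices(pb, t_b, "variable", info$sub_seed + 1L)
    agent <- assign_agent(rec_b)
    shift <- config$convergence_shift[[cond]]
    # compliance is behavioural: the displayed cross-type choice rate, not
    # the latent subtype (which only drives kappa)
    idx_b <- suppressWarnings(compliance_index(rec_b))
    behav_compliant <- !is.na(idx_b) && idx_b >= 25
    applies <- switch(config$shift_applies[[cond]],
                      all = TRUE,
                      compliant = behav_compliant,
                      noncompliant = !behav_compliant,
                      none = FALSE)
    total_shift <- shift * applies +
      config$compliant_extra_shift[[cond]] * behav_compliant
    mu_a <- mu_b
    if (total_shift != 0) {
      gap <- agent - mu_b
      mu_a <- mu_b + sign(gap) * min(total_shift, abs(gap))
    }
    mu_a <- min(max(mu_a + stats::rnorm(1, 0, config$attitude_jitter_sd),
                    -85), 85)
    pa <- list(attitude = mu_a, variability = sig_a, bias_kappa = kap,
               lapse_epsilon = eps)
    rec_a <- simulate_choices(pa, t_a, "variable", info$sub_seed + 2L)
    rec <- rbind(cbind(rec_b, phase = "before"),
                 cbind(rec_a, phase = "after"))
    rec$trial_index <- c(seq_len(nrow(rec_b)), seq_len(nrow(rec_a))) - 1L
    pred <- NULL
    if (cond != "baseline") {
      agent_params <- list(attitude = agent,
                           variability = config$agent_sigma,
                           bias_kappa = 0,
                           lapse_epsilon = config$agent_epsilon)
      agent_choice <- if (cond == "individual")
        simulate_choices(agent_params, manip, "variable",
                         info$sub_seed + 3L)$choice
      else  # group majority; the computer replays the group's criterion
        simulate_group_agent(
          lapply(1:5, function(m)
            list(attitude = agent + stats::rnorm(1, 0, 3),
                 variability = config$agent_sigma, bias_kappa = 0,
                 lapse_epsilon = config$agent_epsilon)),
          manip, "variable", info$sub_seed + 3L)
      hit <- stats::runif(63) < config$prediction_accuracy
      pred <- data.frame(pi_self = manip$pi_self, pi_other = manip$pi_other,
                         agent_choice = agent_choice,
                         predicted = ifelse(hit, agent_choice,
                                            1L - agent_choice),
                         correct = hit)
    }
    ratings <- simulate_norm_ratings(
      if (classify_attitude(rec_b)$class == "prosocial") 1 else -1,
      probes, config$norm_noise_sd, info$sub_seed + 4L)
    list(id = sprintf("p%03d", i), condition = cond,
         prosocial = info$prosocial, compliant = info$compliant,
         true_params_before = pb, true_params_after = pa,
         agent_attitude = agent, records = rec,
         prediction_records = pred, norm_ratings = ratings)
  })
  attr(pop, "config") <- config
  attr(pop, "probes") <- probes
  class(pop) <- "svo_population"
  pop
}

#' @export
print.svo_population <- function(x, ...) {
  conds <- vapply(x, `[[`, "", "condition")
  cat("Synthetic population:", length(x), "participants\n")
  print(table(condition = conds))
  cat(sprintf("  prosocial: %.0f%%; compliant subtype: %.0f%%\n",
              100 * mean(vapply(x, `[[`, TRUE, "prosocial")),
              100 * mean(vapply(x, `[[`, TRUE, "compliant"))))
  invisible(x)
}

#' Flatten a population into the shared choice-record table
#'
#' @param pop an `svo_population`.
#' @return data frame `participant_id`, `condition`, `phase`, `trial_index`,
#'   `pi_self`, `pi_other`, `choice`.
#' @export
population_records <- function(pop) {
  do.call(rbind, lapply(pop, function(p)
    data.frame(participant_id = p$id, condition = p$condition,
               phase = p$records$phase, trial_index = p$records$trial_index,
               pi_self = p$records$pi_self, pi_other = p$records$pi_other,
               choice = p$records$choice)))
}

#' Ground-truth parameter table of a population
#'
#' @param pop an `svo_population`.
#' @return data frame, one row per participant, with the generator's true
#'   parameters before/after, condition, subtype flags and agent attitude.
#' @export
population_truth <- function(pop) {
  do.call(rbind, lapply(pop, function(p)
    data.frame(participant_id = p$id, condition = p$condition,
               prosocial = p$prosocial, compliant = p$compliant,
               alpha_before = p$true_params_before$attitude,
               alpha_after = p$true_params_after$attitude,
               sigma_before = p$true_params_before$variability,
               sigma_after = p$true_params_after$variability,
               kappa_before = p$true_params_before$bias_kappa,
               epsilon = p$true_params_before$lapse_epsilon,
               alpha_obs = p$agent_attitude)))
}

#' Write population choice records and ground truth to CSV
#'
#' `choices.csv` uses the shared dialect
#' `participant_id,condition,phase,trial_index,pi_self,pi_other,choice`;
#' `truth.csv` holds the generator's true parameters for recovery checks.
#'
#' @param pop an `svo_population`.
#' @param dir output directory.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(population_records(pop), file.path(dir, "choices.csv"),
                   row.names = FALSE)
  utils::write.csv(population_truth(pop), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read choice records in the shared CSV dialect
#' @param path CSV file path.
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "phase", "pi_self", "pi_other", "choice")
  if (!all(need %in% names(df)))
    stop("choice CSV must have columns ", paste(need, collapse = ","))
  df
}
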