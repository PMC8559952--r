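PAR_NAMES <- c("attitude_before", "attitude_after",
               "variability_before", "variability_after",
               "kappa_before", "kappa_after",
               "epsilon_before", "epsilon_after")
GROUP_NAMES <- c("mean_attitude", "sd_attitude",
                 "mean_log_variability", "sd_log_variability",
                 "mean_kappa", "sd_kappa",
                 "mean_lapse_logit", "sd_lapse_logit")
# sampling-scale column -> parameter family (1 attitude, 2 log var, 3 kappa,
# 4 lapse logit)
COL_FAMILY <- c(1, 1, 2, 2, 3, 3, 4, 4)

#' Prior specification for the hierarchical model
#'
#' Each subject-level parameter gets a group-level location (Normal prior)
#' and a group-level scale (half-Normal prior); subjects are Normal draws
#' around the group location on the sampling scale: degrees for attitude,
#' log scale for the variability parameter (sigma in degrees or tau in
#' points), points for kappa, and a logit scale over (0, 0.5) for the lapse
#' rate. Defaults are weakly informative and cover the parameter ranges the
#' task can express.
#'
#' @param attitude,log_variability,bias,lapse_logit lists with elements
#'   `loc_mean`, `loc_sd` (Normal prior on the group location) and
#'   `scale_sd` (half-Normal prior on the group scale).
#' @export
default_priors <- function(attitude = list(loc_mean = 0, loc_sd = 30,
                                           scale_sd = 20),
                           log_variability = list(loc_mean = log(10),
                                                  loc_sd = 2, scale_sd = 1),
                           bias = list(loc_mean = 0, loc_sd = 10,
                                       scale_sd = 10),
                           lapse_logit = list(loc_mean = -2, loc_sd = 2,
                                              scale_sd = 1.5)) {
  pr <- list(attitude = attitude, log_variability = log_variability,
             bias = bias, lapse_logit = lapse_logit)
  for (p in pr)
    stopifnot(is.numeric(p$loc_mean), p$loc_sd > 0, p$scale_sd > 0)
  class(pr) <- "svo_priors"
  pr
}

#' MCMC settings
#'
#' Desk-scale defaults (4 chains of 2000 iterations, 500 burn-in, no
#' thinning) keep a full fit in the minutes range on one CPU;
#' `full_scale = TRUE` switches to 100000 iterations, 5000 burn-in,
#' thinning 4.
#'
#' @param chains number of chains (>= 2).
#' @param iterations iterations per chain, including burn-in.
#' @param burn_in discarded initial iterations (adaptation happens here).
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param seed integer master seed.
#' @param full_scale use production-scale settings for final analyses.
#' @export
mcmc_control <- function(chains = 4, iterations = 2000, burn_in = 500,
                         thinning = 1, seed = 1L, full_scale = FALSE) {
  if (full_scale) {
    iterations <- 100000; burn_in <- 5000; thinning <- 4
  }
  stopifnot(chains >= 2, iterations > burn_in, burn_in >= 0, thinning >= 1)
  structure(list(chains = chains, iterations = iterations,
                 burn_in = burn_in, thinning = thinning,
                 seed = as.integer(seed)), class = "mcmc_control")
}

# records -> per-subject list consumed by the compiled sweep
build_subject_data <- function(records) {
  records <- records[!is.na(records$choice), , drop = FALSE]
  ids <- unique(records$participant_id)
  subj <- lapply(ids, function(id) {
    r <- records[records$participant_id == id, , drop = FALSE]
    b <- r[r$phase == "before", , drop = FALSE]
    a <- r[r$phase == "after", , drop = FALSE]
    list(py_before = as.numeric(b$pi_self), po_before = as.numeric(b$pi_other),
         ch_before = as.integer(b$choice),
         py_after = as.numeric(a$pi_self), po_after = as.numeric(a$pi_other),
         ch_after = as.integer(a$choice))
  })
  names(subj) <- as.character(ids)
  subj
}

# crude per-subject attitude profile for chain initialisation
init_attitude <- function(s, family) {
  grid <- seq(-80, 80, by = 5)
  fam <- if (family == "stable") 1L else 2L
  ll <- vapply(grid, function(mu) {
    v <- if (family == "stable") 20 else 10
    phase_loglik_cpp(c(s$py_before, s$py_after), c(s$po_before, s$po_after),
                     c(s$ch_before, s$ch_after), mu, v, 0, 0.05, fam)
  }, 0)
  grid[which.max(ll)]
}

# conjugate Normal update for a group location
update_loc <- function(values, scale, loc_mean, loc_sd) {
  prec <- length(values) / scale^2 + 1 / loc_sd^2
  m <- (sum(values) / scale^2 + loc_mean / loc_sd^2) / prec
  stats::rnorm(1, m, sqrt(1 / prec))
}

# slice-sampling update (on log scale) for a group scale with half-Normal
# prior; robust to the funnel near zero where a fixed-step random walk
# stalls
update_scale <- function(values, loc, scale, scale_sd, w = 1) {
  target <- function(ls) {
    s <- exp(ls)
    sum(stats::dnorm(values, loc, s, log = TRUE)) -
      s^2 / (2 * scale_sd^2) + ls
  }
  x0 <- log(scale)
  y <- target(x0) - stats::rexp(1)
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  for (i in 1:20) {
    if (target(lo) <= y) break
    lo <- lo - w
  }
  for (i in 1:20) {
    if (target(hi) <= y) break
    hi <- hi + w
  }
  for (i in 1:50) {
    x1 <- stats::runif(1, lo, hi)
    if (target(x1) >= y) return(exp(x1))
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  scale
}

active_cols <- function(scheme) {
  setdiff(1:8, switch(scheme, shared_attitude = 2L,
                      shared_variability = 4L, integer(0)))
}

#' Fit a hierarchical Bayesian attitude model to choice data
#'
#' Fits one of the six cognitive model variants (see [model_spec()]) by
#' Metropolis-within-Gibbs MCMC. The hierarchy has two levels: group-level
#' Normal location/scale per parameter, and subject-by-phase parameters drawn
#' from them; before/after phases are exchangeable draws from the group
#' level. Subject-level components use adaptive random-walk proposals (tuned
#' towards 44% acceptance during burn-in only); group locations are updated
#' by conjugate Gibbs steps, group scales by slice sampling on the log
#' scale, and the log-variability and lapse families get an extra
#' ancillarity move (jointly rescaling subject deviations and the group
#' scale) to cross the hierarchical funnel. Deviance (-2 log-likelihood) is
#' recorded at every kept draw for DIC.
#'
#' @param records data frame with columns `participant_id`, `phase`
#'   (`"before"`/`"after"`), `pi_self`, `pi_other`, `choice` (0 default, 1
#'   alternative, NA missing; missing trials are dropped).
#' @param spec a [model_spec()].
#' @param priors a [default_priors()] object.
#' @param mcmc an [mcmc_control()] object.
#' @return an object of class `svo_fit` with posterior draws (natural
#'   scale), group-level draws, deviance trace, DIC, and split-Rhat
#'   diagnostics. A warning is raised (and `$converged` set to FALSE) when
#'   any split-Rhat exceeds 1.05.
#' @export
fit_attitude_model <- function(records, spec = model_spec(),
                               priors = default_priors(),
                               mcmc = mcmc_control()) {
  stopifnot(inherits(spec, "model_spec"))
  subj <- build_subject_data(records)
  n <- length(subj)
  if (n < 1 || all(vapply(subj, function(s)
      length(s$ch_before) + length(s$ch_after), 0L) == 0))
    stop("need at least one participant with at least one non-missing trial")
  fam <- if (spec$family == "stable") 1L else 2L
  cols <- active_cols(spec$scheme)
  kept <- floor((mcmc$iterations - mcmc$burn_in) / mcmc$thinning)
  draws <- array(NA_real_, c(kept, 8, n, mcmc$chains),
                 dimnames = list(NULL, PAR_NAMES, names(subj), NULL))
  gdraws <- array(NA_real_, c(kept, 8, mcmc$chains),
                  dimnames = list(NULL, GROUP_NAMES, NULL))
  dev <- matrix(NA_real_, kept, mcmc$chains)
  prior_by_fam <- list(priors$attitude, priors$log_variability, priors$bias,
                       priors$lapse_logit)
  theta_sum <- matrix(0, n, 8)

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed * 1000L + ch)
    mu0 <- vapply(subj, init_attitude, 0, family = spec$family)
    theta <- cbind(mu0 + stats::rnorm(n, 0, 5), mu0 + stats::rnorm(n, 0, 5),
                   log(10) + stats::rnorm(n, 0, 0.3),
                   log(10) + stats::rnorm(n, 0, 0.3),
                   stats::rnorm(n, 0, 3), stats::rnorm(n, 0, 3),
                   -2.2 + stats::rnorm(n, 0, 0.5),
                   -2.2 + stats::rnorm(n, 0, 0.5))
    theta[, 1:2] <- pmin(pmax(theta[, 1:2], -85), 85)
    if (spec$scheme == "shared_attitude") theta[, 2] <- theta[, 1]
    if (spec$scheme == "shared_variability") theta[, 4] <- theta[, 3]
    gm <- c(mean(theta[, 1:2]), mean(theta[, 1:2]), log(10), log(10),
            0, 0, -2.2, -2.2)
    gs <- c(15, 15, 0.5, 0.5, 3, 3, 0.8, 0.8)
    prop_sd <- matrix(rep(c(4, 4, 0.3, 0.3, 2, 2, 0.6, 0.6), each = n), n, 8)
    cur_ll <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      s <- subj[[i]]
      if (length(s$ch_before))
        cur_ll[i, 1] <- phase_loglik_cpp(s$py_before, s$po_before,
                                         s$ch_before, theta[i, 1],
                                         exp(theta[i, 3]), theta[i, 5],
                                         0.5 * stats::plogis(theta[i, 7]), fam)
      if (length(s$ch_after))
        cur_ll[i, 2] <- phase_loglik_cpp(s$py_after, s$po_after, s$ch_after,
                                         theta[i, 2], exp(theta[i, 4]),
                                         theta[i, 6],
                                         0.5 * stats::plogis(theta[i, 8]), fam)
    }
    acc <- matrix(0L, n, 8)
    batch <- 50L
    k <- 0L
    for (it in seq_len(mcmc$iterations)) {
      subject_sweep_cpp(subj, theta, gm, gs, prop_sd, fam,
                        switch(spec$scheme, full = 0L, shared_attitude = 1L,
                               shared_variability = 2L),
                        cur_ll, acc)
      # group level: per parameter family, pool active columns; a few
      # location/scale scans per sweep help the scale mix across the
      # hierarchy's funnel
      for (f in 1:4) {
        fcols <- intersect(which(COL_FAMILY == f), cols)
        vals <- as.numeric(theta[, fcols])
        pr <- prior_by_fam[[f]]
        sc <- gs[fcols[1]]
        for (scan in 1:3) {
          loc <- update_loc(vals, sc, pr$loc_mean, pr$loc_sd)
          sc <- update_scale(vals, loc, sc, pr$scale_sd)
        }
        gm[COL_FAMILY == f] <- loc
        gs[COL_FAMILY == f] <- sc
      }
      # ancillarity moves for the variability and lapse families: rescale
      # subject deviations and the group scale together, which decorrelates
      # the scale from the shrunk subject values (the funnel)
      for (fi in c(2L, 4L)) {
        fcols <- which(COL_FAMILY == fi)
        cc <- exp(stats::rnorm(1, 0, 0.1))
        th2 <- theta
        th2[, fcols] <- gm[fcols[1]] + cc * (theta[, fcols] - gm[fcols[1]])
        ll2 <- all_phase_ll_cpp(subj, th2, fam)
        s_old <- gs[fcols[1]]; s_new <- cc * s_old
        logr <- sum(ll2) - sum(cur_ll) -
          (s_new^2 - s_old^2) / (2 * prior_by_fam[[fi]]$scale_sd^2) +
          log(cc)
        if (log(stats::runif(1)) < logr) {
          theta[, fcols] <- th2[, fcols]
          cur_ll[] <- ll2
          gs[fcols] <- s_new
        }
      }
      if (it <= mcmc$burn_in && it %% batch == 0L) {
        rate <- acc / batch
        prop_sd <- prop_sd * exp(0.3 * sign(rate - 0.44) *
                                 pmin(abs(rate - 0.44) * 4, 1))
        prop_sd <- pmin(pmax(prop_sd, 1e-3), 50)
        acc[] <- 0L
      }
      if (it > mcmc$burn_in &&
          (it - mcmc$burn_in) %% mcmc$thinning == 0L && k < kept) {
        k <- k + 1L
        nat <- theta
        nat[, 3:4] <- exp(nat[, 3:4])
        nat[, 7:8] <- 0.5 * stats::plogis(nat[, 7:8])
        draws[k, , , ch] <- t(nat)
        gdraws[k, , ch] <- c(gm[1], gs[1], gm[3], gs[3], gm[5], gs[5],
                             gm[7], gs[7])
        dev[k, ch] <- -2 * sum(cur_ll)
        theta_sum <- theta_sum + theta
      }
    }
  }

  theta_bar <- theta_sum / (kept * mcmc$chains)
  plugin_dev <- -2 * total_loglik_cpp(subj, theta_bar, fam)
  dic <- dic_from_deviance(as.numeric(dev), plugin_dev)

  rhat <- c(apply(gdraws, 2, split_rhat),
            attitude = max(apply(draws[, 1, , , drop = FALSE], 3,
                                 function(m) split_rhat(matrix(m, kept)))))
  converged <- all(is.finite(rhat)) && max(rhat, na.rm = TRUE) <= 1.05
  out <- structure(list(draws = draws, group_draws = gdraws, deviance = dev,
                        dic = dic, plugin_deviance = plugin_dev,
                        spec = spec, priors = priors, mcmc = mcmc,
                        participants = names(subj), rhat = rhat,
                        converged = converged,
                        n_trials = vapply(subj, function(s)
                          length(s$ch_before) + length(s$ch_after), 0L)),
                   class = "svo_fit")
  if (!converged)
    warning("fit flagged as unconverged: max split-Rhat = ",
            round(max(rhat, na.rm = TRUE), 3))
  out
}

#' Split-half Rhat for a draws matrix (iterations x chains)
#' @param x numeric matrix, one column per chain.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(sp); n2 <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- n2 * stats::var(means)
  if (W < 1e-12) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# mode of a Gaussian-kernel density estimate, Silverman bandwidth
kde_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 2048)
  d$x[which.max(d$y)]
}

#' Maximum a posteriori estimate of a fitted parameter
#'
#' The mode of the marginal posterior, located with a Gaussian-kernel
#' density estimate (Silverman's rule-of-thumb bandwidth) over the pooled
#' chains.
#'
#' @param fit an `svo_fit`.
#' @param parameter one of `"attitude"`, `"variability"`, `"kappa"`,
#'   `"epsilon"`, or a full draw name such as `"attitude_before"`.
#' @param participant participant id (character or index); NULL for a
#'   group-level parameter name from the fit's `group_draws`.
#' @param phase `"before"` or `"after"` (ignored when `parameter` already
#'   names a phase).
#' @export
map_estimate <- function(fit, parameter, participant = NULL,
                         phase = c("before", "after")) {
  stopifnot(inherits(fit, "svo_fit"))
  if (is.null(participant)) {
    stopifnot(parameter %in% GROUP_NAMES)
    return(kde_mode(as.numeric(fit$group_draws[, parameter, ])))
  }
  if (!parameter %in% PAR_NAMES)
    parameter <- paste(parameter, match.arg(phase), sep = "_")
  stopifnot(parameter %in% PAR_NAMES)
  if (is.character(participant))
    participant <- match(participant, fit$participants)
  kde_mode(as.numeric(fit$draws[, parameter, participant, ]))
}

#' Deviance information criterion
#'
#' Spiegelhalter form: `DIC = Dbar + pD`, `pD = Dbar - Dhat`, with `Dhat`
#' the deviance at the posterior means of the subject-level parameters
#' (means on the sampling scale).
#'
#' @param fit an `svo_fit`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "svo_fit"))
  fit$dic
}

#' @rdname compute_dic
#' @param deviance_draws numeric vector of deviance draws.
#' @param plugin_deviance deviance at the plug-in parameter values.
#' @export
dic_from_deviance <- function(deviance_draws, plugin_deviance) {
  dbar <- mean(deviance_draws)
  pd <- dbar - plugin_deviance
  list(dic = dbar + pd, mean_deviance = dbar, p_d = pd)
}

#' Fit and rank all candidate models by DIC
#'
#' @param records choice records (see [fit_attitude_model()]).
#' @param specs list of [model_spec()]s (default: all six).
#' @param priors,mcmc passed to [fit_attitude_model()].
#' @param keep_fits retain the individual fits in the result.
#' @return data frame of class `svo_model_comparison` with columns `family`,
#'   `scheme`, `dic`, `p_d`, `delta_dic`; the winner has `delta_dic` 0.
#' @export
compare_models <- function(records, specs = all_model_specs(),
                           priors = default_priors(), mcmc = mcmc_control(),
                           keep_fits = FALSE) {
  fits <- lapply(specs, function(sp)
    suppressWarnings(fit_attitude_model(records, sp, priors, mcmc)))
  tab <- data.frame(
    family = vapply(specs, `[[`, "", "family"),
    scheme = vapply(specs, `[[`, "", "scheme"),
    dic = vapply(fits, function(f) f$dic$dic, 0),
    p_d = vapply(fits, function(f) f$dic$p_d, 0))
  tab$delta_dic <- tab$dic - min(tab$dic)
  tab <- tab[order(tab$dic), ]
  rownames(tab) <- NULL
  attr(tab, "winner") <- model_spec(tab$family[1], tab$scheme[1])
  if (keep_fits) attr(tab, "fits") <- fits
  class(tab) <- c("svo_model_comparison", "data.frame")
  tab
}

#' @export
print.svo_model_comparison <- function(x, ...) {
  cat("Model comparison by DIC (lower is better)\n")
  print.data.frame(cbind(data.frame(x)[1:2],
                         round(data.frame(x)[3:5], 1)))
  w <- attr(x, "winner")
  cat(sprintf("winner: %s / %s\n", w$family, w$scheme))
  invisible(x)
}

#' Draw from the marginal prior of a subject-level parameter
#'
#' Samples the group location and scale from their priors and a subject
#' value around them; used to compare no-information posteriors with the
#' prior.
#'
#' @param priors a [default_priors()] object.
#' @param parameter `"attitude"`, `"log_variability"`, `"bias"` or
#'   `"lapse_logit"`.
#' @param n number of draws.
#' @export
draw_prior_marginal <- function(priors, parameter = "attitude", n = 1000) {
  pr <- priors[[parameter]]
  loc <- stats::rnorm(n, pr$loc_mean, pr$loc_sd)
  sc <- abs(stats::rnorm(n, 0, pr$scale_sd))
  stats::rnorm(n, loc, sc)
}

#' @export
print.svo_fit <- function(x, ...) {
  cat(sprintf("Hierarchical SVO choice model (%s family, %s scheme)\n",
              x$spec$family, x$spec$scheme))
  cat(sprintf("  %d participants, %d-%d trials each\n",
              length(x$participants), min(x$n_trials), max(x$n_trials)))
  cat(sprintf("  %d chains x %d kept draws; DIC = %.1f (pD = %.1f)\n",
              x$mcmc$chains, dim(x$draws)[1], x$dic$dic, x$dic$p_d))
  cat(sprintf("  max split-Rhat = %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.svo_fit <- function(object, ...) {
  g <- apply(object$group_draws, 2, function(m)
    c(mean = mean(m), sd = stats::sd(m),
      q2.5 = stats::quantile(m, .025, names = FALSE),
      q97.5 = stats::quantile(m, .975, names = FALSE)))
  out <- list(spec = object$spec, group = t(g), dic = object$dic,
              rhat = object$rhat, converged = object$converged)
  class(out) <- "summary.svo_fit"
  out
}

#' @export
print.summary.svo_fit <- function(x, ...) {
  cat(sprintf("%s family, %s scheme; DIC = %.1f\n", x$spec$family,
              x$spec$scheme, x$dic$dic))
  cat("Group-level posterior:\n")
  print(round(x$group, 3))
  invisible(x)
}

#' MAP parameter table for all participants
#'
#' @param object an `svo_fit`.
#' @param ... unused.
#' @return matrix, participants x parameters, of KDE-mode MAP estimates
#'   (natural scale).
#' @export
coef.svo_fit <- function(object, ...) {
  pars <- PAR_NAMES[active_cols(object$spec$scheme)]
  out <- sapply(pars, function(p)
    vapply(seq_along(object$participants), function(i)
      kde_mode(as.numeric(object$draws[, p, i, ])), 0))
  rownames(out) <- object$participants
  out
}

#' Posterior-predictive default-choice probabilities
#'
#' @param object an `svo_fit`.
#' @param newdata data frame with `pi_self`, `pi_other`.
#' @param participant id or index.
#' @param phase `"before"` or `"after"`.
#' @param ... unused.
#' @return probability of choosing the default on each trial at the
#'   participant's MAP parameters.
#' @export
predict.svo_fit <- function(object, newdata, participant = 1,
                            phase = c("before", "after"), ...) {
  phase <- match.arg(phase)
  pars <- list(
    attitude = map_estimate(object, "attitude", participant, phase),
    variability = map_estimate(object, "variability", participant, phase),
    bias_kappa = map_estimate(object, "kappa", participant, phase),
    lapse_epsilon = map_estimate(object, "epsilon", participant, phase))
  choice_prob_default(newdata$pi_self, newdata$pi_other, pars,
                      object$spec$family)
}

#' Simulate choice records from a fitted model
#'
#' @param object an `svo_fit`.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param trials data frame of allocations (`pi_self`, `pi_other`); one
#'   phase's worth, replayed for both phases.
#' @param ... unused.
#' @export
simulate.svo_fit <- function(object, nsim = 1, seed = 1L, trials, ...) {
  withr_seed(seed, {
    reps <- lapply(seq_len(nsim), function(r) {
      do.call(rbind, lapply(seq_along(object$participants), function(i) {
        do.call(rbind, lapply(c("before", "after"), function(ph) {
          p <- predict(object, trials, i, ph)
          data.frame(participant_id = object$participants[i], phase = ph,
                     trial_index = seq_len(nrow(trials)) - 1L,
                     pi_self = trials$pi_self, pi_other = trials$pi_other,
                     choice = as.integer(stats::runif(nrow(trials)) > p))
        }))
      }))
    })
    if (nsim == 1) reps[[1]] else reps
  })
}

#' @export
plot.svo_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("mean_attitude", "sd_attitude", "mean_log_variability",
              "mean_kappa")) {
    d <- stats::density(as.numeric(x$group_draws[, p, ]))
    plot(d, main = p, xlab = p, ...)
  }
  invisible(x)
}

#' Serialise a fit to a directory
#'
#' Writes `draws.csv` (participant, phase, parameter, chain, iteration,
#' value), `dic.json` and `diagnostics.json`.
#'
#' @param fit an `svo_fit`.
#' @param dir output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kept <- dim(fit$draws)[1]
  rows <- expand.grid(iteration = seq_len(kept), parameter = PAR_NAMES,
                      participant = fit$participants,
                      chain = seq_len(fit$mcmc$chains),
                      stringsAsFactors = FALSE)
  rows$value <- as.numeric(fit$draws)
  rows$phase <- sub(".*_", "", rows$parameter)
  rows$parameter <- sub("_(before|after)$", "", rows$parameter)
  utils::write.csv(rows[c("participant", "phase", "parameter", "chain",
                          "iteration", "value")],
                   file.path(dir, "draws.csv"), row.names = FALSE)
  jsonlite::write_json(fit$dic, file.path(dir, "dic.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(rhat = as.list(round(fit$rhat, 4)),
                            converged = fit$converged),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
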