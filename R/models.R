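#' Subjective value of an allocation
#'
#' The one-parameter SVO utility: `V = pi_self + tan(alpha) * pi_other`.
#' `tan(alpha)` is the exchange rate between points for the other and points
#' for oneself (at alpha = 30 degrees, one point for the other is worth about
#' 0.58 own points). Attitudes must lie strictly inside (-90, 90) degrees.
#'
#' @param pi_self,pi_other points for self and other. Vectorised.
#' @param attitude_alpha social attitude in degrees.
#' @return subjective value(s).
#' @export
utility <- function(pi_self, pi_other, attitude_alpha) {
  check_attitude(attitude_alpha)
  pi_self + tan(attitude_alpha * pi / 180) * pi_other
}

check_attitude <- function(alpha) {
  if (any(abs(alpha) >= 90))
    stop("attitude must lie strictly within (-90, 90) degrees")
  invisible(alpha)
}

#' Subjective value of the default allocation with bias
#'
#' The default option pays (100, 50). The bias kappa acts as penalty (kappa >
#' 0) or bonus (kappa < 0) points on the default, capturing a demand-driven
#' propensity to pick alternatives regardless of their payoffs:
#' `V(D) = 100 + tan(alpha) * 50 - kappa`.
#'
#' @inheritParams utility
#' @param bias_kappa bias in points.
#' @export
default_value <- function(attitude_alpha, bias_kappa = 0) {
  check_attitude(attitude_alpha)
  100 + tan(attitude_alpha * pi / 180) * 50 - bias_kappa
}

#' Indifference attitude of a trial
#'
#' The attitude at which the alternative and the (possibly biased) default
#' have equal subjective value: `T_alpha = atan((pi_self - 100 + kappa) /
#' (50 - pi_other))`, in degrees. Trials with `pi_other == 50` have no
#' indifference attitude (the value difference does not involve the
#' attitude) and raise an error.
#'
#' @inheritParams default_value
#' @export
threshold_alpha <- function(pi_self, pi_other, bias_kappa = 0) {
  if (any(pi_other == 50))
    stop("pi_other == 50: attitude-independent trial, threshold undefined")
  atan((pi_self - 100 + bias_kappa) / (50 - pi_other)) * 180 / pi
}

#' Model-based probability of choosing the default allocation
#'
#' `p_default_stable` is the Stable Attitude (softmax / logit) rule: the
#' attitude alpha is a fixed trait and choice noise comes from value
#' comparison errors with temperature tau, `logit(Pr(D)) = (V_D - V_A) /
#' tau`. `p_default_variable` is the Variable Attitude (random preference)
#' rule: on each trial the acted-on attitude is drawn from Normal(mu, sigma)
#' and compared with the trial's indifference threshold; the default's
#' probability is the attitude mass on its side of the threshold,
#' `Phi((T_alpha - mu)/sigma)` on prosocial trials and `Phi((mu -
#' T_alpha)/sigma)` on antisocial ones. Trials with `pi_other == 50` are
#' attitude-free: the stable rule reduces to `logit(Pr(A)) = (pi_self - 100 +
#' kappa)/tau` and the variable rule to the 0/1 step of `sign(pi_self - 100 +
#' kappa)` (0.5 at exact equality). Both return the probability before lapse
#' mixing.
#'
#' @param pi_self,pi_other trial payoffs. Vectorised.
#' @param attitude degrees: the fixed alpha (stable) or the centre mu
#'   (variable).
#' @param variability tau in value points (stable) or sigma in degrees
#'   (variable); must be positive.
#' @param bias_kappa default-penalty bias in points.
#' @return probability of choosing the default, in (0, 1) on non-degenerate
#'   trials.
#' @export
p_default_stable <- function(pi_self, pi_other, attitude, variability,
                             bias_kappa = 0) {
  stopifnot(variability > 0)
  check_attitude(attitude)
  dv <- (100 - bias_kappa - pi_self) +
    tan(attitude * pi / 180) * (50 - pi_other)
  stats::plogis(dv / variability)
}

#' @rdname p_default_stable
#' @export
p_default_variable <- function(pi_self, pi_other, attitude, variability,
                               bias_kappa = 0) {
  stopifnot(variability > 0)
  check_attitude(attitude)
  n <- max(length(pi_self), length(pi_other), length(attitude),
           length(variability), length(bias_kappa))
  pi_self <- rep_len(pi_self, n); pi_other <- rep_len(pi_other, n)
  attitude <- rep_len(attitude, n); variability <- rep_len(variability, n)
  bias_kappa <- rep_len(bias_kappa, n)
  p <- numeric(n)
  deg <- pi_other == 50
  if (any(!deg)) {
    ta <- threshold_alpha(pi_self[!deg], pi_other[!deg], bias_kappa[!deg])
    z <- (ta - attitude[!deg]) / variability[!deg]
    z[pi_other[!deg] < 50] <- -z[pi_other[!deg] < 50]
    p[!deg] <- stats::pnorm(z)
  }
  if (any(deg)) {
    adv <- pi_self[deg] - 100 + bias_kappa[deg]
    p[deg] <- ifelse(adv > 0, 0, ifelse(adv < 0, 1, 0.5))
  }
  p
}

#' Mix a model probability with uniform lapses
#'
#' With probability epsilon the response is a coin flip (inattention,
#' mistyping), so `Pr(D) = (1 - eps) * p_model + eps / 2`. Maps [0, 1] into
#' [eps/2, 1 - eps/2].
#'
#' @param p_model model-based probability in [0, 1].
#' @param lapse_epsilon lapse probability in [0, 1].
#' @export
apply_lapse <- function(p_model, lapse_epsilon) {
  stopifnot(all(p_model >= 0 & p_model <= 1),
            all(lapse_epsilon >= 0 & lapse_epsilon <= 1))
  (1 - lapse_epsilon) * p_model + lapse_epsilon / 2
}

#' Specify one of the six cognitive model variants
#'
#' Two families (stable softmax vs. variable random-preference) crossed with
#' three parameter schemes: `"full"` (attitude and variability both estimated
#' separately before and after the manipulation phase), `"shared_attitude"`
#' (one attitude across the whole task) and `"shared_variability"` (one
#' tau/sigma across the whole task). Bias kappa and lapse epsilon are always
#' phase-specific.
#'
#' @param family `"stable"` or `"variable"`.
#' @param scheme `"full"`, `"shared_attitude"` or `"shared_variability"`.
#' @export
model_spec <- function(family = c("variable", "stable"),
                       scheme = c("full", "shared_attitude",
                                  "shared_variability")) {
  out <- list(family = match.arg(family), scheme = match.arg(scheme))
  class(out) <- "model_spec"
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model spec: %s attitude family, %s scheme\n",
              x$family, x$scheme))
  invisible(x)
}

#' All six model specifications
#' @export
all_model_specs <- function() {
  specs <- expand.grid(family = c("variable", "stable"),
                       scheme = c("full", "shared_attitude",
                                  "shared_variability"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(specs)),
         function(i) model_spec(specs$family[i], specs$scheme[i]))
}

#' Per-trial default-choice probabilities after lapse mixing
#'
#' @param pi_self,pi_other trial payoffs.
#' @param params named list or vector with `attitude`, `variability`,
#'   `bias_kappa`, `lapse_epsilon`.
#' @param family `"stable"` or `"variable"`.
#' @export
choice_prob_default <- function(pi_self, pi_other, params,
                                family = c("variable", "stable")) {
  family <- match.arg(family)
  f <- if (family == "stable") p_default_stable else p_default_variable
  p <- f(pi_self, pi_other, params[["attitude"]], params[["variability"]],
         params[["bias_kappa"]])
  apply_lapse(p, params[["lapse_epsilon"]])
}

#' Log-likelihood of a participant's choices
#'
#' Sums the log probability of the observed choice over all non-missing
#' trials, composing the family's choice rule with lapse mixing. Parameters
#' are supplied per phase; under a shared scheme the tied parameter must be
#' equal across the supplied phases (enforced). Probabilities are floored at
#' 1e-300 before the log. Reference implementation in plain R; the fitting
#' routine uses a compiled equivalent that is tested against this function.
#'
#' @param records data frame with columns `pi_self`, `pi_other`, `phase`
#'   (`"before"`/`"after"`) and `choice` (0 = default, 1 = alternative, NA =
#'   missing).
#' @param params_by_phase named list, e.g. `list(before = p1, after = p2)`,
#'   each element a named list/vector with `attitude`, `variability`,
#'   `bias_kappa`, `lapse_epsilon`.
#' @param spec a [model_spec()].
#' @return the summed log-likelihood (0, with a warning, for no usable
#'   trials).
#' @export
log_likelihood <- function(records, params_by_phase, spec = model_spec()) {
  records <- records[!is.na(records$choice), , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no non-missing trials; log-likelihood is 0")
    return(0)
  }
  tied <- switch(spec$scheme, shared_attitude = "attitude",
                 shared_variability = "variability", NULL)
  phases <- intersect(c("before", "after"), unique(records$phase))
  if (!is.null(tied) && length(phases) > 1) {
    vals <- vapply(params_by_phase[phases], function(p) p[[tied]], 0)
    if (diff(range(vals)) > 1e-12)
      stop("scheme ties ", tied, " across phases but values differ")
  }
  ll <- 0
  for (ph in phases) {
    r <- records[records$phase == ph, , drop = FALSE]
    p_def <- choice_prob_default(r$pi_self, r$pi_other,
                                 params_by_phase[[ph]], spec$family)
    p_obs <- ifelse(r$choice == 0, p_def, 1 - p_def)
    ll <- ll + sum(log(pmax(p_obs, 1e-300)))
  }
  ll
}
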