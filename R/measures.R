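#' Model-free attitude classification from before-phase choices
#'
#' Sums, over every trial where the alternative was chosen, the half polar
#' angle of that alternative: `atan((pi_o - 50) / (sqrt((pi_y - 50)^2 +
#' (pi_o - 50)^2) + pi_y - 50))` (the tangent half-angle identity), in
#' degrees. Prosocial choices push the score up, antisocial ones down, more
#' extreme choices count more. Degenerate trials (`pi_other == 50`) and
#' missing responses are excluded. A score of exactly zero (e.g. no
#' alternative ever chosen) classifies as prosocial by the tie rule.
#'
#' @param before_records data frame with `pi_self`, `pi_other`, `choice`
#'   (0 default, 1 alternative, NA missing).
#' @return list with `class` (`"prosocial"`/`"antisocial"`) and `score`
#'   (degrees).
#' @export
classify_attitude <- function(before_records) {
  r <- before_records[!is.na(before_records$choice) &
                        before_records$pi_other != 50, , drop = FALSE]
  if (nrow(r) == 0)
    stop("no scorable trials (all missing or degenerate)")
  chosen <- r[r$choice == 1, , drop = FALSE]
  score <- 0
  if (nrow(chosen) > 0) {
    dy <- chosen$pi_self - 50
    do <- chosen$pi_other - 50
    score <- sum(atan(do / (sqrt(dy^2 + do^2) + dy))) * 180 / pi
  }
  list(class = if (score >= 0) "prosocial" else "antisocial", score = score)
}

#' Attitude convergence towards the observed agent
#'
#' `delta_diff = |alpha_before - alpha_obs| - |alpha_after - alpha_obs|`:
#' positive when the participant ends up closer to the agent's attitude,
#' negative when they move away or overshoot past the agent to a larger
#' distance. Vectorised.
#'
#' @param alpha_before,alpha_after participant attitude in degrees.
#' @param alpha_obs agent attitude in degrees.
#' @export
attitude_convergence <- function(alpha_before, alpha_after, alpha_obs) {
  stopifnot(all(is.finite(c(alpha_before, alpha_after, alpha_obs))))
  abs(alpha_before - alpha_obs) - abs(alpha_after - alpha_obs)
}

#' Attitude polarisation in the agent's direction
#'
#' `delta_alpha = sign(alpha_obs) * (alpha_after - alpha_before)`: positive
#' when the attitude moves in the agent's direction, without penalising
#' overshoot. Vectorised.
#'
#' @inheritParams attitude_convergence
#' @export
attitude_polarisation <- function(alpha_before, alpha_after, alpha_obs) {
  stopifnot(all(alpha_obs != 0))
  sign(alpha_obs) * (alpha_after - alpha_before)
}

#' Compliance index from before-phase choices
#'
#' The smaller of the percentage of prosocial alternatives and the
#' percentage of antisocial alternatives chosen over the default, among
#' answered trials. A participant who exhibits both behaviours at a
#' substantial rate is suspected of complying with presumed experimenter
#' demand rather than expressing an attitude. Undefined (NA with a warning)
#' when a participant answered no prosocial or no antisocial trials; such
#' participants are excluded from compliance analyses.
#'
#' @param before_records data frame with `pi_self`, `pi_other`, `choice`.
#' @return percentage in [0, 100], or NA when undefined.
#' @export
compliance_index <- function(before_records) {
  r <- before_records[!is.na(before_records$choice), , drop = FALSE]
  pro <- r$pi_other > 50
  anti <- r$pi_other < 50
  if (!any(pro) || !any(anti)) {
    warning("compliance index undefined: no answered prosocial or ",
            "antisocial trials")
    return(NA_real_)
  }
  min(100 * mean(r$choice[pro] == 1), 100 * mean(r$choice[anti] == 1))
}

#' Compliance flag
#'
#' Inclusive at the boundary: compliant means choosing both prosocial and
#' antisocial alternatives at least once out of every four choices.
#'
#' @param index compliance index in percent.
#' @param threshold percent threshold (default 25).
#' @export
is_compliant <- function(index, threshold = 25) {
  stopifnot(all(is.na(index) | (index >= 0 & index <= 100)))
  index >= threshold
}

#' Change in choice consistency
#'
#' `sigma_before - sigma_after` in degrees (or tau in points for the stable
#' family): positive means the participant became more consistent after the
#' manipulation phase.
#'
#' @param sigma_before,sigma_after positive variability estimates.
#' @export
consistency_change <- function(sigma_before, sigma_after) {
  stopifnot(all(sigma_before > 0), all(sigma_after > 0))
  sigma_before - sigma_after
}

#' Per-participant measures table
#'
#' Assembles the derived quantities used by the statistical battery from
#' per-participant parameter estimates and before-phase choice records.
#'
#' @param params data frame with columns `participant_id`, `condition`,
#'   `alpha_before`, `alpha_after`, `sigma_before`, `sigma_after`,
#'   `kappa_before`, `alpha_obs`.
#' @param records choice records for the before phase (all participants),
#'   with `participant_id`.
#' @param threshold compliance threshold in percent.
#' @return data frame with the input columns plus `delta_diff`,
#'   `delta_alpha`, `compliance_index`, `compliant`, `consistency_change`.
#' @export
measures_table <- function(params, records, threshold = 25) {
  idx <- vapply(params$participant_id, function(id) {
    r <- records[records$participant_id == id, , drop = FALSE]
    if (nrow(r) == 0) return(NA_real_)
    suppressWarnings(compliance_index(r))
  }, 0)
  out <- params
  out$delta_diff <- attitude_convergence(params$alpha_before,
                                         params$alpha_after,
                                         params$alpha_obs)
  out$delta_alpha <- attitude_polarisation(params$alpha_before,
                                           params$alpha_after,
                                           params$alpha_obs)
  out$compliance_index <- idx
  out$compliant <- is_compliant(idx, threshold)
  out$consistency_change <- consistency_change(params$sigma_before,
                                               params$sigma_after)
  out
}

#' Write the measures table as CSV
#' @param measures output of [measures_table()].
#' @param path file path.
#' @export
write_measures <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE)
  invisible(path)
}
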