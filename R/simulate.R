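#' Simulate one switching cohort
#'
#' Draws one replicate of a two-arm treatment-naive cohort.  Latent
#' adverse-event times are i.i.d. Weibull (the [stats::rweibull()]
#' parameterization), identical in both arms under the null and unaffected
#' by switching.  Switching is assigned at baseline by an independent
#' Bernoulli draw with probability `switch_prop` and a common switching
#' time; an assigned switcher becomes an *observed* switcher only if still
#' event-free and uncensored strictly beyond the switching time
#' (`latent_event_time > switch_time`, so an event exactly at the switching
#' time counts as pre-switch).  Follow-up is administratively censored at
#' the horizon.
#'
#' The draw is deterministic given `(config$seed, config$scenario_id,
#' rep_index)`: each replicate uses its own derived substream, so replicates
#' are independently re-runnable and study results are schedule-independent.
#'
#' @param config a [scenario_config()].
#' @param rep_index replicate counter, a non-negative integer.
#' @return A `data.frame` with one row per subject and columns
#'   `subject_id`, `initial_arm` (factor, `CD`/`TD`), `latent_event_time`,
#'   `followup_time`, `event` (logical), `switch_assigned`,
#'   `observed_switch` (logical), `switch_time` (`NA` unless the switch is
#'   observed).
#' @examples
#' cfg <- scenario_config(1, shape = 1, scale = 4, switch_time = 1,
#'                        switch_prop = 0.3, n_td = 50, n_cd = 50)
#' coh <- simulate_cohort(cfg, rep_index = 1)
#' table(coh$initial_arm, coh$observed_switch)
#' @export
simulate_cohort <- function(config, rep_index = 0L) {
  validate_scenario_config(config)
  if (!is.numeric(rep_index) || length(rep_index) != 1L || rep_index < 0) {
    stop(config_error("rep_index must be a single non-negative integer"))
  }
  n <- config$n_td + config$n_cd
  arm <- factor(rep(c("TD", "CD"), c(config$n_td, config$n_cd)),
                levels = c("CD", "TD"))

  set.seed(substream_seed(config$seed, config$scenario_id, rep_index))
  latent <- numeric(n)
  is_td <- arm == "TD"
  latent[is_td]  <- stats::rweibull(config$n_td, config$shape, config$scale)
  latent[!is_td] <- stats::rweibull(config$n_cd, config$shape, config$scale_cd)
  assigned <- stats::rbinom(n, 1L, config$switch_prop) == 1L

  followup <- pmin(latent, config$admin_censor)
  event <- latent <= config$admin_censor
  observed <- assigned & latent > config$switch_time &
    config$switch_time < config$admin_censor

  data.frame(
    subject_id = seq_len(n),
    initial_arm = arm,
    latent_event_time = latent,
    followup_time = followup,
    event = event,
    switch_assigned = assigned,
    observed_switch = observed,
    switch_time = ifelse(observed, config$switch_time, NA_real_)
  )
}

# Derived 32-bit substream seed; products stay below 2^53 so the arithmetic
# is exact in doubles on every platform.
substream_seed <- function(seed, scenario_id, rep_index) {
  s <- (abs(as.double(seed)) %% 2100000) * 1009 + as.double(scenario_id)
  s <- (s * 1669 + as.double(rep_index)) %% 2147483647
  as.integer(s)
}

#' Expected number of observed events in a scenario
#'
#' Closed-form companion to [simulate_cohort()]: the expected count of
#' subjects whose adverse event occurs before the administrative censoring
#' horizon, \eqn{(n_{TD}+n_{CD})(1 - \exp(-(c/scale)^{shape}))} (averaging
#' the per-arm Weibull CDFs when the arms differ).  Switching does not
#' affect event times, so the expectation is unchanged by `switch_prop`.
#'
#' @param config a [scenario_config()].
#' @return Expected event count (a real number).
#' @export
expected_event_count <- function(config) {
  validate_scenario_config(config)
  p_arm <- function(scale) {
    stats::pweibull(config$admin_censor, config$shape, scale)
  }
  config$n_td * p_arm(config$scale) + config$n_cd * p_arm(config$scale_cd)
}

#' Expected number of observed switchers per arm
#'
#' An assigned switcher is observed only if event-free at the switching
#' time, so the expected observed-switcher count in an arm of size \eqn{n}
#' is \eqn{n \cdot p_{SW} \cdot S(t_{SW})}.  Used as the binomial oracle
#' for clone counts: under the clock-restart augmentations every observed
#' switcher contributes one clone to the time-0 risk set.
#'
#' @param config a [scenario_config()].
#' @param arm `"CD"` or `"TD"` (the arm switched *from*).
#' @return Expected observed-switcher count in that arm.
#' @export
expected_observed_switchers <- function(config, arm = c("CD", "TD")) {
  arm <- match.arg(arm)
  validate_scenario_config(config)
  scale <- if (arm == "TD") config$scale else config$scale_cd
  n <- if (arm == "TD") config$n_td else config$n_cd
  n * config$switch_prop *
    stats::pweibull(config$switch_time, config$shape, scale, lower.tail = FALSE)
}
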