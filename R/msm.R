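#' Cause-specific transition curves of an approach's multistate representation
#'
#' Decomposes an augmented analysis dataset into the strata of its
#' illness-death representation and estimates each cause-specific cumulative
#' transition hazard with [nelson_aalen()].  States: 0 = on the initiated
#' drug, 1 = switched, 2 = adverse event.
#'
#' For the **hierarchical** approach the strata are: TD starters with their
#' entire follow-up (the numerator's naive-user part), CD starters censored
#' at switch (the denominator), switched-to-TD clones on the chosen
#' timescale (the numerator's prevalent-user part), and the CD 0 to 1
#' switch hazard.  For the **overlapping** approach both arms keep full
#' follow-up, both switch directions are cloned, and both arms' switch
#' hazards are estimated.
#'
#' @param subjects a cohort from [simulate_cohort()].
#' @param approach `"hierarchical"` or `"overlapping"`.
#' @param restart_clock logical, as in [augmentation].
#' @param grid times at which the at-risk table is tabulated; defaults to
#'   0, 1, ..., `ceiling(max follow-up)`.
#' @return An object of class `transition_curves`: `curves` (named list of
#'   `na_estimate`), `strata` (the underlying record sets), `timescale`,
#'   `approach`, `restart_clock`, and `at_risk_table` (`data.frame` of
#'   per-stratum and total at-risk counts over `grid`).  Curve names:
#'   `td_starter_02`, `cd_starter_02`, `switch_to_td_12`, `switch_cd_01`,
#'   and for the overlapping approach also `switch_to_cd_12`,
#'   `switch_td_01`.
#' @examples
#' coh <- simulate_cohort(scenario_config(1, 1, 4, 1, 0.3,
#'                                        n_td = 200, n_cd = 200))
#' tc <- transition_curves(coh, "hierarchical", restart_clock = TRUE)
#' names(tc$curves)
#' @export
transition_curves <- function(subjects,
                              approach = c("hierarchical", "overlapping"),
                              restart_clock = TRUE, grid = NULL) {
  approach <- match.arg(approach)
  validate_subjects(subjects)
  s <- subjects
  ts <- if (restart_clock) "restarted" else "original"

  stratum <- function(sub, arm, exit, event, clone = FALSE, entry = 0) {
    if (nrow(sub) == 0L) {
      return(data.frame(subject_id = integer(), clone = logical(),
                        arm = character(), entry = numeric(),
                        exit = numeric(), event = logical(),
                        timescale = character()))
    }
    data.frame(subject_id = sub$subject_id, clone = clone, arm = arm,
               entry = entry, exit = exit, event = event, timescale = ts)
  }
  clone_stratum <- function(sub, arm) {
    stratum(sub, arm,
            entry = if (restart_clock) 0 else sub$switch_time,
            exit = if (restart_clock) sub$followup_time - sub$switch_time
                   else sub$followup_time,
            event = sub$event, clone = TRUE)
  }

  td <- s[s$initial_arm == "TD", , drop = FALSE]
  cd <- s[s$initial_arm == "CD", , drop = FALSE]
  cd_sw <- cd[cd$observed_switch, , drop = FALSE]
  td_sw <- td[td$observed_switch, , drop = FALSE]

  strata <- list(
    # TD starters, full follow-up (attribution keeps them on TD throughout)
    td_starter_02 = stratum(td, "TD", td$followup_time, td$event),
    # CD starters: hierarchical censors at switch; overlapping keeps all
    cd_starter_02 = if (approach == "hierarchical") {
      stratum(cd, "CD",
              exit = ifelse(cd$observed_switch, cd$switch_time,
                            cd$followup_time),
              event = cd$event & !cd$observed_switch)
    } else {
      stratum(cd, "CD", cd$followup_time, cd$event)
    },
    switch_to_td_12 = clone_stratum(cd_sw, "TD"),
    # 0 -> 1 switch hazard out of CD: switchers exit at the switch with the
    # transition; everyone else is at risk of switching until event/censoring
    switch_cd_01 = stratum(cd, "CD",
                           exit = ifelse(cd$observed_switch, cd$switch_time,
                                         cd$followup_time),
                           event = cd$observed_switch)
  )
  if (approach == "overlapping") {
    strata$switch_to_cd_12 <- clone_stratum(td_sw, "CD")
    strata$switch_td_01 <- stratum(td, "TD",
                                   exit = ifelse(td$observed_switch,
                                                 td$switch_time,
                                                 td$followup_time),
                                   event = td$observed_switch)
  }

  curves <- lapply(strata, nelson_aalen)
  if (is.null(grid)) {
    grid <- seq(0, ceiling(max(s$followup_time)), by = 1)
  }
  # risk sets just after t (entry <= t < exit): matches "number at risk at t"
  # as printed under survival plots, so t = 0 counts starters plus any
  # restarted clones
  risk_after <- function(st, t) {
    vapply(t, function(u) sum(st$entry <= u & st$exit > u), 0L)
  }
  art <- data.frame(time = grid)
  for (nm in names(strata)) art[[nm]] <- risk_after(strata[[nm]], grid)
  failure_strata <- intersect(
    c("td_starter_02", "cd_starter_02", "switch_to_td_12", "switch_to_cd_12"),
    names(strata))
  art$total <- rowSums(art[failure_strata])

  structure(list(curves = curves, strata = strata, timescale = ts,
                 approach = approach, restart_clock = restart_clock,
                 at_risk_table = art),
            class = "transition_curves")
}

#' @export
print.transition_curves <- function(x, ...) {
  cat(sprintf("Transition curves: %s approach, %s timescale\n", x$approach,
              x$timescale))
  for (nm in names(x$curves)) {
    k <- length(x$curves[[nm]]$jump_times)
    cat(sprintf("  %-16s %5d jumps, A(max) = %.4g\n", nm, k,
                if (k) max(x$curves[[nm]]$cumulative) else 0))
  }
  invisible(x)
}

#' Hazard-ratio decomposition of a switching estimator
#'
#' Expresses the approach's hazard ratio as a ratio of composite cumulative
#' hazards built from the cause-specific transition curves.  The numerator
#' mixes, at each time, the TD starters' failure-hazard increment with the
#' switched-to-TD transition-hazard increment, weighted by
#' \eqn{\hat P_{TD}(t)} — the at-risk fraction of TD starters among all
#' rows at risk in the numerator strata, evaluated on the analysis
#' timescale of the chosen variant (for the clock-restarted variant that is
#' the "world" where switchers' clocks were reset, so the shifted hazard is
#' already embedded in the strata).  The hierarchical denominator is the CD
#' starters' hazard censored at switch; the overlapping denominator is the
#' symmetric mixture with \eqn{\hat P_{CD}(t)}.
#'
#' Cumulative hazards (not raw increments, which are noisy atoms) are mixed
#' over grid intervals, matching the use of cumulative Nelson-Aalen plots
#' and the identity \eqn{\exp(\hat\beta) \approx \hat A_{TD}/\hat A_{CD}}
#' under proportional hazards.
#'
#' @param curves a [transition_curves()] object.
#' @param grid evaluation times; default 200 equally spaced points on
#'   `(0, max jump time]`.
#' @return An object of class `hr_decomposition`: `grid`, `p_td`, `p_cd`
#'   (`NA` for the hierarchical approach), `numerator` and `denominator`
#'   (composite cumulative hazards per grid point), `hr_curve` (their
#'   ratio, `NA` flagged where the denominator risk set is empty or the
#'   denominator is 0).
#' @export
hr_decomposition <- function(curves, grid = NULL) {
  stopifnot(inherits(curves, "transition_curves"))
  cv <- curves$curves
  st <- curves$strata
  if (is.null(grid)) {
    horizon <- max(unlist(lapply(st, function(x) x$exit)), 0)
    grid <- seq(0, horizon, length.out = 201L)[-1L]
  }
  grid <- sort(grid)

  at_risk <- function(stratum, t) {
    vapply(t, function(u) sum(stratum$entry < u & stratum$exit >= u), 0L)
  }
  # mixing weights at interval starts: composition of the risk set just
  # prior to the increment being accrued
  left <- c(0, grid[-length(grid)])
  wt_left <- function(a, b) {
    ya <- at_risk(a, pmax(left, .Machine$double.eps))
    yb <- at_risk(b, pmax(left, .Machine$double.eps))
    tot <- ya + yb
    ifelse(tot > 0, ya / tot, 1)
  }
  dA <- function(est) diff(c(0, na_at(est, grid)))
  mix <- function(p, a, b) cumsum(p * dA(a) + (1 - p) * dA(b))

  p_td <- wt_left(st$td_starter_02, st$switch_to_td_12)
  numerator <- mix(p_td, cv$td_starter_02, cv$switch_to_td_12)

  if (curves$approach == "hierarchical") {
    p_cd <- rep(NA_real_, length(grid))
    denominator <- na_at(cv$cd_starter_02, grid)
    denom_empty <- at_risk(st$cd_starter_02, grid) == 0
  } else {
    p_cd <- wt_left(st$cd_starter_02, st$switch_to_cd_12)
    denominator <- mix(p_cd, cv$cd_starter_02, cv$switch_to_cd_12)
    denom_empty <- (at_risk(st$cd_starter_02, grid) +
                      at_risk(st$switch_to_cd_12, grid)) == 0
  }
  hr <- ifelse(!denom_empty & denominator > 0, numerator / denominator,
               NA_real_)
  structure(list(grid = grid, p_td = p_td, p_cd = p_cd,
                 numerator = numerator, denominator = denominator,
                 hr_curve = hr, approach = curves$approach,
                 timescale = curves$timescale),
            class = "hr_decomposition")
}

#' @export
print.hr_decomposition <- function(x, ...) {
  k <- length(x$grid)
  cat(sprintf(
    "HR decomposition (%s, %s timescale): HR(horizon %.3g) = %.4g\n",
    x$approach, x$timescale, x$grid[k], x$hr_curve[k]))
  invisible(x)
}

#' Empirical-mixture transition hazard of the switched stratum
#'
#' The observable marginal transition hazard of the patients who switched
#' out of `arm_of_origin`, with each switcher's clock shifted back by their
#' *own* switching time: the pooled Nelson-Aalen estimate over the
#' individually restarted post-switch records \eqn{(0, T_i - t_{SW,i}]}.
#' When all switching times coincide (the common-switch-time design) this
#' reduces exactly to the shifted single switched-stratum curve.
#'
#' @param subjects a cohort `data.frame`; individual `switch_time` values
#'   are honored, so hand-built cohorts with distinct switching times work.
#' @param arm_of_origin `"CD"` (switchers to TD) or `"TD"` (switchers to
#'   CD).
#' @return An `na_estimate` on the restarted timescale; empty (cumulative
#'   identically 0) when there are no observed switchers from that arm.
#' @export
empirical_mixture_hazard <- function(subjects, arm_of_origin = c("CD", "TD")) {
  arm_of_origin <- match.arg(arm_of_origin)
  validate_subjects(subjects)
  sw <- subjects[subjects$initial_arm == arm_of_origin &
                   subjects$observed_switch, , drop = FALSE]
  to_arm <- if (arm_of_origin == "CD") "TD" else "CD"
  rec <- if (nrow(sw) == 0L) {
    data.frame(subject_id = integer(), clone = logical(), arm = character(),
               entry = numeric(), exit = numeric(), event = logical(),
               timescale = character())
  } else {
    data.frame(subject_id = sw$subject_id, clone = TRUE, arm = to_arm,
               entry = 0, exit = sw$followup_time - sw$switch_time,
               event = sw$event, timescale = "restarted")
  }
  nelson_aalen(rec)
}
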