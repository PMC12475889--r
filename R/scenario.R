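#' Scenario configuration for a switching cohort simulation
#'
#' Bundles the parameters of one simulation scenario: the Weibull
#' adverse-event-time distribution shared by both arms under the null, the
#' common switching time, the baseline switching proportion, the arm sizes
#' and the administrative censoring horizon.
#'
#' The Weibull parameterization follows [stats::rweibull()]: survival
#' \eqn{S(t) = \exp(-(t/scale)^{shape})}, hazard
#' \eqn{\alpha(t) = (shape/scale)(t/scale)^{shape-1}}.  A shape of 1 gives a
#' constant hazard of rate \eqn{1/scale} per year.
#'
#' @param scenario_id integer label for the scenario.
#' @param shape Weibull shape (dimensionless, > 0).
#' @param scale Weibull scale in years (> 0) for the TD arm (and for the CD
#'   arm unless `scale_cd` is given).
#' @param switch_time common switching time in years (> 0).
#' @param switch_prop baseline switching proportion in `[0, 1]`; assigned at
#'   baseline by a Bernoulli draw, independent of the event time.
#' @param n_td,n_cd arm sizes (treatment-naive initiators of the test drug
#'   and the comparator drug).
#' @param admin_censor administrative censoring horizon in years;
#'   `switch_time` must not exceed it.
#' @param n_reps number of simulation replicates a study run performs.
#' @param seed base random seed; per-replicate substreams are derived from
#'   `(seed, scenario_id, rep_index)`.
#' @param scale_cd optional CD-arm Weibull scale in years.  Defaults to
#'   `scale` (the null hypothesis of equal hazards); set it differently only
#'   to generate alternative-hypothesis cohorts for parameter-recovery
#'   checks, with `switch_prop = 0`.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(1, shape = 1, scale = 4, switch_time = 1,
#'                        switch_prop = 0.3)
#' expected_event_count(cfg)
#' @export
scenario_config <- function(scenario_id, shape, scale, switch_time,
                            switch_prop, n_td = 3000L, n_cd = 3000L,
                            admin_censor = 8, n_reps = 1000L, seed = 1L,
                            scale_cd = NULL) {
  cfg <- list(
    scenario_id = as.integer(scenario_id),
    shape = as.numeric(shape),
    scale = as.numeric(scale),
    scale_cd = if (is.null(scale_cd)) as.numeric(scale) else as.numeric(scale_cd),
    switch_time = as.numeric(switch_time),
    switch_prop = as.numeric(switch_prop),
    n_td = as.integer(n_td),
    n_cd = as.integer(n_cd),
    admin_censor = as.numeric(admin_censor),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(config_error(sprintf("invalid scenario field '%s': %s", field, msg)))
    }
  }
  num_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  chk(num_pos(cfg$shape), "shape", "must be a single positive number")
  chk(num_pos(cfg$scale), "scale", "must be a single positive number")
  chk(num_pos(cfg$scale_cd), "scale_cd", "must be a single positive number")
  chk(num_pos(cfg$switch_time), "switch_time", "must be a single positive number")
  chk(num_pos(cfg$admin_censor), "admin_censor", "must be a single positive number")
  chk(cfg$switch_time <= cfg$admin_censor, "switch_time",
      "must not exceed admin_censor")
  chk(is.numeric(cfg$switch_prop) && length(cfg$switch_prop) == 1L &&
        cfg$switch_prop >= 0 && cfg$switch_prop <= 1,
      "switch_prop", "must lie in [0, 1]")
  chk(is.integer(cfg$n_td) && cfg$n_td >= 1L, "n_td", "must be a positive integer")
  chk(is.integer(cfg$n_cd) && cfg$n_cd >= 1L, "n_cd", "must be a positive integer")
  chk(is.integer(cfg$n_reps) && cfg$n_reps >= 1L, "n_reps",
      "must be a positive integer")
  chk(is.integer(cfg$seed) && !is.na(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

config_error <- function(msg) {
  structure(class = c("switchclone_config_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario %d: Weibull(shape %.3g, scale %.4g)%s, switch at %.3g y (%.0f%%),\n  %d TD + %d CD starters, censored at %.3g y, %d reps, seed %d\n",
    x$scenario_id, x$shape, x$scale,
    if (x$scale_cd != x$scale) sprintf(" [CD scale %.4g]", x$scale_cd) else "",
    x$switch_time, 100 * x$switch_prop, x$n_td, x$n_cd, x$admin_censor,
    x$n_reps, x$seed))
  invisible(x)
}

#' Load scenario configurations from a YAML file
#'
#' Reads a scenario table in the packaged YAML layout: a `defaults` block
#' (arm sizes, censoring horizon, replicates, seed) and a `scenarios` list
#' with per-row `id`, `shape`, `scale`, `switch_time`, `switch_prop`.
#' Per-scenario entries override defaults.
#'
#' @param path path to a YAML file; defaults to the packaged table of the 22
#'   study scenarios (`table1_scenarios.yaml`).
#' @param seed if not `NULL`, overrides the base seed of every scenario.
#' @return A named list of [scenario_config()] objects (names `"1"`,
#'   `"2"`, ...).
#' @examples
#' scen <- scenario_table()
#' length(scen)      # 22
#' scen[["3"]]
#' @export
scenario_table <- function(path = NULL, seed = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_scenarios.yaml",
                        package = "switchclone", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenarios)) {
    stop(config_error("malformed scenario file: no 'scenarios' block"))
  }
  defaults <- raw$defaults %||% list()
  cfgs <- lapply(raw$scenarios, function(row) {
    p <- utils::modifyList(defaults, row)
    if (is.null(p$id)) stop(config_error("scenario row without an 'id'"))
    scenario_config(
      scenario_id = p$id, shape = p$shape, scale = p$scale,
      switch_time = p$switch_time, switch_prop = p$switch_prop,
      n_td = p$n_td %||% 3000L, n_cd = p$n_cd %||% 3000L,
      admin_censor = p$admin_censor %||% 8,
      n_reps = p$n_reps %||% 1000L,
      seed = if (!is.null(seed)) seed else p$seed %||% 1L
    )
  })
  names(cfgs) <- vapply(cfgs, function(c) as.character(c$scenario_id), "")
  cfgs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
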