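#' CSV interchange for cohorts, records and study results
#'
#' All stages exchange plain CSV (RFC 4180, header row, `.` decimal):
#' cohorts as one row per subject, augmented datasets in the
#' counting-process start/stop layout any standard survival fitter
#' consumes, and study results as one row per scenario-variant.  Readers
#' restore the column types the in-memory structures use, so a write/read
#' round trip is an identity.
#'
#' @param x the object to write.
#' @param path file path.
#' @return Writers return `path` invisibly; readers return a `data.frame`.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$initial_arm <- factor(d$initial_arm, levels = c("CD", "TD"))
  for (col in c("event", "switch_assigned", "observed_switch")) {
    d[[col]] <- as.logical(d[[col]])
  }
  d$switch_time <- as.numeric(d$switch_time)
  validate_subjects(d)
  d
}

#' @rdname csv_io
#' @export
write_records_csv <- function(x, path) {
  validate_records(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$arm <- factor(d$arm, levels = c("CD", "TD"))
  d$clone <- as.logical(d$clone)
  d$event <- as.logical(d$event)
  validate_records(d)
  d
}

#' @rdname csv_io
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tidy the transition curves of an approach for plotting or export
#'
#' @param tc a [transition_curves()] object.
#' @return A `data.frame` with columns `transition`, `time`, `cum_hazard`
#'   (one row per jump, plus a time-0 anchor per curve).
#' @export
curves_as_table <- function(tc) {
  stopifnot(inherits(tc, "transition_curves"))
  rows <- lapply(names(tc$curves), function(nm) {
    est <- tc$curves[[nm]]
    data.frame(transition = nm,
               time = c(0, est$jump_times),
               cum_hazard = c(0, est$cumulative))
  })
  do.call(rbind, rows)
}

#' Plot cumulative transition hazards
#'
#' Step plot of the Nelson-Aalen cumulative cause-specific transition
#' hazards of one approach's multistate representation, with an at-risk
#' caption at time 0 showing how clock restart inflates the initial risk
#' set.
#'
#' @param tc a [transition_curves()] object.
#' @return A ggplot object.
#' @export
plot_transition_curves <- function(tc) {
  stopifnot(inherits(tc, "transition_curves"))
  d <- curves_as_table(tc)
  n0 <- tc$at_risk_table$total[tc$at_risk_table$time == 0]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cum_hazard,
                                  colour = .data$transition)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(
      title = sprintf("Cumulative transition hazards: %s approach (%s timescale)",
                      tc$approach, tc$timescale),
      caption = sprintf("At risk for failure at time 0: %d", n0),
      x = sprintf("time (years, %s timescale)", tc$timescale),
      y = "cumulative hazard") +
    ggplot2::theme_minimal()
}

#' Plot rejection-rate panels of a study results table
#'
#' Empirical type-1-error by Weibull shape, faceted by switching time
#' (columns) and switching proportion (rows), with approximate 95%
#' Monte-Carlo intervals and the nominal level marked.
#'
#' @param results a results `data.frame` from [run_study()] (or read back
#'   with [read_results_csv()]).
#' @param alpha nominal level to mark, default 0.05.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(results, alpha = 0.05) {
  d <- results
  d$variant <- paste0(d$approach, ifelse(d$restart, " (restart)",
                                         " (no restart)"))
  d$sw_time <- sprintf("switch at %g y", d$switch_time)
  d$sw_prop <- sprintf("%.0f%% switching", 100 * d$switch_prop)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shape, y = .data$rejection_prop,
                                  colour = .data$variant,
                                  group = .data$variant)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$rejection_prop - 1.96 * .data$mc_se),
      ymax = .data$rejection_prop + 1.96 * .data$mc_se),
      position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::facet_grid(sw_prop ~ sw_time) +
    ggplot2::labs(x = "Weibull shape", y = "rejection proportion",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
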