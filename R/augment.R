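#' Clone-and-censor dataset construction
#'
#' `augment_hierarchical()` and `augment_overlapping()` turn a subject-level
#' cohort into the counting-process ("start/stop") analysis dataset of the
#' corresponding treatment-switching approach.  Each output row is an
#' at-risk interval `(entry, exit]` with an event flag and an *attributed*
#' analysis arm — attribution bookkeeping, not current exposure.
#'
#' The **experimental hierarchical** approach is asymmetric: all follow-up
#' after any initiation of the test drug (TD) belongs to TD, so a TD starter
#' keeps a single TD row for the whole follow-up even after switching away,
#' while a comparator-drug (CD) starter who switches to TD is censored on CD
#' at the switch and cloned onto TD for the post-switch period.
#'
#' The **overlapping** approach is symmetric: the initiated drug keeps the
#' entire follow-up, and the post-switch period is *additionally* attributed
#' to the drug switched to, so every observed switcher is cloned and the
#' post-switch time (and any event in it) is counted twice.
#'
#' With `restart_clock = TRUE` a clone re-enters the analysis at time 0 and
#' its interval is `(0, T - s]` — the clone sits in the time-0 risk set next
#' to the treatment-naive starters, which is the source of the
#' type-1-error distortion when the event hazard is time-dependent.  With
#' `restart_clock = FALSE` (the modified variants) the clone keeps the
#' original timescale as a left-truncated / delayed-entry interval `(s, T]`,
#' so it only joins the risk set once it is genuinely at risk on that arm.
#'
#' Zero-length rows cannot arise from [simulate_cohort()] (an observed
#' switch requires `switch_time < followup_time`); should imported data
#' produce any, they are dropped with a warning.
#'
#' @param subjects a cohort `data.frame` as produced by [simulate_cohort()].
#' @param restart_clock logical; restart the clock at switch for clones
#'   (`TRUE`, replicating the approaches as used in practice) or keep the
#'   original timescale with delayed entry (`FALSE`, the modified variants).
#' @return A `data.frame` of records with columns `subject_id`, `clone`
#'   (logical; `TRUE` for duplicated post-switch contributions), `arm`
#'   (factor `CD`/`TD`, the analysis attribution), `entry`, `exit` (years,
#'   `exit > entry`), `event` (logical), and `timescale` (`"restarted"` when
#'   `restart_clock = TRUE`, else `"original"`).
#' @examples
#' coh <- simulate_cohort(scenario_config(1, 1, 4, 1, 0.3,
#'                                        n_td = 100, n_cd = 100))
#' hier <- augment_hierarchical(coh, restart_clock = TRUE)
#' count_clones_at_time_zero(hier)
#' @name augmentation
NULL

#' @rdname augmentation
#' @export
augment_hierarchical <- function(subjects, restart_clock = TRUE) {
  validate_subjects(subjects)
  s <- subjects
  cd_switch <- s$initial_arm == "CD" & s$observed_switch

  # base rows: TD starters keep everything; CD switchers are censored at switch
  base <- data.frame(
    subject_id = s$subject_id,
    clone = FALSE,
    arm = s$initial_arm,
    entry = 0,
    exit = ifelse(cd_switch, s$switch_time, s$followup_time),
    event = s$event & !cd_switch
  )
  clones <- clone_rows(s[cd_switch, , drop = FALSE], to_arm = "TD",
                       restart_clock = restart_clock)
  finish_records(rbind(base, clones), restart_clock)
}

#' @rdname augmentation
#' @export
augment_overlapping <- function(subjects, restart_clock = TRUE) {
  validate_subjects(subjects)
  s <- subjects
  base <- data.frame(
    subject_id = s$subject_id,
    clone = FALSE,
    arm = s$initial_arm,
    entry = 0,
    exit = s$followup_time,
    event = s$event
  )
  sw <- s$observed_switch
  to_arm <- ifelse(s$initial_arm[sw] == "CD", "TD", "CD")
  clones <- clone_rows(s[sw, , drop = FALSE], to_arm = to_arm,
                       restart_clock = restart_clock)
  finish_records(rbind(base, clones), restart_clock)
}

clone_rows <- function(switchers, to_arm, restart_clock) {
  if (nrow(switchers) == 0L) {
    return(data.frame(subject_id = integer(), clone = logical(),
                      arm = character(), entry = numeric(),
                      exit = numeric(), event = logical()))
  }
  if (anyNA(switchers$switch_time)) {
    stop(data_error("observed switcher without a switch_time"))
  }
  data.frame(
    subject_id = switchers$subject_id,
    clone = TRUE,
    arm = rep_len(to_arm, nrow(switchers)),
    entry = if (restart_clock) 0 else switchers$switch_time,
    exit = if (restart_clock) {
      switchers$followup_time - switchers$switch_time
    } else {
      switchers$followup_time
    },
    event = switchers$event
  )
}

finish_records <- function(rec, restart_clock) {
  rec$arm <- factor(as.character(rec$arm), levels = c("CD", "TD"))
  rec$timescale <- if (restart_clock) "restarted" else "original"
  zero <- rec$exit <= rec$entry
  if (any(zero)) {
    warning(sprintf("dropping %d zero-length record(s)", sum(zero)))
    rec <- rec[!zero, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Count clones sitting in the time-0 risk set
#'
#' Under a clock-restart augmentation every clone re-enters the analysis at
#' time 0, inflating the time-0 risk set beyond the simulated cohort size.
#' This counts clone rows with `entry == 0`; for a delayed-entry (no
#' restart) augmentation it is 0 by construction.
#'
#' @param records an augmented record `data.frame`.
#' @return Integer count of clone rows entering at time 0.
#' @export
count_clones_at_time_zero <- function(records) {
  validate_records(records)
  sum(records$clone & records$entry == 0)
}

validate_subjects <- function(s) {
  need <- c("subject_id", "initial_arm", "followup_time", "event",
            "observed_switch", "switch_time")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop(data_error(paste("subjects table missing column(s):",
                          paste(miss, collapse = ", "))))
  }
  bad <- s$observed_switch & (is.na(s$switch_time) |
                                s$switch_time >= s$followup_time)
  if (any(bad)) {
    stop(data_error("observed switchers must have switch_time < followup_time"))
  }
  invisible(s)
}

validate_records <- function(r) {
  need <- c("subject_id", "clone", "arm", "entry", "exit", "event", "timescale")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    stop(data_error(paste("record table missing column(s):",
                          paste(miss, collapse = ", "))))
  }
  if (any(r$exit <= r$entry)) stop(data_error("records with exit <= entry"))
  invisible(r)
}

data_error <- function(msg) {
  structure(class = c("switchclone_data_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
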