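#' Nelson-Aalen cumulative-hazard estimate with delayed entry
#'
#' Nonparametric step-function estimate of a cumulative (cause-specific)
#' hazard from counting-process records: at each distinct event time
#' \eqn{t_k} the estimate jumps by \eqn{d_k / n_k}, the number of events at
#' \eqn{t_k} over the number of records at risk just prior, where a record
#' is at risk on `(entry, exit]` only — delayed entry (left truncation) is
#' honored.
#'
#' All records must carry the same `timescale` tag: pooling rows from a
#' clock-restarted and an original-timescale augmentation would average
#' hazards measured on different clocks and is refused.
#'
#' @param records a record `data.frame` (see [augmentation]); may be empty.
#' @return An object of class `na_estimate` with fields `jump_times`
#'   (ordered distinct event times), `increments` (\eqn{d_k/n_k}),
#'   `cumulative` (running sum, right-continuous, starting at 0),
#'   `risk_sizes` (\eqn{n_k}), `n_events` (\eqn{d_k}), `timescale`, and
#'   `at_risk`, a function returning the number of records at risk at any
#'   time.  Evaluate the step function with [na_at()].
#' @examples
#' rec <- data.frame(subject_id = 1:3, clone = FALSE, arm = "TD",
#'                   entry = 0, exit = 1:3,
#'                   event = c(TRUE, TRUE, FALSE), timescale = "original")
#' na <- nelson_aalen(rec)
#' na_at(na, c(1, 2, 3))   # 1/3, 1/3 + 1/2, unchanged
#' @export
nelson_aalen <- function(records) {
  if (nrow(records) == 0L) {
    return(new_na_estimate(numeric(), numeric(), numeric(), integer(),
                           timescale = NA_character_,
                           at_risk = function(t) rep(0L, length(t))))
  }
  validate_records(records)
  ts <- unique(records$timescale)
  if (length(ts) > 1L) {
    stop(data_error(paste("records mix timescales:",
                          paste(ts, collapse = ", "))))
  }
  entry <- records$entry
  exit <- records$exit
  at_risk <- function(t) {
    vapply(t, function(u) sum(entry < u & exit >= u), 0L)
  }
  ev <- records$event
  if (!any(ev)) {
    return(new_na_estimate(numeric(), numeric(), numeric(), integer(),
                           timescale = ts, at_risk = at_risk))
  }
  jump_times <- sort(unique(exit[ev]))
  d <- tabulate(match(exit[ev], jump_times), length(jump_times))
  n <- at_risk(jump_times)
  stopifnot(all(n > 0L))
  inc <- d / n
  new_na_estimate(jump_times, inc, cumsum(inc), n, d, ts, at_risk)
}

new_na_estimate <- function(jump_times, increments, cumulative, risk_sizes,
                            n_events = integer(), timescale, at_risk) {
  structure(list(jump_times = jump_times, increments = increments,
                 cumulative = cumulative, risk_sizes = risk_sizes,
                 n_events = n_events, timescale = timescale,
                 at_risk = at_risk),
            class = "na_estimate")
}

#' Evaluate a Nelson-Aalen estimate
#'
#' Right-continuous step-function evaluation of the cumulative hazard.
#'
#' @param est an `na_estimate` from [nelson_aalen()].
#' @param t numeric vector of times.
#' @return \eqn{\hat A(t)} for each `t`.
#' @export
na_at <- function(est, t) {
  stopifnot(inherits(est, "na_estimate"))
  if (length(est$jump_times) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, est$jump_times)
  c(0, est$cumulative)[idx + 1L]
}

#' @export
print.na_estimate <- function(x, ...) {
  k <- length(x$jump_times)
  cat(sprintf("Nelson-Aalen estimate: %d jump(s)%s, A(max) = %.4g\n", k,
              if (!is.na(x$timescale)) paste0(" [", x$timescale, " timescale]") else "",
              if (k) x$cumulative[k] else 0))
  invisible(x)
}

#' Cox proportional-hazards fit of the arm effect
#'
#' Fits the single-covariate proportional-hazards model (TD vs CD) to a
#' counting-process dataset by partial likelihood ([survival::coxph()],
#' Breslow tie handling), honoring delayed entry.  This is the model both
#' switching approaches fit to their augmented datasets; `beta_hat` is the
#' log hazard ratio of TD relative to CD.
#'
#' With `robust = TRUE` the standard error is the subject-clustered
#' sandwich estimate, grouping a patient's rows across clones — the
#' correction recommended when clones of one patient can sit in two risk
#' sets at once.  The default `FALSE` is the naive fit the approaches use
#' in practice.
#'
#' @param records a record `data.frame` with both arms present and at least
#'   one event in each arm.
#' @param robust logical; subject-clustered sandwich standard error.
#' @return An object of class `cox_fit`: `beta_hat`, `se`, `hr`
#'   (`exp(beta_hat)`), `wald_z`, `p_value` (two-sided normal), `n_rows`,
#'   `n_events`, `robust`.
#' @seealso [wald_reject()]
#' @export
cox_fit <- function(records, robust = FALSE) {
  validate_records(records)
  if (!all(c("CD", "TD") %in% records$arm)) {
    stop(fit_error("both arms must be present in the records"))
  }
  ev_arms <- unique(as.character(records$arm[records$event]))
  if (length(ev_arms) == 0L) {
    stop(fit_error("no events: the partial likelihood is flat"))
  }
  if (length(ev_arms) == 1L) {
    stop(fit_error(sprintf(
      "events only in arm %s: monotone partial likelihood, beta diverges",
      ev_arms)))
  }
  d <- data.frame(entry = records$entry, exit = records$exit,
                  event = records$event,
                  arm = factor(as.character(records$arm), c("CD", "TD")),
                  id = records$subject_id)
  # timefix = FALSE: simulated continuous times are exact; the default
  # tie-rounding can collapse genuinely tiny intervals to length zero
  ctrl <- survival::coxph.control(timefix = FALSE)
  fit <- withCallingHandlers(
    if (robust) {
      survival::coxph(survival::Surv(entry, exit, event) ~ arm,
                      data = d, ties = "breslow", cluster = id,
                      control = ctrl)
    } else {
      survival::coxph(survival::Surv(entry, exit, event) ~ arm,
                      data = d, ties = "breslow", control = ctrl)
    },
    warning = function(w) {
      if (grepl("did not converge|infinite|out of iterations",
                conditionMessage(w))) {
        stop(convergence_error(conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit)[1L])
  se <- if (robust) sqrt(fit$var[1L, 1L]) else sqrt(fit$naive.var %||% fit$var)[1L]
  if (!is.finite(beta) || !is.finite(se)) {
    stop(convergence_error("non-finite estimate from the partial-likelihood fit"))
  }
  z <- beta / se
  structure(list(beta_hat = beta, se = se, hr = exp(beta), wald_z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_rows = nrow(d), n_events = sum(d$event), robust = robust),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit (TD vs CD): beta = %.4f (%s se %.4f), HR = %.3f, z = %.3f, p = %.4g\n  %d rows, %d events\n",
    x$beta_hat, if (x$robust) "robust" else "model", x$se, x$hr, x$wald_z,
    x$p_value, x$n_rows, x$n_events))
  invisible(x)
}

#' Two-sided Wald test of no arm effect
#'
#' Rejects the null hypothesis of equal adverse-event hazards
#' (\eqn{\beta = 0}) when the two-sided normal p-value of the Wald
#' statistic falls strictly below `alpha`.
#'
#' @param fit a [cox_fit()] result.
#' @param alpha significance level, default 0.05.
#' @return `TRUE` iff `p_value < alpha`.
#' @export
wald_reject <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_fit"), is.finite(fit$se))
  fit$p_value < alpha
}

fit_error <- function(msg) {
  structure(class = c("switchclone_fit_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

convergence_error <- function(msg) {
  structure(class = c("switchclone_convergence_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
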