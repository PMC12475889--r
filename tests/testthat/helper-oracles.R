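# Independent oracles and small fixture builders, used across test files.

# Brute-force maximizer of the Breslow partial log-likelihood for the
# single binary arm covariate on (entry, exit] records: two-stage dense
# grid search, independent of any package fitting path.
brute_force_beta <- function(rec, lower = -5, upper = 5) {
  x <- as.integer(rec$arm == "TD")
  logpl <- function(beta) {
    s <- 0
    for (i in which(rec$event)) {
      t <- rec$exit[i]
      risk <- rec$entry < t & rec$exit >= t
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  grid <- seq(lower, upper, by = 0.01)
  b0 <- grid[which.max(vapply(grid, logpl, 0))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  fine[which.max(vapply(fine, logpl, 0))]
}

# Hand-built subject table in the cohort layout.
make_subjects <- function(initial_arm, followup_time, event,
                          switch_time = NA_real_) {
  n <- length(initial_arm)
  observed <- !is.na(switch_time)
  data.frame(
    subject_id = seq_len(n),
    initial_arm = factor(initial_arm, levels = c("CD", "TD")),
    latent_event_time = ifelse(event, followup_time, Inf),
    followup_time = followup_time,
    event = event,
    switch_assigned = observed,
    observed_switch = observed,
    switch_time = switch_time
  )
}

# Record rows in the counting-process layout.
make_records <- function(arm, entry, exit, event, clone = FALSE,
                         timescale = "original", subject_id = NULL) {
  n <- length(exit)
  data.frame(
    subject_id = subject_id %||% seq_len(n),
    clone = rep_len(clone, n),
    arm = factor(rep_len(arm, n), levels = c("CD", "TD")),
    entry = rep_len(entry, n),
    exit = exit,
    event = event,
    timescale = rep_len(timescale, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small-but-not-tiny scenario for pipeline tests that do not need n = 6000.
small_config <- function(scenario_id = 1, shape = 1, scale = 4,
                         switch_time = 1, switch_prop = 0.3,
                         n = 400, seed = 42, ...) {
  scenario_config(scenario_id, shape, scale, switch_time, switch_prop,
                  n_td = n, n_cd = n, seed = seed, ...)
}
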