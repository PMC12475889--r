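test_that("Nelson-Aalen reproduces hand-computed risk-set ratios", {
  rec <- make_records("TD", entry = 0, exit = c(1, 2, 3),
                      event = c(TRUE, TRUE, FALSE))
  na <- nelson_aalen(rec)
  expect_equal(na$jump_times, c(1, 2))
  expect_equal(na$increments, c(1 / 3, 1 / 2))
  expect_equal(na$risk_sizes, c(3L, 2L))
  expect_equal(na_at(na, c(0.5, 1, 2, 3, 10)),
               c(0, 1 / 3, 1 / 3 + 1 / 2, 5 / 6, 5 / 6))
})

test_that("delayed entry keeps rows out of earlier risk sets", {
  rec <- make_records("TD", entry = 2, exit = 3, event = TRUE)
  na <- nelson_aalen(rec)
  expect_equal(na$jump_times, 3)
  expect_equal(na$increments, 1)      # risk set of size 1 on (2, 3]
  expect_equal(na_at(na, c(1, 2.5, 3)), c(0, 0, 1))
  expect_equal(na$at_risk(c(1, 2, 2.5, 3, 3.5)), c(0L, 0L, 1L, 1L, 0L))
})

test_that("event-free and empty inputs give the zero estimate", {
  rec <- make_records("CD", 0, exit = c(1, 2), event = FALSE)
  expect_equal(na_at(nelson_aalen(rec), c(0, 1, 5)), c(0, 0, 0))
  empty <- rec[0, ]
  expect_equal(na_at(nelson_aalen(empty), 1:3), c(0, 0, 0))
})

test_that("mixed timescales are refused", {
  rec <- rbind(make_records("TD", 0, 1, TRUE, timescale = "original"),
               make_records("TD", 0, 2, TRUE, timescale = "restarted"))
  expect_error(nelson_aalen(rec), class = "switchclone_data_error",
               regexp = "timescale")
})

test_that("Nelson-Aalen agrees with the survival-package estimator on left-truncated data", {
  set.seed(31)
  n <- 400
  entry <- runif(n, 0, 2) * rbinom(n, 1, 0.5)
  exit <- entry + rexp(n, 0.4)
  event <- rbinom(n, 1, 0.7) == 1
  rec <- make_records("TD", entry, exit, event)
  na <- nelson_aalen(rec)
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1,
                          ctype = 1)
  expect_equal(na_at(na, sf$time), sf$cumhaz, tolerance = 1e-12)
  # with all entries 0 a naive no-truncation implementation agrees exactly
  rec0 <- make_records("TD", 0, exit, event)
  naive_inc <- function(t) sum(event & exit == t) / sum(exit >= t)
  na0 <- nelson_aalen(rec0)
  expect_equal(na0$increments, vapply(na0$jump_times, naive_inc, 0))
})

test_that("the Cox fit maximizes the partial likelihood (brute-force oracle)", {
  # four subjects, events interleaved between arms so the partial
  # likelihood has an interior maximum
  rec <- make_records(c("TD", "CD", "TD", "CD"), 0, exit = 1:4, event = TRUE)
  fit <- cox_fit(rec)
  expect_equal(fit$beta_hat, brute_force_beta(rec), tolerance = 1e-4)

  # a left-truncated instance with censoring
  rec2 <- make_records(c("TD", "TD", "CD", "CD"),
                       entry = c(0, 0.5, 0, 1),
                       exit = c(2, 3, 2.5, 4),
                       event = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(cox_fit(rec2)$beta_hat, brute_force_beta(rec2),
               tolerance = 1e-4)
})

test_that("symmetric data gives a null estimate and label swap flips the sign", {
  set.seed(8)
  exit <- rexp(30, 0.3)
  event <- rbinom(30, 1, 0.8) == 1
  twin <- rbind(make_records("TD", 0, exit, event),
                make_records("CD", 0, exit, event))
  fit <- cox_fit(twin)
  expect_equal(fit$beta_hat, 0, tolerance = 1e-10)
  expect_equal(fit$hr, 1, tolerance = 1e-10)
  expect_false(wald_reject(fit))

  rec <- make_records(c("TD", "CD", "TD", "CD"), 0, exit = 1:4, event = TRUE)
  swapped <- rec
  swapped$arm <- factor(ifelse(rec$arm == "TD", "CD", "TD"), c("CD", "TD"))
  expect_equal(cox_fit(swapped)$beta_hat, -cox_fit(rec)$beta_hat,
               tolerance = 1e-8)
})

test_that("degenerate fits raise distinct classed errors", {
  no_events <- make_records(c("TD", "CD"), 0, exit = c(1, 2), event = FALSE)
  expect_error(cox_fit(no_events), class = "switchclone_fit_error",
               regexp = "no events")
  one_arm <- make_records(c("TD", "TD", "CD"), 0, exit = c(1, 2, 3),
                          event = c(TRUE, TRUE, FALSE))
  expect_error(cox_fit(one_arm), class = "switchclone_fit_error",
               regexp = "monotone")
  td_only <- make_records("TD", 0, exit = c(1, 2), event = TRUE)
  expect_error(cox_fit(td_only), class = "switchclone_fit_error")
})

test_that("the Wald test uses the two-sided normal tail strictly below alpha", {
  rec <- make_records(c("TD", "CD", "TD", "CD"), 0, exit = 1:4, event = TRUE)
  fit <- cox_fit(rec)
  expect_equal(fit$p_value, 2 * pnorm(-abs(fit$beta_hat / fit$se)))
  expect_false(wald_reject(fit, alpha = fit$p_value))          # p == alpha
  expect_true(wald_reject(fit, alpha = fit$p_value + 1e-12))
  expect_false(wald_reject(fit, alpha = 1e-6))
})

test_that("robust clustering across clones widens the naive standard error", {
  coh <- simulate_cohort(small_config(n = 1500, switch_prop = 0.5), 4)
  rec <- augment_overlapping(coh, restart_clock = TRUE)
  naive <- cox_fit(rec, robust = FALSE)
  rob <- cox_fit(rec, robust = TRUE)
  expect_equal(rob$beta_hat, naive$beta_hat, tolerance = 1e-10)
  expect_true(rob$robust && !naive$robust)
  expect_true(is.finite(rob$se) && rob$se > 0)
  expect_false(isTRUE(all.equal(rob$se, naive$se)))
})

test_that("the Cox HR tracks the Nelson-Aalen ratio under proportional hazards", {
  # two-arm exponential cohorts with true hazard ratio 2, no switching
  cfg <- scenario_config(91, shape = 1, scale = 2, switch_time = 1,
                         switch_prop = 0, scale_cd = 4, seed = 13L)
  coh <- simulate_cohort(cfg, 1)
  rec <- augment_hierarchical(coh, restart_clock = TRUE)
  fit <- cox_fit(rec)
  expect_equal(fit$beta_hat, log(2), tolerance = 3 * fit$se / log(2))
  na_td <- nelson_aalen(rec[rec$arm == "TD", ])
  na_cd <- nelson_aalen(rec[rec$arm == "CD", ])
  horizon <- 8
  ratio <- na_at(na_td, horizon) / na_at(na_cd, horizon)
  expect_equal(fit$hr, ratio, tolerance = 0.1)
})
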