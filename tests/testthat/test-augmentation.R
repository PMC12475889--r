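# Hand-built patient journeys: the TD->CD switcher censored at follow-up end
# and the CD->TD switcher whose follow-up ends with the adverse event.
td_to_cd_censored <- function() {
  make_subjects("TD", followup_time = 6, event = FALSE, switch_time = 2)
}
cd_to_td_event <- function() {
  make_subjects("CD", followup_time = 5, event = TRUE, switch_time = 2)
}

test_that("hierarchical attribution keeps a TD starter's whole follow-up", {
  rec <- augment_hierarchical(td_to_cd_censored(), restart_clock = TRUE)
  expect_equal(nrow(rec), 1L)
  expect_equal(as.character(rec$arm), "TD")
  expect_equal(c(rec$entry, rec$exit), c(0, 6))
  expect_false(rec$event)
  expect_false(rec$clone)
})

test_that("hierarchical cloning splits a CD->TD switcher at the switch", {
  rec <- augment_hierarchical(cd_to_td_event(), restart_clock = TRUE)
  expect_equal(nrow(rec), 2L)
  cd <- rec[rec$arm == "CD", ]; td <- rec[rec$arm == "TD", ]
  expect_equal(c(cd$entry, cd$exit), c(0, 2))
  expect_false(cd$event)           # censored on CD at the switch
  expect_equal(c(td$entry, td$exit), c(0, 3))   # restarted clock: T - s
  expect_true(td$event && td$clone)
  expect_equal(unique(rec$timescale), "restarted")

  # modified variant: the clone is a left-truncated row on the original clock
  rec2 <- augment_hierarchical(cd_to_td_event(), restart_clock = FALSE)
  td2 <- rec2[rec2$arm == "TD", ]
  expect_equal(c(td2$entry, td2$exit), c(2, 5))
  expect_true(td2$event)
  expect_equal(unique(rec2$timescale), "original")
})

test_that("overlapping attribution doubles switchers from both arms", {
  rec <- augment_overlapping(cd_to_td_event(), restart_clock = TRUE)
  expect_equal(nrow(rec), 2L)
  cd <- rec[rec$arm == "CD", ]; td <- rec[rec$arm == "TD", ]
  expect_equal(c(cd$entry, cd$exit), c(0, 5))   # initiated arm keeps it all
  expect_equal(c(td$entry, td$exit), c(0, 3))
  # the event is counted once per arm
  expect_true(cd$event && td$event)

  rec2 <- augment_overlapping(td_to_cd_censored(), restart_clock = TRUE)
  expect_equal(as.character(rec2$arm[!rec2$clone]), "TD")
  expect_equal(rec2$exit[!rec2$clone], 6)
  expect_equal(as.character(rec2$arm[rec2$clone]), "CD")
  expect_equal(rec2$exit[rec2$clone], 4)
  expect_false(any(rec2$event))
})

test_that("no switching makes every augmentation the raw dataset", {
  coh <- simulate_cohort(small_config(switch_prop = 0))
  for (f in list(augment_hierarchical, augment_overlapping)) {
    for (restart in c(TRUE, FALSE)) {
      rec <- f(coh, restart)
      expect_equal(nrow(rec), nrow(coh))
      expect_false(any(rec$clone))
      expect_equal(rec$exit, coh$followup_time)
      expect_equal(rec$event, coh$event)
      expect_equal(as.character(rec$arm), as.character(coh$initial_arm))
    }
  }
})

test_that("person-time is conserved (hierarchical) or exceeds by the post-switch time (overlapping)", {
  for (seed in c(1, 2, 3)) {
    coh <- simulate_cohort(small_config(seed = seed, switch_prop = 0.4))
    total_fu <- sum(coh$followup_time)
    post_switch <- sum((coh$followup_time - coh$switch_time)[coh$observed_switch])
    for (restart in c(TRUE, FALSE)) {
      h <- augment_hierarchical(coh, restart)
      expect_equal(sum(h$exit - h$entry), total_fu)
      o <- augment_overlapping(coh, restart)
      expect_equal(sum(o$exit - o$entry), total_fu + post_switch)
    }
  }
})

test_that("the no-restart hierarchical rows partition each subject's follow-up", {
  coh <- simulate_cohort(small_config(seed = 9, switch_prop = 0.5))
  rec <- augment_hierarchical(coh, restart_clock = FALSE)
  by_subj <- split(rec, rec$subject_id)
  for (rows in by_subj) {
    rows <- rows[order(rows$entry), ]
    expect_equal(rows$entry[1], 0)
    if (nrow(rows) > 1) {
      # contiguous, non-overlapping intervals
      expect_equal(rows$entry[-1], rows$exit[-nrow(rows)])
    }
    fu <- coh$followup_time[coh$subject_id == rows$subject_id[1]]
    expect_equal(rows$exit[nrow(rows)], fu)
  }
  # each event appears exactly once in the hierarchical dataset
  expect_equal(sum(rec$event), sum(coh$event))
})

test_that("clock restart puts a switcher in two risk sets at once", {
  coh <- cd_to_td_event()   # switch at 2, event at 5
  rec <- augment_hierarchical(coh, restart_clock = TRUE)
  # on (0, min(s, T - s)] both the CD row and the restarted TD clone cover t
  t <- 1
  covered <- rec$entry < t & rec$exit >= t
  expect_equal(sum(covered), 2L)
  # without restart the clone enters only at s
  rec2 <- augment_hierarchical(coh, restart_clock = FALSE)
  expect_equal(sum(rec2$entry < t & rec2$exit >= t), 1L)
})

test_that("clone counts at time zero track restart and approach", {
  coh <- simulate_cohort(small_config(n = 3000, switch_prop = 0.3), 2)
  h <- augment_hierarchical(coh, TRUE)
  n_cd_sw <- sum(coh$initial_arm == "CD" & coh$observed_switch)
  n_sw <- sum(coh$observed_switch)
  expect_equal(count_clones_at_time_zero(h), n_cd_sw)
  expect_equal(count_clones_at_time_zero(augment_hierarchical(coh, FALSE)), 0L)
  # the overlapping approach doubles switchers from both arms
  expect_equal(count_clones_at_time_zero(augment_overlapping(coh, TRUE)), n_sw)
  expect_equal(count_clones_at_time_zero(augment_overlapping(coh, FALSE)), 0L)
})

test_that("malformed switcher data is rejected", {
  bad <- cd_to_td_event()
  bad$switch_time <- NA_real_
  expect_error(augment_hierarchical(bad), class = "switchclone_data_error")
  bad2 <- cd_to_td_event()
  bad2$switch_time <- bad2$followup_time   # switch at exit: zero-length clone
  expect_error(augment_overlapping(bad2), class = "switchclone_data_error")
})
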