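#!/usr/bin/env Rscript
# Simulate the two high-event-count "extreme" scenarios (constant hazard and
# strongly time-dependent Weibull hazard) and record the cohort-level
# summaries: observed events, observed switchers vs the assigned 30%.
# Writes one cohort CSV per scenario under results/.

library(switchclone)
dir.create("results", showWarnings = FALSE)

scen <- scenario_table(seed = 20260928L)
for (id in c("1", "2")) {
  cfg <- scen[[id]]
  coh <- simulate_cohort(cfg, rep_index = 1)
  path <- sprintf("results/cohort_scenario%s.csv", id)
  write_cohort_csv(coh, path)
  cat(sprintf(
    "scenario %s (shape %.1f, scale %.4g): %d events (expected %.0f), %.1f%% observed switchers (assigned %.0f%%)\n  -> %s\n",
    id, cfg$shape, cfg$scale, sum(coh$event), expected_event_count(cfg),
    100 * mean(coh$observed_switch), 100 * cfg$switch_prop, path))
}
cat("\nObserved switching sits below the assigned proportion because only\n",
    "subjects still event-free at the 1-year switch time can switch.\n", sep = "")
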