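#!/usr/bin/env Rscript
# Decompose both switching approaches into their illness-death transition
# hazards on the extreme scenarios: the Nelson-Aalen curve sets, the inflated
# time-0 risk sets under clock restart, and step-plot figures.
# Reads the cohort CSVs from 01_cohorts.R; writes curve tables and SVGs.

library(switchclone)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

for (id in c("1", "2")) {
  coh <- read_cohort_csv(sprintf("results/cohort_scenario%s.csv", id))
  for (approach in c("hierarchical", "overlapping")) {
    tc <- transition_curves(coh, approach, restart_clock = TRUE)
    at0 <- tc$at_risk_table$total[tc$at_risk_table$time == 0]
    clones <- at0 - nrow(coh)
    cat(sprintf(
      "scenario %s, %s (restart): at risk for failure at t=0: %d = %d subjects + %d clones\n",
      id, approach, at0, nrow(coh), clones))
    utils::write.csv(curves_as_table(tc),
                     sprintf("results/curves_s%s_%s.csv", id, approach),
                     row.names = FALSE)
    utils::write.csv(tc$at_risk_table,
                     sprintf("results/atrisk_s%s_%s.csv", id, approach),
                     row.names = FALSE)
    ggplot2::ggsave(
      sprintf("results/figures/curves_s%s_%s.svg", id, approach),
      plot_transition_curves(tc), width = 8, height = 5,
      device = grDevices::svg)
  }
}
cat("\nWith a constant hazard every failure curve shares one slope; with the\n",
    "shape-0.3 hazard the restarted switched-stratum curve is much steeper\n",
    "at small t than the starter curves, which is what distorts the\n",
    "combined numerator.\n", sep = "")
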