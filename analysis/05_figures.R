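#!/usr/bin/env Rscript
# Rejection-rate panel figures from the study results table: empirical
# type-1-error by Weibull shape, faceted by switching time and proportion,
# one figure per analysis variant plus a combined view.

library(switchclone)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

tab <- read_results_csv("results/type1_study.csv")
for (v in study_variants()) {
  sub <- tab[tab$approach == v$approach & tab$restart == v$restart_clock, ]
  stub <- sprintf("%s_%s", v$approach,
                  if (v$restart_clock) "restart" else "norestart")
  ggplot2::ggsave(sprintf("results/figures/rejection_%s.svg", stub),
                  plot_rejection_rates(sub), width = 8, height = 6,
                  device = grDevices::svg)
  cat(sprintf("%-30s max rejection %.3f\n", stub, max(sub$rejection_prop)))
}
ggplot2::ggsave("results/figures/rejection_all_variants.svg",
                plot_rejection_rates(tab), width = 9, height = 7,
                device = grDevices::svg)
cat("-> results/figures/\n")
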