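Package: switchclone
Title: Treatment-Switching Estimators for Long-Term Drug Safety via
    Multistate Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation machinery for evaluating two
    clone-and-censor estimators of long-term comparative drug safety under
    treatment switching: the experimental hierarchical approach and the
    overlapping approach, together with their modified no-clock-restart
    (left-truncated) variants.  Expresses each estimator through its
    illness-death multistate-model representation (cause-specific
    Nelson-Aalen transition hazards and hazard-ratio decompositions),
    generates synthetic switching cohorts with Weibull adverse-event times
    and administrative censoring, and orchestrates null-hypothesis
    simulation studies quantifying type-1-error inflation or deflation of
    the Wald test from Cox proportional-hazards fits on the augmented
    counting-process datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
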