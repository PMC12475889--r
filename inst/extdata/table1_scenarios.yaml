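# The 22 null-hypothesis simulation scenarios of the study.
# All scenarios: 3000 TD + 3000 CD treatment-naive starters, administrative
# censoring at 8 years, event times Weibull(shape, scale) in the rweibull()
# parameterization, identical in both arms (null), baseline-assigned
# switching with a common switching time.
# Scenarios 1-2 are high-event-count "extreme" settings used for the
# transition-hazard plots; scenarios 3-22 are rare-event settings calibrated
# to ~330 events each, crossing shape {1, 1.1, 1.2, 1.3, 1.5} with switch
# time {1, 5} years and switching proportion {25%, 50%}.
defaults:
  n_td: 3000
  n_cd: 3000
  admin_censor: 8
  n_reps: 1000
  seed: 1
scenarios:
  - {id: 1,  shape: 1.0, scale: 4.0,    switch_time: 1, switch_prop: 0.30}
  - {id: 2,  shape: 0.3, scale: 2.0,    switch_time: 1, switch_prop: 0.30}
  - {id: 3,  shape: 1.0, scale: 142.85, switch_time: 1, switch_prop: 0.25}
  - {id: 4,  shape: 1.0, scale: 142.85, switch_time: 5, switch_prop: 0.25}
  - {id: 5,  shape: 1.0, scale: 142.85, switch_time: 1, switch_prop: 0.50}
  - {id: 6,  shape: 1.0, scale: 142.85, switch_time: 5, switch_prop: 0.50}
  - {id: 7,  shape: 1.1, scale: 109.93, switch_time: 1, switch_prop: 0.25}
  - {id: 8,  shape: 1.1, scale: 109.93, switch_time: 5, switch_prop: 0.25}
  - {id: 9,  shape: 1.1, scale: 109.93, switch_time: 1, switch_prop: 0.50}
  - {id: 10, shape: 1.1, scale: 109.93, switch_time: 5, switch_prop: 0.50}
  - {id: 11, shape: 1.2, scale: 88.36,  switch_time: 1, switch_prop: 0.25}
  - {id: 12, shape: 1.2, scale: 88.36,  switch_time: 5, switch_prop: 0.25}
  - {id: 13, shape: 1.2, scale: 88.36,  switch_time: 1, switch_prop: 0.50}
  - {id: 14, shape: 1.2, scale: 88.36,  switch_time: 5, switch_prop: 0.50}
  - {id: 15, shape: 1.3, scale: 73.45,  switch_time: 1, switch_prop: 0.25}
  - {id: 16, shape: 1.3, scale: 73.45,  switch_time: 5, switch_prop: 0.25}
  - {id: 17, shape: 1.3, scale: 73.45,  switch_time: 1, switch_prop: 0.50}
  - {id: 18, shape: 1.3, scale: 73.45,  switch_time: 5, switch_prop: 0.50}
  - {id: 19, shape: 1.5, scale: 54.66,  switch_time: 1, switch_prop: 0.25}
  - {id: 20, shape: 1.5, scale: 54.66,  switch_time: 5, switch_prop: 0.25}
  - {id: 21, shape: 1.5, scale: 54.66,  switch_time: 1, switch_prop: 0.50}
  - {id: 22, shape: 1.5, scale: 54.66,  switch_time: 5, switch_prop: 0.50}
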