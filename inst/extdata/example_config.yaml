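# Example pulpcea run configuration. Every key is optional: omitted keys
# take the base-case defaults. Costs are USD, keyed by CDT procedure code.
costs:
  D3330: 1109.31   # root canal treatment
  D3220: 210.50    # pulpotomy
  D2393: 294.82    # direct composite restoration
  D2751: 1095.76   # crown, porcelain fused to metal
  D3348: 1246.06   # nonsurgical retreatment
  D3425: 961.87    # surgical retreatment
  D7140: 189.83    # extraction
  symptomatic_visit: 0
probabilities:
  p_success_pulpotomy_first_year: 0.96
  p_success_rct_first_year: 0.99
  p_success_pulpotomy_followup: 0.95
  p_success_rct_followup: 0.97
  p_complication_pulpotomy: 0.05
  p_complication_rct: 0.03
  p_rct_after_failed_pulpotomy: 0.875
  p_extraction_after_failed_pulpotomy: 0.125
  p_nsretx_after_failed_rct: 0.1
  p_sretx_after_failed_rct: 0.15
  p_extraction_after_failed_rct: 0.75
discount_rate: 0.03
start_age: 18
horizon_age: 110
half_cycle: false
life_table:
  target_le: 60.6   # remaining life expectancy calibrated at `at_age` ...
  at_age: 18        # ... or instead supply `csv: path/to/table.csv`
psa:
  iterations: 10000
  cost_sd_fraction: 0.10
  prob_sd: 0.02
  percentile_bounds: [0.05, 0.95]
tornado:
  range_fraction: 0.2
wtp:
  min: 0
  max: 1000
  step: 25
seed: 1
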