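# Demo pipeline configuration: a small synthetic site and two scenario
# combinations, end to end in well under a minute.
landscape:
  size: 16
  latitude: 55
  seed: 1
  relief: 200
  cellsize: 100
  missing_frac: 0.05
site:
  soil_class: sandy_loam
  smooth_window: 3
scenarios:
  planting_rules: [SM1, SM2]
  climate_scenarios: [CS3]
  start_year: 2025
  end_year: 2080
  initial_stems: 1650
  dry_threshold: 0.33
  wet_threshold: 0.67
  planting_seed: 1
  trace_year: 2079
  conifer_species: black_spruce
  deciduous_species: generic_deciduous
analysis:
  adjust_method: holm
  flag_threshold: 0.05
outdir: afforest3PG_demo
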