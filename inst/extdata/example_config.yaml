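# Synthetic-baseline generator configuration (see ?synth_config).
# Any key may be omitted; the defaults below mirror the function defaults.
n_provinces: 5
cities_per_province: 4
tier_mix:
  T1: 0.05
  NT1: 0.10
  T2: 0.20
  T3: 0.65
east_fraction: 0.4
total_population: 2.0e7
baseline_tfr: 1.5
baseline_e0:
  M: 72.4
  F: 77.4
baseline_srb: 1.18
mig_rate_scale: 0.004
baseline_year: 2010
seed: 1
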