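# Reference run configuration: the full 648-condition factorial design at
# 1000 replications per condition.  Any key may be omitted; omitted keys
# take these same defaults.
factor_levels:
  n_waves: [3, 4, 5]
  class_size: [10, 20, 30]
  n_classrooms: [20, 30, 40, 50]
  prop_treatment: [0.5, 0.3]
  icc: [0.086, 0.113, 0.2]
  effect_label: [small, medium, large]
base_params:
  gamma000: 0.0
  gamma001: 0.1
  gamma010: 0.5
  gamma011: 0.3
  gamma100: 0.1
  gamma110: 0.5
  gamma111: 0.1
  sigma2_e: 1.0
  tau_pi00: 0.2
  tau_pi01: 0.05
  tau_pi11: 0.1
  aptitude_mean: 0.0
  aptitude_sd: 15.0
n_reps: 1000
master_seed: 1
alpha: 0.05
df_policy: normal
probe_mode: as_printed
denominator: all
aptitude_value: -1.0
n_workers: 1
output_dir: "."
audit: false
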