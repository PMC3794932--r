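# example generator parameters for `pace.R simulate`
n_patients: 500
seed: 1
event_day_prob: 0.05
drugs:
  - drug_code: KCL
    baseline_daily_prob: 0.3
    post_event_multiplier: 0.25
  - drug_code: AML
    baseline_daily_prob: 0.3
    post_event_multiplier: 1
  - drug_code: SPS
    baseline_daily_prob: 0.3
    post_event_multiplier: 3
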