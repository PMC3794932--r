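# example run configuration for the command-line wrapper
inputs:
  dir: cohort/            # directory with the four cohort CSV tables
event:
  analyte: potassium
  kind: lab_threshold
  threshold: 5.5
  upper_ref: 5.5
  exclusion_icd10_prefixes: [I12.0, I13.0, I13.1, N17, N18, N19]
  min_event_gap_days: 0
drugs: [KCL, AML, SPS]
cutoffs:
  lower: 0.667
  upper: 1.5
flags:
  compare_binomial: true
  min_prescriptions: 10
sweep:
  mode: severity
  from: 4.5
  to: 7.0
  step: 0.25
output_dir: out/
seed: 1
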