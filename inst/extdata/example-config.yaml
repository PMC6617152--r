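# Example pipeline configuration: simulate the study-shaped preset, screen,
# grid-search (R, L0) by leave-one-out MSEP, fit and report.
data:
  synthetic: study_preset
seed: 7
screen:
  threshold: 0.55
model:
  R_values: [1, 2]
  L0_values: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
output_dir: blockpls_out
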