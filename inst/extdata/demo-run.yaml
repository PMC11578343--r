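# Small demonstration run: simulate a handful of cells through the reference
# device and analyze the trace end to end.
geometry: geometry-mz4.yaml
seed: 42
output_dir: visconps-demo
simulate:
  n_cells: 4
  noise_sd: 0.05
  event_rate: 1800
pipeline:
  cutoff: 2000
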