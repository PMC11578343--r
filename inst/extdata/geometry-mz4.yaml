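# Reference four-zone device: 1 mm sizing pore followed by four 6 mm
# sinusoidal contraction zones (L_p = 500/250/167/125 um), 21 um nodes,
# 13.8 kPa driving pressure, 10 kHz sampling.
device_id: mz4-6mm
sample_rate: 10000
applied_pressure: 13800
mu_f: 0.1
node_length: 300
pore:
  L_pore: 1000
  D_eff: 25
zones:
- {L_zone: 6000, L_p: 500, w0: 11.25, a: 2.75, w_node: 21, D_eff: 25}
- {L_zone: 6000, L_p: 250, w0: 11.25, a: 2.75, w_node: 21, D_eff: 25}
- {L_zone: 6000, L_p: 167, w0: 11.25, a: 2.75, w_node: 21, D_eff: 25}
- {L_zone: 6000, L_p: 125, w0: 11.25, a: 2.75, w_node: 21, D_eff: 25}
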