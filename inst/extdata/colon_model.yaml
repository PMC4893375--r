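# Three-layer colon tissue model: mucosa / submucosa / muscle.
# Fractions stored as [0,1]; a_mie in cm^-1; d in micrometers.
# a_mie given as mean +/- halfwidth 18.9 +/- 10.2 -> uniform [8.7, 29.1].
name: colon
c_hb_gram_per_liter: 120
shared_s: true
b_fixed: 1.286
max_total_thickness_um: .inf
layers:
  - {v_hb: [0.0, 0.10], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.36, 1.36], d: [600, 1010]}
  - {v_hb: [0.0, 0.10], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.36, 1.36], d: [415, 847]}
  - {v_hb: [0.0, 0.10], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.38, 1.38], d: [395, 603]}
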