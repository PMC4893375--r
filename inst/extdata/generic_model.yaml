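# Generic three-layer soft-tissue model with wide parameter ranges
# (covers malignancy-level blood volume fractions). Layer thicknesses are
# rescaled after sampling so the stack totals at most 2 mm.
name: generic
c_hb_gram_per_liter: 120
shared_s: true
b_fixed: 1.286
max_total_thickness_um: 2000
layers:
  - {v_hb: [0.0, 1.0], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.33, 1.54], d: [0, 2000]}
  - {v_hb: [0.0, 1.0], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.33, 1.54], d: [0, 2000]}
  - {v_hb: [0.0, 1.0], s: [0.0, 1.0], a_mie: [8.7, 29.1], b: [1.286, 1.286],
     g: [0.80, 0.95], n_refr: [1.33, 1.54], d: [0, 2000]}
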