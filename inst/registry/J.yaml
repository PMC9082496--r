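# PSYCHE 2D J experiment: pure absorption-mode J-resolved spectroscopy.
abbreviation: "J"
display_name: "PSYCHE 2DJ"
category: PURESHIFT_2DJ
slot: HOMO
au_program: noah_jres
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: []
t1_delay: d19
ea_gradients: []
supports_flags: []
parameters:
  - p1
  - p16
  - p40
  - d16
  - d19
  - cnst20
  - cnst21
phase_cycles: [ph1, ph5, ph29]
gradients: [gpz22, gpz23]
wavemaker:
  - ";sp40:wvm:psyche_saltire: saltire(30 ms; Q=0.15)"
variants: []
body: |
  ; PSYCHE 2D J (pure absorption line shapes)
  (p1 ph1):f1
  d19
  (p40:sp40 ph5):f1 ; saltire pair, flip angle cnst20
  p40:gp22
  d16
  p16:gp23
  d16
  d19
  goscnp ph29
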