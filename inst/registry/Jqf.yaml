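# Magnitude-mode 2D J experiment ("J^qf"): a simple spin echo in t1.
abbreviation: Jqf
display_name: "magnitude-mode 2DJ"
category: PURESHIFT_2DJ
slot: HOMO
au_program: noah_jres
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: []
t1_delay: d23
ea_gradients: []
supports_flags: [ES]
parameters:
  - p1
  - p2
  - p12
  - p16
  - d16
  - d23
  - cnst21
phase_cycles: [ph1, ph2, ph5, ph6, ph29]
gradients: [gpz25, gpz20]
wavemaker:
  - ";sp1:wvm:sqa100H1: squa100.1000(2 ms; L2H)"
variants: []
body: |
  ; magnitude-mode 2D J
  (p1 ph1):f1
  d23
  (p2 ph2):f1
  d23
  p16:gp25
  d16
  #ifdef ES
  ; excitation sculpting (shaped + hard 180 pair)
  p16:gp20
  d16
  (p12:sp1 ph6):f1
  (p2 ph6):f1
  p16:gp20
  d16
  #endif
  goscnp ph29
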