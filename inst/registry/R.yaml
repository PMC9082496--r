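# ROESY with a shaped spin-lock.
abbreviation: "R"
display_name: "ROESY"
category: HOMONUCLEAR
slot: HOMO
au_program: noah_roesy
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: [BULK_1H]
t1_delay: d15
ea_gradients: []
supports_flags: [ES, NUS]
parameters:
  - p1
  - p2
  - p12
  - p16
  - p44
  - d15
  - d16
phase_cycles: [ph1, ph5, ph6, ph29]
gradients: [gpz21, gpz20]
wavemaker:
  - ";sp1:wvm:sqa100H1: squa100.1000(2 ms; L2H)"
  - ";sp44:wvm:roesy_sl: squa100.1000(200 ms; L2H)"
variants: []
body: |
  ; ROESY
  (p1 ph1):f1
  d15
  (p44:sp44 ph5):f1 ; spin lock
  p16:gp21
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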