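# TOCSY with DIPSI-2 isotropic mixing.
abbreviation: "T"
display_name: "TOCSY"
category: HOMONUCLEAR
slot: HOMO
au_program: noah_tocsy
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: [BULK_1H]
t1_delay: d13
ea_gradients: []
supports_flags: [ES, NUS]
parameters:
  - p1
  - p2
  - p12
  - p16
  - p43
  - d13
  - d16
phase_cycles: [ph1, ph5, ph6, ph29]
gradients: [gpz18, gpz20]
wavemaker:
  - ";sp1:wvm:sqa100H1: squa100.1000(2 ms; L2H)"
  - ";sp43:wvm:dipsi2_mix: dipsi-2(60 ms; L2H)"
variants: []
body: |
  ; TOCSY
  (p1 ph1):f1
  d13
  (p43:sp43 ph5):f1 ; DIPSI-2 isotropic mixing
  p16:gp18
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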