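# CLIP-COSY ("C^c"): in-phase COSY via perfect-echo transfer.
abbreviation: Cc
display_name: "CLIP-COSY"
category: HOMONUCLEAR
slot: HOMO
au_program: noah_clipcosy
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: [BULK_1H]
t1_delay: d12
ea_gradients: []
supports_flags: [ES, NUS]
parameters:
  - p1
  - p2
  - p12
  - p16
  - d12
  - d16
  - cnst16
  - {kind: LOCAL_DELAY, name: DH_CLIP1, definition: "DH_CLIP1=0.25s/cnst16", comment: "1/(4J(HH)) perfect-echo in-phase transfer delay"}
phase_cycles: [ph1, ph5, ph6, ph29]
gradients: [gpz16, gpz17, gpz20]
wavemaker:
  - ";sp1:wvm:sqa100H1: squa100.1000(2 ms; L2H)"
variants: []
body: |
  ; CLIP-COSY
  (p1 ph1):f1
  d12
  (p1 ph5):f1
  ; perfect echo in-phase transfer
  DH_CLIP1
  (p2 ph5):f1
  DH_CLIP1
  (p1 ph6):f1
  p16:gp16
  d16
  DH_CLIP1
  (p2 ph5):f1
  DH_CLIP1
  (p1 ph5):f1
  p16:gp17
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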