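# 13C HSQC-TOCSY ("S^T").  HSQC transfer followed by DIPSI-2 isotropic
# mixing so that cross peaks spread along the proton spin system.
abbreviation: "St"
display_name: "13C HSQC-TOCSY"
category: HET_13C
slot: C13
au_program: noah_hsqctocsy
pools_required: [C13_BOUND_1H]
pools_consumed: [C13_BOUND_1H]
pools_preserved: [BULK_1H, N15_BOUND_1H]
t1_delay: d10
ea_gradients: [7]
supports_flags: [NUS]
parameters:
  - p1
  - p2
  - p3
  - p14
  - p16
  - p43
  - d4
  - d10
  - d16
  - cnst2
  - {kind: LOCAL_DELAY, name: DC_HSQCT1, definition: "DC_HSQCT1=d4-p14/2", comment: "INEPT transfer delay, compensated for the shaped 180"}
phase_cycles: [ph1, ph2, ph5, ph6, ph30]
gradients: [gpz6, gpz7, gpz9]
wavemaker:
  - ";sp3:wvm:wu180C13: cawurst-20(60 kHz, 0.5 ms; L2H)"
  - ";sp43:wvm:dipsi2_mix: dipsi-2(60 ms; L2H)"
variants: []
body: |
  ; 13C HSQC-TOCSY
  (p1 ph5):f1
  DC_HSQCT1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_HSQCT1
  (p1 ph6):f1 (p3 ph1):f2
  d10
  (p2 ph5):f1
  d10
  p16:gp6
  d16
  (p14:sp3 ph5):f2
  (p1 ph5):f1 (p3 ph2):f2
  DC_HSQCT1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_HSQCT1
  (p43:sp43 ph5):f1 ; DIPSI-2 isotropic mixing
  p16:gp9
  d16
  p16:gp7*EA
  d16
  goscnp ph30
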