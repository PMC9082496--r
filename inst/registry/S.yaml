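# 13C HSQC.  Excites only 13C-bound 1H; bulk and 15N-bound 1H are returned
# to +z, so homonuclear modules may follow.  Multiplicity editing is a
# conditional block guarded by the EDIT acquisition flag.
abbreviation: "S"
display_name: "13C HSQC"
category: HET_13C
slot: C13
au_program: noah_hsqc
pools_required: [C13_BOUND_1H]
pools_consumed: [C13_BOUND_1H]
pools_preserved: [BULK_1H, N15_BOUND_1H]
t1_delay: d10
ea_gradients: [7]
supports_flags: [EDIT, NUS]
parameters:
  - p1
  - p2
  - p3
  - p14
  - p16
  - d4
  - d10
  - d16
  - cnst2
  - {kind: LOCAL_DELAY, name: DC_HSQC1, definition: "DC_HSQC1=d4-p14/2", comment: "INEPT transfer delay, compensated for the shaped 180"}
  - {kind: LOCAL_DELAY, name: DC_HSQC2, definition: "DC_HSQC2=0.5s/cnst2", comment: "1/(2J(CH)) multiplicity editing echo"}
phase_cycles: [ph1, ph2, ph5, ph6, ph30]
gradients: [gpz6, gpz7]
wavemaker:
  - ";sp3:wvm:wu180C13: cawurst-20(60 kHz, 0.5 ms; L2H)"
variants: []
body: |
  ; 13C HSQC
  (p1 ph5):f1
  DC_HSQC1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_HSQC1
  (p1 ph6):f1 (p3 ph1):f2
  d10
  (p2 ph5):f1
  d10
  p16:gp6
  d16
  (p14:sp3 ph5):f2
  #ifdef EDIT
  ; multiplicity editing spin echo
  DC_HSQC2
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_HSQC2
  #endif
  (p1 ph5):f1 (p3 ph2):f2
  DC_HSQC1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_HSQC1
  p16:gp7*EA
  d16
  goscnp ph30
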