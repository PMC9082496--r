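# 13C sensitivity-enhanced HSQC (seHSQC, "S+").  The PEP back-transfer gives
# the sensitivity enhancement but saturates bulk 1H unless the ZIP element is
# prepended; the resolver inserts <<ZIP>> only when a later module still
# draws on the bulk pool, and omits it when the module is last.
abbreviation: "Sp"
display_name: "13C seHSQC"
category: HET_13C
slot: C13
au_program: noah_hsqc
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
  - p4
  - p14
  - p16
  - d4
  - d10
  - d16
  - cnst2
  - {kind: LOCAL_DELAY, name: DC_SEHSQC1, definition: "DC_SEHSQC1=d4-p14/2", comment: "INEPT transfer delay, compensated for the shaped 180"}
  - {kind: LOCAL_DELAY, name: DC_SEHSQC2, definition: "DC_SEHSQC2=0.125s/cnst2", comment: "1/(8J(CH)) PEP back-transfer delay"}
phase_cycles: [ph1, ph3, ph5, ph6, ph29]
gradients: [gpz6, gpz7, gpz8]
wavemaker:
  - ";sp3:wvm:wu180C13: cawurst-20(60 kHz, 0.5 ms; L2H)"
variants: []
zip_block: |
  ; ZIP element (returns bulk 1H to +z for later modules)
  (p1 ph5):f1
  d4
  (p2 ph5):f1 (p4 ph5):f2
  d4
  (p1 ph6):f1
  p16:gp8
  d16
body: |
  ; 13C seHSQC
  <<ZIP>>
  (p1 ph5):f1
  DC_SEHSQC1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_SEHSQC1
  (p1 ph6):f1 (p3 ph1):f2
  d10
  (p2 ph5):f1
  d10
  p16:gp6
  d16
  (p14:sp3 ph5):f2
  (p1 ph5):f1 (p3 ph3):f2
  DC_SEHSQC2
  (p2 ph5):f1 (p4 ph5):f2
  DC_SEHSQC2
  (p1 ph6):f1 (p3 ph5):f2
  DC_SEHSQC1
  (p2 ph5):f1 (p14:sp3 ph5):f2
  DC_SEHSQC1
  p16:gp7*EA
  d16
  goscnp ph29
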