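# 15N sensitivity-enhanced HSQC ("SN+").  Long (2.5 ms) t1-bracketing CTP
# gradients as in the 15N HMQC; PEP back-transfer for the enhancement; ZIP
# element inserted by the resolver when bulk 1H is needed later.
abbreviation: SNp
display_name: "15N seHSQC"
category: HET_15N
slot: N15
au_program: noah_nhsqc
pools_required: [N15_BOUND_1H]
pools_consumed: [N15_BOUND_1H]
pools_preserved: [BULK_1H, C13_BOUND_1H]
t1_delay: d20
ea_gradients: [13]
supports_flags: [NUS]
parameters:
  - p1
  - p2
  - p16
  - p19
  - p21
  - p22
  - d16
  - d20
  - d24
  - cnst4
  - {kind: LOCAL_DELAY, name: DN_SEHSQC1, definition: "DN_SEHSQC1=0.25s/cnst4", comment: "1/(4J(NH)) INEPT transfer delay"}
  - {kind: LOCAL_DELAY, name: DN_SEHSQC2, definition: "DN_SEHSQC2=0.125s/cnst4", comment: "1/(8J(NH)) PEP back-transfer delay"}
phase_cycles: [ph1, ph3, ph5, ph6, ph29]
gradients: [gpz8, gpz12, gpz13]
wavemaker: []
variants: []
zip_block: |
  ; ZIP element (returns bulk 1H to +z for later modules)
  (p1 ph5):f1
  d24
  (p2 ph5):f1 (p22 ph5):f3
  d24
  (p1 ph6):f1
  p16:gp8
  d16
body: |
  ; 15N seHSQC
  <<ZIP>>
  (p1 ph5):f1
  DN_SEHSQC1
  (p2 ph5):f1 (p22 ph5):f3
  DN_SEHSQC1
  (p1 ph6):f1 (p21 ph1):f3
  d20
  (p2 ph5):f1
  d20
  p19:gp12
  d16
  (p22 ph5):f3
  (p1 ph5):f1 (p21 ph3):f3
  DN_SEHSQC2
  (p2 ph5):f1 (p22 ph5):f3
  DN_SEHSQC2
  (p1 ph6):f1 (p21 ph5):f3
  DN_SEHSQC1
  (p2 ph5):f1 (p22 ph5):f3
  DN_SEHSQC1
  p19:gp13*EA
  d16
  goscnp ph29
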