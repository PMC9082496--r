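# Triple spin-echo (TSE) PSYCHE ("P^T"): improved robustness toward strong
# coupling compared with plain PSYCHE.
abbreviation: Pt
display_name: "TSE-PSYCHE pure shift"
category: PURESHIFT_2DJ
slot: HOMO
au_program: noah_psyche
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: []
t1_delay: d18
ea_gradients: []
supports_flags: []
parameters:
  - p1
  - p2
  - p16
  - p40
  - d16
  - d18
  - cnst20
  - cnst21
  - {kind: LOCAL_DELAY, name: DH_PSYCHET1, definition: "DH_PSYCHET1=in18*cnst21/2", comment: "half t1 chunk duration (k-scaled)"}
phase_cycles: [ph1, ph5, ph6, ph29]
gradients: [gpz22, gpz23, gpz24]
wavemaker:
  - ";sp40:wvm:psyche_saltire: saltire(30 ms; Q=0.15)"
variants: []
body: |
  ; TSE-PSYCHE pure shift (pseudo-2D, SAPPHIRE averaging)
  (p1 ph1):f1
  DH_PSYCHET1
  (p2 ph5):f1
  DH_PSYCHET1
  p16:gp24
  d16
  (p40:sp40 ph5):f1 ; saltire pair, flip angle cnst20
  p40:gp22
  d16
  p16:gp24
  d16
  p16:gp23
  d16
  (p2 ph6):f1
  p16:gp23
  d16
  d18
  goscnp ph29
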