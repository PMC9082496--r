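# Pseudo-2D PSYCHE pure shift experiment.  t1 is acquired in chunks
# (16-32 increments); SAPPHIRE averaging uses the extra transients that the
# NOAH framework makes available.  The saltire flip angle (cnst20) trades
# sensitivity against artifact level; t1 chunking is k-scaled via cnst21.
abbreviation: "P"
display_name: "PSYCHE pure shift"
category: PURESHIFT_2DJ
slot: HOMO
au_program: noah_psyche
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: []
t1_delay: d17
ea_gradients: []
supports_flags: []
parameters:
  - p1
  - p2
  - p16
  - p40
  - d16
  - d17
  - cnst20
  - cnst21
  - {kind: LOCAL_DELAY, name: DH_PSYCHE1, definition: "DH_PSYCHE1=in17*cnst21/2", comment: "half t1 chunk duration (k-scaled)"}
phase_cycles: [ph1, ph5, ph29]
gradients: [gpz22, gpz23]
wavemaker:
  - ";sp40:wvm:psyche_saltire: saltire(30 ms; Q=0.15)"
variants: []
body: |
  ; PSYCHE pure shift (pseudo-2D, SAPPHIRE averaging)
  (p1 ph1):f1
  DH_PSYCHE1
  (p2 ph5):f1
  DH_PSYCHE1
  p16:gp23
  d16
  (p40:sp40 ph5):f1 ; saltire pair, flip angle cnst20
  p40:gp22
  d16
  p16:gp23
  d16
  d17
  goscnp ph29
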