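# 15N HMQC.  CTP selection uses a single PFG in each half of t1 (duration
# 2.5 ms, amplitude 80%) so that bulk magnetization evolving in one t1 half
# is dephased; this suppresses "wing artifacts" in downstream homonuclear
# modules.  The refocusing gradient amplitude is n * g1 * |gammaN/gammaH|
# with n = 2 bracketing PFGs, i.e. 2 * 8.1%.
abbreviation: "M"
display_name: "15N HMQC"
category: HET_15N
slot: N15
au_program: noah_hmqc
pools_required: [N15_BOUND_1H]
pools_consumed: [N15_BOUND_1H]
pools_preserved: [BULK_1H, C13_BOUND_1H]
t1_delay: d20
ea_gradients: [11]
supports_flags: [NUS]
parameters:
  - p1
  - p2
  - p19
  - p21
  - d16
  - d20
  - cnst4
  - {kind: LOCAL_DELAY, name: DN_HMQC1, definition: "DN_HMQC1=0.5s/cnst4", comment: "1/(2J(NH)) transfer delay"}
phase_cycles: [ph1, ph2, ph5, ph29]
gradients: [gpz10, gpz11]
wavemaker: []
variants: []
body: |
  ; 15N HMQC
  (p1 ph5):f1
  DN_HMQC1
  (p21 ph1):f3
  p19:gp10
  d16
  d20
  (p2 ph5):f1
  d20
  p19:gp10
  d16
  (p21 ph2):f3
  DN_HMQC1
  p19:gp11*EA
  d16
  goscnp ph29
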