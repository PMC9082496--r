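# 13C zz-HMBC.  Placed first in a supersequence: the zz-filter excites only
# the bulk (12C-bound) 1H pool and returns heteronucleus-bound 1H to +z.
# The 13C 90-degree pulse after the zz-filter converts residual antiphase
# 1H-13C magnetization into multiple-quantum terms that the low-pass
# J-filter dephases, suppressing one-bond artifacts.
# Body lines are stored flush-left; the assembler indents instructions.
abbreviation: "B"
display_name: "13C zz-HMBC"
category: HET_13C
slot: HMBC
au_program: noah_hmbc
pools_required: [BULK_1H]
pools_consumed: [BULK_1H]
pools_preserved: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
t1_delay: d0
ea_gradients: [5]
supports_flags: [NUS]
parameters:
  - p1
  - p2
  - p3
  - p16
  - d0
  - d4
  - d16
  - cnst2
  - cnst13
  - {kind: LOCAL_DELAY, name: DC_HMBC1, definition: "DC_HMBC1=0.5s/cnst13", comment: "1/(2 nJ(CH)) long-range evolution delay"}
  - {kind: LOCAL_DELAY, name: DC_HMBC2, definition: "DC_HMBC2=p16+d16+4u", comment: "gradient + recovery compensation delay"}
phase_cycles: [ph1, ph2, ph5, ph6, ph30]
gradients: [gpz1, gpz2, gpz3, gpz4, gpz5]
wavemaker: []
variants:
  - label: NONE
    description: "zz-filter retaining no heteronucleus-bound 1H"
    retains: []
    extra_parameters: []
    block: |
      ; zz-filter (no heteronucleus-bound 1H retained)
      (p1 ph5):f1
      p16:gp1
      d16
      (p1 ph6):f1
      p16:gp2
      d16
  - label: "C"
    description: "zz-filter retaining 13C-bound 1H"
    retains: [C13_BOUND_1H]
    extra_parameters: [p4]
    block: |
      ; zz-filter (retains 13C-bound 1H)
      (p1 ph5):f1
      d4
      (p2 ph5):f1 (p4 ph5):f2
      d4
      (p1 ph6):f1 (p3 ph5):f2
      p16:gp1
      d16
      (p3 ph5):f2
      p16:gp2
      d16
  - label: "N"
    description: "zz-filter retaining 15N-bound 1H"
    retains: [N15_BOUND_1H]
    extra_parameters: [p21, p22, d24, cnst4]
    block: |
      ; zz-filter (retains 15N-bound 1H)
      (p1 ph5):f1
      d24
      (p2 ph5):f1 (p22 ph5):f3
      d24
      (p1 ph6):f1 (p21 ph5):f3
      p16:gp1
      d16
      (p21 ph5):f3
      p16:gp2
      d16
  - label: CN
    description: "zz-filter retaining 13C- and 15N-bound 1H"
    retains: [C13_BOUND_1H, N15_BOUND_1H]
    extra_parameters: [p4, p21, p22, d24, cnst4]
    block: |
      ; zz-filter (retains 13C- and 15N-bound 1H)
      (p1 ph5):f1
      d24
      (p2 ph5):f1 (p4 ph5):f2 (p22 ph5):f3
      d24
      (p1 ph6):f1 (p3 ph5):f2 (p21 ph5):f3
      p16:gp1
      d16
      (p3 ph5):f2 (p21 ph5):f3
      p16:gp2
      d16
body: |
  ; 13C zz-HMBC
  <<ZZFILTER>>
  (p3 ph5):f2 ; 13C 90 degree purge pulse: antiphase 1H-13C -> MQ, dephased by LPJF
  ; low-pass J-filter
  d4
  (p3 ph1):f2
  p16:gp3
  d16
  ; long-range evolution
  DC_HMBC1
  (p3 ph2):f2
  d0
  (p2 ph5):f1
  d0
  p16:gp4
  d16
  (p3 ph2):f2
  DC_HMBC2
  p16:gp5*EA
  d16
  goscnp ph30
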