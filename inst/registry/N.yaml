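# NOESY.  Presaturation may be applied during the mixing time (PRESAT flag);
# zero-quantum suppression during mixing is guarded by the ZQS flag.
abbreviation: "N"
display_name: "NOESY"
category: HOMONUCLEAR
slot: HOMO
au_program: noah_noesy
pools_required: [BULK_1H]
pools_consumed: [BULK_1H, C13_BOUND_1H, N15_BOUND_1H]
pools_preserved: [BULK_1H]
t1_delay: d14
ea_gradients: []
supports_flags: [ES, NUS, PRESAT, ZQS]
parameters:
  - p1
  - p2
  - p12
  - p16
  - p32
  - d8
  - d14
  - d16
phase_cycles: [ph1, ph5, ph6, ph29]
gradients: [gpz19, gpz20, gpz27]
wavemaker:
  - ";sp1:wvm:sqa100H1: squa100.1000(2 ms; L2H)"
  - ";sp32:wvm:zqs_chirp: smoothed_chirp(20 ms, 40 kHz; L2H)"
variants: []
body: |
  ; NOESY
  (p1 ph1):f1
  d14
  (p1 ph5):f1
  #ifdef ZQS
  ; zero-quantum suppression (swept-frequency pulse + weak gradient)
  (p32:sp32 ph5):f1
  p16:gp27
  d16
  #endif
  #ifdef PRESAT
  ; presaturation during the NOE mixing time
  4u pl9:f1
  d8 cw:f1
  4u do:f1
  4u pl1:f1
  #else
  d8 ; NOE mixing time
  #endif
  p16:gp19
  d16
  (p1 ph5):f1
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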