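# Shared dictionary of standardized TopSpin parameters, phase cycles and
# gradient channels.  Module files reference these entries by token so that
# every symbol has exactly one meaning across all supersequences; see
# README.md in this directory for the schema.
parameters:
  p1:  {kind: PULSE, definition: "", comment: "f1 channel - 90 degree high power pulse"}
  p2:  {kind: PULSE, definition: "p2=p1*2", comment: "f1 channel - 180 degree high power pulse"}
  p3:  {kind: PULSE, definition: "", comment: "f2 channel - 90 degree high power pulse"}
  p4:  {kind: PULSE, definition: "p4=p3*2", comment: "f2 channel - 180 degree high power pulse"}
  p12: {kind: PULSE, definition: "", comment: "f1 channel - 180 degree shaped pulse (excitation sculpting)"}
  p14: {kind: PULSE, definition: "", comment: "f2 channel - 180 degree shaped adiabatic pulse"}
  p16: {kind: PULSE, definition: "", comment: "pulsed field gradient (1 ms)"}
  p19: {kind: PULSE, definition: "", comment: "pulsed field gradient (2.5 ms)"}
  p21: {kind: PULSE, definition: "", comment: "f3 channel - 90 degree high power pulse"}
  p22: {kind: PULSE, definition: "p22=p21*2", comment: "f3 channel - 180 degree high power pulse"}
  p32: {kind: PULSE, definition: "", comment: "f1 channel - swept-frequency pulse (zero-quantum suppression)"}
  p40: {kind: PULSE, definition: "", comment: "f1 channel - PSYCHE saltire/chirp pulse"}
  p41: {kind: PULSE, definition: "", comment: "f1 channel - ASAP isotropic mixing element"}
  p43: {kind: PULSE, definition: "", comment: "f1 channel - DIPSI-2 isotropic mixing element"}
  p44: {kind: PULSE, definition: "", comment: "f1 channel - ROESY spin lock"}
  d0:  {kind: DELAY, definition: "d0=3u", comment: "t1/2 for HMBC (incremented)"}
  d1:  {kind: DELAY, definition: "", comment: "recovery (relaxation) delay"}
  d4:  {kind: DELAY, definition: "d4=0.25s/cnst2", comment: "1/(4J(CH))"}
  d8:  {kind: DELAY, definition: "", comment: "NOESY mixing time"}
  d10: {kind: DELAY, definition: "d10=3u", comment: "t1/2 for 13C HSQC-type modules (incremented)"}
  d11: {kind: DELAY, definition: "d11=3u", comment: "t1 for COSY (incremented)"}
  d12: {kind: DELAY, definition: "d12=3u", comment: "t1 for CLIP-COSY (incremented)"}
  d13: {kind: DELAY, definition: "d13=3u", comment: "t1 for TOCSY (incremented)"}
  d14: {kind: DELAY, definition: "d14=3u", comment: "t1 for NOESY (incremented)"}
  d15: {kind: DELAY, definition: "d15=3u", comment: "t1 for ROESY (incremented)"}
  d16: {kind: DELAY, definition: "", comment: "gradient recovery delay"}
  d17: {kind: DELAY, definition: "d17=3u", comment: "t1 chunk delay for PSYCHE (incremented)"}
  d18: {kind: DELAY, definition: "d18=3u", comment: "t1 chunk delay for TSE-PSYCHE (incremented)"}
  d19: {kind: DELAY, definition: "d19=3u", comment: "t1 for PSYCHE 2DJ (incremented)"}
  d20: {kind: DELAY, definition: "d20=3u", comment: "t1/2 for 15N modules (incremented)"}
  d23: {kind: DELAY, definition: "d23=3u", comment: "t1 for magnitude-mode 2DJ (incremented)"}
  d24: {kind: DELAY, definition: "d24=0.25s/cnst4", comment: "1/(4J(NH))"}
  cnst2:  {kind: CONSTANT, definition: "", comment: "= 1J(CH) in Hz"}
  cnst4:  {kind: CONSTANT, definition: "", comment: "= 1J(NH) in Hz"}
  cnst13: {kind: CONSTANT, definition: "", comment: "= nJ(CH) long-range coupling in Hz"}
  cnst16: {kind: CONSTANT, definition: "", comment: "= J(HH) in Hz (CLIP-COSY transfer)"}
  cnst20: {kind: CONSTANT, definition: "", comment: "PSYCHE saltire flip angle in degrees"}
  cnst21: {kind: CONSTANT, definition: "", comment: "k-scaling factor for pure shift / 2DJ t1"}
phases:
  ph1:  {steps: ["x", "-x"], receiver: false}
  ph2:  {steps: ["x", "x", "-x", "-x"], receiver: false}
  ph3:  {steps: ["y", "y", "-y", "-y"], receiver: false}
  ph5:  {steps: ["x"], receiver: false}
  ph6:  {steps: ["y"], receiver: false}
  ph29: {steps: ["x", "-x"], receiver: true}
  ph30: {steps: ["x", "-x", "-x", "x"], receiver: true}
gradients:
  gpz1:  {amplitude: -15, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "zz-filter purge 1 (HMBC)"}
  gpz2:  {amplitude: 10, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "zz-filter purge 2 (HMBC)"}
  gpz3:  {amplitude: 5, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "low-pass J-filter purge (HMBC)"}
  gpz4:  {amplitude: 80, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP encode (HMBC)"}
  gpz5:  {amplitude: 40.2, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: true, comment: "CTP refocus (HMBC, echo-antiecho)"}
  gpz6:  {amplitude: 80, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP encode (13C HSQC-type)"}
  gpz7:  {amplitude: 20.1, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: true, comment: "CTP refocus (13C HSQC-type, echo-antiecho)"}
  gpz8:  {amplitude: 11, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "ZIP element purge"}
  gpz9:  {amplitude: 17, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "mixing purge (HSQC-TOCSY)"}
  gpz10: {amplitude: 80, duration_ms: 2.5, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP encode, t1-bracketing pair (15N HMQC)"}
  gpz11: {amplitude: 16.2, duration_ms: 2.5, shape: SMSQ10.100, echo_antiecho: true, comment: "CTP refocus (15N HMQC, echo-antiecho)"}
  gpz12: {amplitude: 80, duration_ms: 2.5, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP encode, t1-bracketing pair (15N seHSQC)"}
  gpz13: {amplitude: 16.2, duration_ms: 2.5, shape: SMSQ10.100, echo_antiecho: true, comment: "CTP refocus (15N seHSQC, echo-antiecho)"}
  gpz14: {amplitude: 31, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "inter-module purge gradient"}
  gpz15: {amplitude: 30, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP selection (COSY)"}
  gpz16: {amplitude: 43, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "perfect echo purge 1 (CLIP-COSY)"}
  gpz17: {amplitude: 32, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "perfect echo purge 2 (CLIP-COSY)"}
  gpz18: {amplitude: 49, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "mixing purge (TOCSY)"}
  gpz19: {amplitude: 40, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "mixing-time purge (NOESY)"}
  gpz20: {amplitude: 22, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "excitation sculpting gradient pair"}
  gpz21: {amplitude: 37, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "spin-lock purge (ROESY)"}
  gpz22: {amplitude: 2, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "weak CTP gradient during PSYCHE element"}
  gpz23: {amplitude: 49, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP selection (PSYCHE)"}
  gpz24: {amplitude: 77, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "TSE echo gradient (TSE-PSYCHE)"}
  gpz25: {amplitude: 33, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "CTP selection (magnitude 2DJ)"}
  gpz26: {amplitude: 15, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "purge before ASAP mixing"}
  gpz27: {amplitude: 3, duration_ms: 1, shape: SMSQ10.100, echo_antiecho: false, comment: "zero-quantum suppression gradient"}
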