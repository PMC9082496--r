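# noahgen

Offline generation of Bruker-dialect pulse programs for **NOAH NMR
supersequences** (NMR by Ordered Acquisition using ¹H detection).

NOAH experiments concatenate up to five 2D modules — HMBC, HSQC, seHSQC,
HMQC, COSY, CLIP-COSY, TOCSY, NOESY, ROESY, HSQC-TOCSY, and pure shift /
2D J experiments — into one supersequence sharing a single recovery delay
*d*₁, cutting total experiment time by up to a factor of the module count.
Each combination needs its own pulse program, hundreds of lines long and
easy to get wrong by hand. `noahgen` generates them from a data-driven
module registry, for spectroscopists who want a tailored supersequence and
for sequence developers who want to add or modify a module once and have
every combination updated.

## The model at the core

Module ordering is governed by bookkeeping of three ¹H magnetization
pools: the *bulk* pool (protons on NMR-inactive ¹²C), the ¹³C-bound pool
and the ¹⁵N-bound pool. Each module declares the pools it requires,
consumes and preserves; an ordering is viable when no module destroys a
pool a later module draws on (with two documented tolerated-loss
exceptions), modules follow the slot order HMBC → ¹⁵N → ¹³C →
homonuclear, and no slot is over-occupied. Hence SC (HSQC → COSY) is
viable while CS is not, and BSC is the preferred HMBC/HSQC/COSY layout.
Enumeration over the shipped 15-module registry yields **1184 viable
supersequences** of 2–5 modules.

Transfer delays derive from scalar couplings, Δ = 1/(4·¹J꜀ₕ),
Δ_LR = 1/(2·ⁿJ꜀ₕ), Δ_N = 1/(4·¹Jₙₕ), and coherence-transfer-pathway
gradient amplitudes from gyromagnetic ratios: a refocusing gradient is
*n*·round(g₁·|γₓ/γₕ|, 1) for *n* bracketing PFGs of amplitude g₁ — e.g.
8.1 % per gradient for ¹⁵N at g₁ = 80 %, hence ±16.2 % in the two-PFG
¹⁵N HMQC scheme, and ±40.2 % for the ¹³C zz-HMBC.

## Worked example

```r
library(noahgen)

check_viability(c("C", "S"))
#> NOT viable
#>   [fatal] S (C13) may not follow C (HOMO): modules must be ordered HMBC, 15N, 13C, then homonuclear
#>   [fatal] C consumes C13_BOUND_1H magnetization needed by later module S

prog <- build_pulse_program(c("B", "S", "C"), flags = "ES",
                            timestamp = "2022-01-20T00:00:00Z")
head(as.character(prog), 7)
```

```
; === pulse program header ===
; ngn_noah3-BSC
; NOAH-3 supersequence: 13C zz-HMBC + 13C HSQC + COSY
; modules: B,S,C
; delta = 1.7241 ms (1J(CH) = 145 Hz); delta_LR = 100.0000 ms (nJ(CH) = 5 Hz); delta_N = 2.7778 ms (1J(NH) = 90 Hz)
;zgoptns: -DES
;flags-available: EDIT,ES,NUS,PRESAT
```

The header records the computed transfer delays (1.7241 ms is
1/(4 × 145 Hz)) and the acquisition flags; the zz-filter variant retaining
¹³C-bound magnetization is selected automatically because an HSQC follows
the HMBC, and ASAP mixing is placed before the COSY. The program ends with
the reproducibility footer that the processing script parses to dispatch
each module's FIDs to its AU program:

```
;MODULES: B,S,C
;AUPROG: noah_hmbc,noah_hsqc,noah_cosy
;VERSION: 2.1.0
;TIMESTAMP: 2022-01-20T00:00:00Z
```

```r
lint_pulse_program(prog)$passed     # TRUE
generate_nus_schedule(16, 0.25, seed = 7)$increments
#> [1]  1  4 11 13
```

The same operations are available from the shell via the installed
`exec/noahgen` script:

```sh
noahgen build --modules B,S,C --flags ES --out noah3-BSC.prog
noahgen explain C,S            # exit status 3, prints the diagnostics
noahgen enumerate              # "1184 viable supersequences"
noahgen nus --td1 64 --fraction 0.25 --seed 11 --out sched.nus
```

Exit codes: 0 ok, 2 usage error, 3 viability failure, 4 parameter/phase
conflict, 5 lint failure.

## Layout

- `inst/registry/` — one YAML document per module plus the shared
  standardized parameter/phase/gradient dictionary (schema in
  `inst/registry/README.md`); adding a module is a data change.
- `R/` — registry loader, viability engine, variant resolver, assembler,
  flags/NUS, linter and CLI.
- `vignettes/noah-supersequence-generation.Rmd` — the methods vignette:
  the magnetization-pool model, the enumeration rules and their relation
  to published counts, the generated format, and design decisions.
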