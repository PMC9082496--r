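---
title: "Generating NOAH supersequence pulse programs"
author: "noahgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating NOAH supersequence pulse programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noahgen)
```

## The problem

NOAH (NMR by Ordered Acquisition using ^1^H detection) experiments
concatenate several 2D NMR modules — HMBC, HSQC, seHSQC, HMQC, COSY,
TOCSY, NOESY, ROESY, and pure shift / 2D J experiments — into a single
"supersequence" sharing one recovery delay, so that a full small-molecule
characterization data set is acquired in a fraction of the conventional
time. The price is engineering complexity: each module combination needs
its own Bruker pulse program, typically hundreds of lines long, with
mutually consistent parameter numbering, phase cycles, gradient tables and
processing metadata. `noahgen` generates these programs from a data-driven
module registry, the way a compiler generates code from a library of
well-tested templates: each module is defined once and is then usable in
every combination.

## The magnetization-pool model

The physical constraint on module ordering is bookkeeping of three ^1^H
magnetization pools:

* **bulk** magnetization — protons bound to NMR-inactive ^12^C (the vast
  majority at 1.1% ^13^C natural abundance);
* **^13^C-bound** protons;
* **^15^N-bound** protons.

A well-behaved module excites only the pool it needs and returns the rest
to +*z*. The ^13^C HSQC, for example, draws on the ^13^C-bound pool and
leaves the bulk intact, so a COSY can follow it with essentially no
sensitivity loss (SC is viable); in the reverse order the nonselective
COSY destroys the ^13^C-bound pool first (CS is not viable). Each module
therefore declares three sets: the pools it *requires*, the pools it
*consumes*, and the pools it *preserves*; a pool that is both consumed and
preserved survives partially (the HMBC's zz-filter leaves part of the bulk
pool; a COSY leaves enough bulk for a second homonuclear module).

`check_viability()` flags a fatal diagnostic whenever a module consumes a
pool that a later module requires, unless one of two documented
tolerated-loss rules applies: a homonuclear module may follow an HMBC
(their shared bulk-pool loss is tolerated because the homonuclear
experiment is vastly more sensitive), and a second homonuclear module may
follow a first (partial bulk survival). On top of the pool logic, modules
must follow the slot ordering HMBC → ^15^N → ^13^C → homonuclear/pure
shift, each heteronuclear slot holds at most one module, at most two
homonuclear/pure-shift modules are allowed, and no module repeats.

```{r}
check_viability(c("C", "S"))
```

### Enumeration and the viable count

`enumerate_viable()` walks the registry depth-first, pruning on the prefix
property (every length-≥2 prefix of a viable sequence is viable — a tested
invariant). The test suite proves it equivalent to brute-force filtering
of all ordered selections on reduced registries, and checks the count on
the full registry against a closed-form combinatorial computation over the
slot rules. Under this package's 15-module inventory and the rules above
there are 1184 viable supersequences of 2–5 modules. Published counts for
the web-based generator are larger (4242 at its v2.1.0 release) because
its registry counts additional module versions that are represented here
as flags or variants of a single module rather than as separate modules;
the counting conventions of that tally are not reproducible from the main
text, so this package pins its enumeration to the documented rule set and
asserts the structural properties (oracle equivalence, prefix closure,
monotonicity under registry restriction) instead of the headline figure.

## Context-sensitive resolution

Three decisions depend on the whole sequence, not on a single module:

* **zz-filter form (HMBC).** The HMBC's zz-filter must return to +*z*
  exactly those heteronucleus-bound pools that later modules draw on. The
  choice is a pure function of the set of later modules' required pools:
  retain neither / ^13^C / ^15^N / both (`resolve_hmbc_filter()`, labels
  `NONE`, `C`, `N`, `CN`). In developer mode an explicit override wins.
* **ZIP insertion (seHSQC).** The sensitivity-enhanced HSQC saturates bulk
  magnetization unless a ZIP element is prepended; the element costs a
  little sensitivity, so it is inserted exactly when a later module still
  needs the bulk pool and omitted when the module is last
  (`resolve_zip()`).
* **Glue.** ASAP isotropic mixing is placed immediately before the first
  homonuclear module when an HMBC precedes it, redistributing the shared
  bulk magnetization; every other internal boundary receives a purge pulse
  + gradient. ASAP is suppressed when the homonuclear module is a NOESY
  (mixing immediately before the NOE period would perturb the buildup);
  the `"ASAP"` option forces it. Whether mixing helps before TOCSY or
  CLIP-COSY exactly as before COSY is treated uniformly here.

## The generated format

`assemble()` renders a resolved sequence into a nine-section document:
header comments; `define delay` blocks for module-local delays (named
`DC_HSQC1`-style, first letter = indirect nucleus); standardized parameter
relations (`"d4=0.25s/cnst2"`); the main instruction block (module bodies
concatenated with glue); t1-incrementation and echo–antiecho
gradient-inversion commands; merged phase cycles; gradient comments
(gppp-compatible); WaveMaker directives; ased parameter descriptions; and
a reproducibility footer:

```
;MODULES: B,S,C
;AUPROG: noah_hmbc,noah_hsqc,noah_cosy
;VERSION: 2.1.0
;TIMESTAMP: 2022-01-20T00:00:00Z
```

`parse_footer()` recovers all four lines exactly — this is the contract
that lets a processing script split the interleaved FIDs and dispatch each
module's data to its AU program without user-set parameters. The
timestamp is injectable, so output is byte-deterministic for testing.

Parameter standardization is enforced at registry curation time: a token
(`p#`, `d#`, `cnst#`, `gpz#`, `ph#`) means the same thing in every module,
identical duplicate definitions are merged at collation, and a genuine
conflict is an error naming both modules — never a silent renumbering.
Each module owns exactly one receiver phase cycle; because NOAH acquires
one FID per module, the assembled program's phase table contains one
receiver list per acquisition statement, all collated with program-wide
unique indices.

The emitted dialect is a documented subset of the Bruker language (`;`
comments, `define delay`, quoted relations, `#ifdef` conditionals, an
explicit loop tail). Full TopSpin macro fidelity is not claimed; the
package's linter defines conformance, and the test suite lints every one
of the 1184 enumerated supersequences and checks the footer round trip on
each.

## Acquisition flags and NUS

Optional features are compiled conditionally: multiplicity editing
(`EDIT`), excitation sculpting with a shaped + hard 180° pair (`ES`),
presaturation during the recovery delay and NOESY mixing time (`PRESAT`),
zero-quantum suppression (`ZQS`) and nonuniform sampling (`NUS`). The
guarded blocks are always present in the text — one program serves all
flag combinations — and `apply_flags()` records the chosen `-D` symbols in
the `;zgoptns:` header comment. The linter verifies that every guard
symbol is known and balanced under all subsets.

NUS schedules are generated by `generate_nus_schedule()`: uniform random
sampling without replacement, with increment 1 always included to anchor
the interferogram, deterministic given a seed, written one increment per
line to a sidecar file. Uniform sampling was chosen as the simplest
defensible default (the weighting used by the original initialization
script is not documented); the sampling law is isolated in one function
and is straightforward to replace with, e.g., Poisson-gap sampling.

## Numerical choices and defaults

* Coupling-constant defaults: ^1^J~CH~ = 145 Hz, ^n^J~CH~ = 5 Hz,
  ^1^J~NH~ = 90 Hz — conventional small-molecule values, overridable via
  `coupling_constants()` or the CLI config file. Transfer delays follow
  Δ = 1/(4·^1^J~CH~), Δ~LR~ = 1/(2·^n^J~CH~), Δ~N~ = 1/(4·^1^J~NH~).
* Gyromagnetic ratios: γ~H~ = 26.7522128×10⁷, γ~C~ = 6.728284×10⁷,
  γ~N~ = −2.7126×10⁷ rad s⁻¹ T⁻¹. CTP refocusing amplitudes are
  n·round(g₁·|γ~X~/γ~H~|, 1): with g₁ = 80% this gives 20.1% per gradient
  for ^13^C and 8.1% for ^15^N; the ^15^N HMQC uses two 2.5 ms bracketing
  PFGs, hence ±16.2%, and the zz-HMBC's published ±40.2% echo–antiecho
  gradient is carried in the registry.
* Timestamps are ISO-8601 UTC and injectable; all enumeration and assembly
  is deterministic, and the only randomness in the package (NUS sampling)
  is seed-controlled and restores the caller's RNG state.

## What the tests do and do not show

The test suite covers the printed constants of the registry (zz-HMBC phase
cycles and gradient table; HMQC bracketing scheme), the viability ground
truths (SC/BSC accepted, CS/SBC rejected), the decision tables, exhaustive
lint-cleanliness and footer round-trips over all 1184 enumerated
sequences, and the NUS invariants over 1000 seeded draws (problem sizes
chosen to keep the default run in the minutes range). What none of this
shows is spectroscopic correctness on a spectrometer: artifact suppression
and sensitivity are properties of spins, not of text, and validating them
requires acquiring spectra. The package's claim is narrower and checkable:
the generated programs are internally consistent, deterministic, complete
with respect to their own symbol tables, and faithful to the published
module parameters.

## Known limitations

* The registry is reconstructed from published module descriptions; it is
  not a byte-level copy of any existing generator's output, and the
  unpublished variant labels of the HMBC family are implementation-chosen.
* Only the Bruker dialect subset described above is emitted; parallel
  ("p-NOAH") supersequences, pulse-shape waveform synthesis and spin
  dynamics simulation are out of scope.
* ASAP mixing times, PSYCHE flip angles and similar acquisition parameters
  are exposed as constants for the operator to set, not optimized.
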