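# Module registry schema

One YAML document per NOAH module, plus `_common.yaml`, the shared
dictionary of standardized TopSpin parameters, phase cycles and gradient
channels. Adding a module to the library is a data change: drop a new file
in this directory.

## Module file keys

| key | meaning |
|-----|---------|
| `abbreviation` | short CLI-safe module name (`B`, `S`, `Sp`, `SNp`, ...) |
| `display_name` | human-readable experiment name |
| `category` | one of `HET_13C`, `HET_15N`, `HOMONUCLEAR`, `PURESHIFT_2DJ` |
| `slot` | ordering slot: `HMBC`, `N15`, `C13` or `HOMO` (viability engine) |
| `au_program` | processing AU program recorded in the footer |
| `pools_required` | magnetization pool(s) the module draws on |
| `pools_consumed` | pool(s) destroyed by the module |
| `pools_preserved` | pool(s) surviving it (intersection with consumed = partial survival) |
| `t1_delay` | the incremented indirect-dimension delay token |
| `ea_gradients` | gpz indices whose sign alternates between FIDs (echo-antiecho) |
| `supports_flags` | acquisition flags with guarded blocks in the body |
| `parameters` | list of shared tokens (strings, resolved in `_common.yaml`) or full entries `{kind, name, definition, comment}` (used for the named local delays `D<X>_<NAME><n>`) |
| `phase_cycles` | shared phase tokens (`ph1`, ...); exactly one must be a receiver cycle |
| `gradients` | shared gradient tokens (`gpz1`, ...) |
| `wavemaker` | WaveMaker directive lines emitted verbatim |
| `variants` | optional list `{label, description, retains, extra_parameters, block}`; the block replaces the `<<ZZFILTER>>` placeholder |
| `zip_block` | optional block substituted for `<<ZIP>>` when a later module needs bulk 1H |
| `body` | pulse program instructions, flush-left; the assembler indents |

Magnetization pools: `BULK_1H` (protons on NMR-inactive 12C), `C13_BOUND_1H`,
`N15_BOUND_1H`.

Every `p#`, `d#`, `cnst#`, `gpz#`/`gp#`, `ph#` or named-delay token used in a
body, variant block or ZIP block must resolve within the module's own tables
(checked at load time and by the test suite). Entries with the same token in
different modules must be identical; sharing is the norm and is what makes
concatenation safe.
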