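Package: noahgen
Title: Assembly of NOAH NMR Supersequence Pulse Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Offline generator for Bruker-dialect pulse programs implementing
    NOAH (NMR by Ordered Acquisition using 1H detection) supersequences.
    Modules (HMBC, HSQC, seHSQC, HMQC, COSY, TOCSY, NOESY, ROESY, pure shift
    and 2D J experiments) are described in a data-driven registry; the package
    checks magnetization-pool viability of module orderings, enumerates viable
    supersequences, resolves context-sensitive module variants (zz-filter
    forms, ZIP insertion, inter-module glue), assembles complete annotated
    pulse programs with a reproducibility footer, supports acquisition flags
    and nonuniform-sampling schedules, and ships a linter plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
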