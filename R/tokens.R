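# Tokenizer for the Bruker-dialect subset emitted by the assembler.
# Recognised symbol families: p# (pulses), d# (delays), cnst# (constants),
# gpz#/gp# (gradient amplitudes), ph# (phase cycles), and named local delays
# of the form D<nucleus letter>_<MODULE><n> (e.g. DC_HSQC1).

.token_regexes <- c(
  pulse    = "\\bp[0-9]+\\b",
  delay    = "\\bd[0-9]+\\b",
  constant = "\\bcnst[0-9]+\\b",
  gradient = "\\bgpz?[0-9]+\\b",
  phase    = "\\bph[0-9]+\\b",
  local    = "\\b[A-Z]{1,2}_[A-Z0-9_]*[0-9]\\b"
)

# strip whole-line and trailing `;` comments
strip_comments <- function(lines) sub(";.*$", "", lines)

# Extract referenced tokens from pulse-program instruction lines.
# `gp#` references are normalised to `gpz#`.  Preprocessor lines (#ifdef etc)
# are skipped; their symbols are handled separately by the linter.
extract_tokens <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  code <- strip_comments(lines)
  out <- character(0)
  for (rx in .token_regexes) {
    m <- regmatches(code, gregexpr(rx, code))
    out <- c(out, unlist(m, use.names = FALSE))
  }
  out <- sub("^gp([0-9]+)$", "gpz\\1", out)
  unique(out)
}

# preprocessor symbols used in #ifdef lines
extract_guard_symbols <- function(lines) {
  m <- regmatches(lines, regexec("^\\s*#ifdef\\s+([A-Za-z0-9_]+)", lines))
  unique(vapply(Filter(function(x) length(x) == 2, m), `[[`, "", 2))
}
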