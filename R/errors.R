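# Classed conditions. Every error raised by the package carries class
# "noah_error" plus a specific subclass so that callers (and the CLI exit-code
# map) can dispatch without string matching.

noah_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "noah_error")))
}

# precondition helper: `cond` must be TRUE
noah_stopifnot <- function(cond, message, class = "noah_precondition") {
  if (!isTRUE(cond)) noah_abort(message, class)
  invisible(TRUE)
}
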