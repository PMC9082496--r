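# Acquisition flags: optional features compiled conditionally via TopSpin's
# zgoptns mechanism.  The assembled text always contains the guarded blocks,
# so one pulse program serves all flag combinations; applying flags only
# records the -D symbols in the header comment that users copy into zgoptns.

#' Known acquisition flags
#'
#' @return Data frame describing each flag symbol, its effect, and where it
#'   applies.
#' @export
acquisition_flags <- function() {
  data.frame(
    symbol = c("EDIT", "ES", "NUS", "PRESAT", "ZQS"),
    effect = c(
      "multiplicity editing in HSQC-type modules",
      "excitation sculpting (shaped + hard 180) before homonuclear acquisition",
      "nonuniform sampling of the indirect dimension from a schedule file",
      "presaturation during the recovery delay (and NOESY mixing time)",
      "zero-quantum suppression during NOESY mixing"
    ),
    applies_to = c("HSQC-type modules", "homonuclear modules", "t1 modules",
                   "recovery delay / NOESY", "NOESY"),
    stringsAsFactors = FALSE
  )
}

#' Record acquisition flags in an assembled pulse program
#'
#' Validates the flag symbols and rewrites the `;zgoptns:` header line to
#' list them as `-D` symbols.  The guarded `#ifdef` blocks themselves are
#' always present in the text (that is the point of acquisition flags: one
#' program for all uses), so apart from the header line the text is
#' unchanged.
#'
#' @param program A `noah_program` from [assemble()].
#' @param flags Character vector of flag symbols (subset of
#'   `acquisition_flags()$symbol`).
#' @return The modified `noah_program`.
#' @export
#' @examples
#' prog <- assemble(resolve_sequence(c("S", "C")))
#' prog <- apply_flags(prog, c("ES", "NUS"))
apply_flags <- function(program, flags) {
  noah_stopifnot(inherits(program, "noah_program"),
                 "apply_flags needs an assembled program")
  flags <- unique(as.character(flags))
  known <- acquisition_flags()$symbol
  bad <- setdiff(flags, known)
  if (length(bad)) {
    noah_abort(sprintf("unknown acquisition flag '%s' (known: %s)", bad[[1]],
                       paste(known, collapse = ",")), "noah_unknown_flag")
  }
  avail_line <- grep("^;flags-available: ", program$sections$header, value = TRUE)
  if (length(avail_line) == 1) {
    avail <- strsplit(sub("^;flags-available: ", "", avail_line), ",")[[1]]
    unsupported <- setdiff(flags, avail)
    if (length(unsupported)) {
      warning(sprintf("flag(s) %s have no effect in this supersequence",
                      paste(unsupported, collapse = ",")), call. = FALSE)
    }
  }
  value <- if (length(flags)) paste0("-D", sort(flags), collapse = " ") else "(none)"
  i <- grep("^;zgoptns:", program$sections$header)
  program$sections$header[i] <- paste0(";zgoptns: ", value)
  program
}
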