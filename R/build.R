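#' Build a complete pulse program for a supersequence
#'
#' One-call pipeline: viability check, variant/glue resolution, assembly and
#' flag application.  Outside developer mode a non-viable module ordering is
#' an error carrying the verdict; in developer mode generation proceeds with
#' a warning.
#'
#' @param modules Character vector of module abbreviations (or one
#'   comma-separated string), in acquisition order.
#' @param flags Acquisition flag symbols recorded in the zgoptns header line
#'   (see [acquisition_flags()]).
#' @param options Behaviour options (e.g. `"ASAP"` to force ASAP mixing
#'   before a NOESY module).
#' @param developer Lift length and viability restrictions.
#' @param variant_overrides Named vector of variant labels (developer mode).
#' @param version,timestamp Metadata for the reproducibility footer; a fixed
#'   timestamp makes the output byte-reproducible.
#' @param couplings A [coupling_constants()] object.
#' @return A `noah_program`.
#' @export
#' @examples
#' prog <- build_pulse_program(c("B", "S", "C"),
#'                             timestamp = "2022-01-20T00:00:00Z")
#' parse_footer(prog)$au_programs
build_pulse_program <- function(modules, flags = character(),
                                options = character(), developer = FALSE,
                                variant_overrides = NULL,
                                version = "2.1.0", timestamp = NULL,
                                couplings = coupling_constants()) {
  seq <- supersequence(modules, options = options, developer_mode = developer,
                       variant_overrides = variant_overrides)
  verdict <- check_viability(seq)
  if (!verdict$viable) {
    msgs <- paste(verdict$diagnostics$message[verdict$diagnostics$fatal],
                  collapse = "; ")
    if (!developer) {
      noah_abort(sprintf("supersequence %s is not viable: %s",
                         paste(seq$modules, collapse = ","), msgs),
                 "noah_not_viable", verdict = verdict)
    }
    warning(sprintf("developer mode: generating non-viable supersequence (%s)",
                    msgs), call. = FALSE)
  }
  prog <- assemble(resolve_sequence(seq),
                   generator_metadata(version = version, timestamp = timestamp),
                   couplings = couplings)
  apply_flags(prog, flags)
}
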