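#' Construct a NOAH supersequence request
#'
#' A supersequence is an ordered selection of 2-5 modules sharing one
#' recovery delay.  Outside developer mode the length limits are enforced at
#' construction; ordering/viability is checked by [check_viability()].
#'
#' @param modules Character vector of module abbreviations, in acquisition
#'   order (e.g. `c("B", "S", "C")`), or a single comma-separated string.
#' @param options Set of option symbols (acquisition flags such as
#'   `"PRESAT"`, or behaviour switches such as `"ASAP"` to force ASAP mixing
#'   before a NOESY module).
#' @param developer_mode Lift the length and viability restrictions;
#'   generation then proceeds with warnings instead of errors.
#' @param variant_overrides Named character vector mapping a module
#'   abbreviation to a variant label (honoured in developer mode only),
#'   e.g. `c(B = "CN")`.
#' @return An object of class `noah_supersequence`.
#' @export
#' @examples
#' supersequence(c("B", "S", "C"))
supersequence <- function(modules, options = character(),
                          developer_mode = FALSE,
                          variant_overrides = NULL) {
  if (length(modules) == 1 && grepl(",", modules)) {
    modules <- strsplit(modules, ",", fixed = TRUE)[[1]]
  }
  modules <- trimws(modules)
  noah_stopifnot(length(modules) >= 1, "at least one module is required",
                 "noah_bad_sequence")
  if (!developer_mode && (length(modules) < 2 || length(modules) > 5)) {
    noah_abort(sprintf("a supersequence has 2-5 modules (got %d); use developer mode to override",
                       length(modules)), "noah_bad_sequence")
  }
  known <- names(noah_registry()$modules)
  unknown <- setdiff(modules, known)
  if (length(unknown)) {
    noah_abort(sprintf("unknown module '%s'", unknown[[1]]), "noah_unknown_module")
  }
  if (!is.null(variant_overrides) &&
      (is.null(names(variant_overrides)) || any(!nzchar(names(variant_overrides))))) {
    noah_abort("variant_overrides must be a named vector", "noah_precondition")
  }
  structure(list(modules = modules, options = as.character(options),
                 developer_mode = isTRUE(developer_mode),
                 variant_overrides = variant_overrides),
            class = "noah_supersequence")
}

# accept either a supersequence or a bare character vector
as_supersequence <- function(x, developer_mode = FALSE) {
  if (inherits(x, "noah_supersequence")) return(x)
  supersequence(x, developer_mode = developer_mode)
}

#' @export
print.noah_supersequence <- function(x, ...) {
  cat(sprintf("<NOAH-%d supersequence> %s%s\n", length(x$modules),
              paste(x$modules, collapse = ","),
              if (x$developer_mode) " [developer mode]" else ""))
  if (length(x$options)) cat("  options:", paste(x$options, collapse = ","), "\n")
  invisible(x)
}
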