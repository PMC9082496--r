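# Linter for the generated pulse-program dialect.  The generator's output is
# predictable, so conformance is defined by these checks: section order,
# symbol resolution, duplicate definitions, balanced and known #ifdef
# guards, and a well-formed reproducibility footer.  The linter reports and
# never throws.

.lint_local_rx <- "^[A-Z]{1,2}_[A-Z0-9_]*[0-9]$"

#' Lint a pulse program
#'
#' Errors: `SECTION_ORDER` (marker missing or out of order),
#' `UNDEFINED_SYMBOL` (a p#/d#/cnst#/gpz#/ph#/named-delay token used in the
#' instruction sections without a definition), `DUPLICATE_DEF` (a token
#' defined twice within one definition section), `GUARD_UNBALANCED` /
#' `UNKNOWN_FLAG_SYMBOL` (conditional-compilation guards), and
#' `MALFORMED_FOOTER`.  Warnings: `UNUSED_DEFINITION` for `define delay`
#' names never referenced.
#'
#' @param text A `noah_program`, character vector of lines, or single string.
#' @return Object of class `noah_lint_report`: list with `errors` and
#'   `warnings` data frames (`line`, `code`, `message`) and `passed`
#'   (`TRUE` iff no errors).
#' @export
#' @examples
#' lint_pulse_program(assemble(resolve_sequence(c("S", "C"))))$passed
lint_pulse_program <- function(text) {
  lines <- program_lines(text)
  errors <- list()
  warnings <- list()
  err <- function(line, code, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      line = line %||% NA_integer_, code = code, message = message,
      stringsAsFactors = FALSE)
  }
  warn <- function(line, code, message) {
    warnings[[length(warnings) + 1L]] <<- data.frame(
      line = line %||% NA_integer_, code = code, message = message,
      stringsAsFactors = FALSE)
  }

  # --- section structure ---
  marker_pos <- vapply(.section_markers, function(m) {
    i <- which(lines == m)
    if (length(i) == 1) i else if (length(i) == 0) NA_integer_ else -1L
  }, 0L)
  for (nm in names(marker_pos)) {
    if (is.na(marker_pos[[nm]])) {
      err(NULL, "SECTION_ORDER", sprintf("section marker '%s' missing", nm))
    } else if (marker_pos[[nm]] < 0) {
      err(NULL, "SECTION_ORDER", sprintf("section marker '%s' duplicated", nm))
    }
  }
  present <- marker_pos[!is.na(marker_pos) & marker_pos > 0]
  if (length(present) > 1 && any(diff(present[order(match(names(present),
                                                          names(.section_markers)))]) < 0)) {
    err(NULL, "SECTION_ORDER", "sections out of canonical order")
  }
  section <- function(nm) {
    i <- marker_pos[[nm]]
    if (is.na(i) || i < 0) return(character(0))
    later <- present[present > i]
    end <- if (length(later)) min(later) - 1L else length(lines)
    if (end <= i) character(0) else lines[(i + 1L):end]
  }

  # --- definitions ---
  defs <- list()
  collect <- function(section_lines, rx, group, what) {
    m <- regmatches(section_lines, regexec(rx, section_lines))
    toks <- vapply(Filter(function(x) length(x) >= group, m), `[[`, "", group)
    dup <- unique(toks[duplicated(toks)])
    for (d in dup) {
      err(NULL, "DUPLICATE_DEF", sprintf("%s '%s' defined more than once", what, d))
    }
    unique(toks)
  }
  define_names <- collect(section("local_delays"),
                          "^define delay ([A-Za-z0-9_]+)", 2, "local delay")
  relation_lhs <- collect(c(section("local_delays"), section("relations")),
                          "^\"([A-Za-z0-9_]+)=", 2, "relation")
  phase_defs <- collect(section("phases"), "^(ph[0-9]+)=", 2, "phase cycle")
  grad_defs <- collect(section("gradients"), "^;(gpz[0-9]+):", 2, "gradient")
  ased_defs <- collect(section("ased"), "^;([A-Za-z0-9_]+):", 2, "ased comment")

  # --- references ---
  body_lines <- c(section("main"), section("increments"))
  refs <- extract_tokens(body_lines)
  for (tok in refs) {
    defined <-
      if (grepl("^ph[0-9]+$", tok)) tok %in% phase_defs
      else if (grepl("^gpz[0-9]+$", tok)) tok %in% grad_defs
      else if (grepl(.lint_local_rx, tok)) tok %in% define_names
      else tok %in% c(relation_lhs, ased_defs)
    if (!defined) {
      err(NULL, "UNDEFINED_SYMBOL",
          sprintf("'%s' is referenced but never defined", tok))
    }
  }

  # --- guards ---
  known <- acquisition_flags()$symbol
  depth <- 0L
  for (i in seq_along(body_lines)) {
    ln <- body_lines[i]
    if (grepl("^\\s*#ifdef\\b", ln)) {
      depth <- depth + 1L
      sym <- sub("^\\s*#ifdef\\s+([A-Za-z0-9_]+).*$", "\\1", ln)
      if (!sym %in% known) {
        err(i, "UNKNOWN_FLAG_SYMBOL",
            sprintf("guard symbol '%s' is not a known acquisition flag", sym))
      }
    } else if (grepl("^\\s*#else\\b", ln)) {
      if (depth < 1) err(i, "GUARD_UNBALANCED", "#else outside #ifdef")
    } else if (grepl("^\\s*#endif\\b", ln)) {
      depth <- depth - 1L
      if (depth < 0) {
        err(i, "GUARD_UNBALANCED", "#endif without #ifdef")
        depth <- 0L
      }
    }
  }
  if (depth != 0) err(NULL, "GUARD_UNBALANCED", "unclosed #ifdef block")

  # --- footer ---
  tryCatch(parse_footer(lines), noah_error = function(e) {
    err(NULL, "MALFORMED_FOOTER", conditionMessage(e))
  })

  # --- unused local delays ---
  unused <- setdiff(define_names, refs)
  for (u in unused) {
    warn(NULL, "UNUSED_DEFINITION", sprintf("local delay '%s' defined but unused", u))
  }

  empty <- data.frame(line = integer(0), code = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  errors <- if (length(errors)) do.call(rbind, errors) else empty
  warnings <- if (length(warnings)) do.call(rbind, warnings) else empty
  structure(list(errors = errors, warnings = warnings,
                 passed = nrow(errors) == 0),
            class = "noah_lint_report")
}

#' @export
print.noah_lint_report <- function(x, ...) {
  cat(sprintf("lint: %s (%d error(s), %d warning(s))\n",
              if (x$passed) "passed" else "FAILED",
              nrow(x$errors), nrow(x$warnings)))
  for (i in seq_len(nrow(x$errors))) {
    cat(sprintf("  error %s: %s\n", x$errors$code[i], x$errors$message[i]))
  }
  for (i in seq_len(nrow(x$warnings))) {
    cat(sprintf("  warning %s: %s\n", x$warnings$code[i], x$warnings$message[i]))
  }
  invisible(x)
}
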