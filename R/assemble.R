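# Rendering a resolved sequence into the nine-section pulse program text:
# (1) header comments, (2) local-delay definitions, (3) standardized
# parameter relations, (4) main instruction block, (5) incrementation and
# echo-antiecho commands, (6) phase cycles, (7) gradient comments (gppp),
# (8) WaveMaker directives (wvm), (9) ased parameter comments, and the
# reproducibility footer.  Serialization is byte-deterministic given fixed
# metadata.

.section_markers <- c(
  header       = "; === pulse program header ===",
  local_delays = "; === local delay definitions ===",
  relations    = "; === parameter relations ===",
  main         = "; === main pulse sequence ===",
  increments   = "; === incrementation and echo-antiecho ===",
  phases       = "; === phase cycles ===",
  gradients    = "; === gradient table (gppp) ===",
  wavemaker    = "; === wavemaker directives (wvm) ===",
  ased         = "; === parameter descriptions (ased) ===",
  footer       = "; === reproducibility footer ==="
)

.kind_order <- c("PULSE", "DELAY", "CONSTANT", "GRAD_AMP", "GRAD_NAME",
                 "PHASE", "LOCAL_DELAY")

#' Generator metadata recorded in the reproducibility footer
#'
#' @param version Generator version string (semver).
#' @param timestamp UTC timestamp in ISO-8601 (`%Y-%m-%dT%H:%M:%SZ`);
#'   defaults to the current time.  Injectable so that output is
#'   byte-reproducible.
#' @return Object of class `noah_metadata`.
#' @export
generator_metadata <- function(version = "2.1.0", timestamp = NULL) {
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  structure(list(version = version, timestamp = timestamp),
            class = "noah_metadata")
}

# pseudo-module definition tables for assembler-owned blocks ---------------

glue_definition <- function(kind) {
  cached <- the$glue_defs[[kind]]
  if (!is.null(cached)) return(cached)
  def <- glue_definition_impl(kind)
  if (is.null(the$glue_defs)) the$glue_defs <- list()
  the$glue_defs[[kind]] <- def
  def
}

glue_definition_impl <- function(kind) {
  common <- noah_registry()$common
  if (kind == "PURGE_PULSE_PFG") {
    list(name = "purge",
         parameters = expand_param_list(list("p1", "p16", "d16"), common, "glue"),
         phase_cycles = expand_phases(list("ph6"), common, "glue"),
         gradients = expand_gradients(list("gpz14"), common, "glue"),
         wavemaker = character(0),
         body = c("; inter-module purge pulse + PFG",
                  "(p1 ph6):f1", "p16:gp14", "d16"))
  } else if (kind == "ASAP_MIXING") {
    list(name = "ASAP",
         parameters = expand_param_list(list("p16", "p41", "d16"), common, "glue"),
         phase_cycles = expand_phases(list("ph5"), common, "glue"),
         gradients = expand_gradients(list("gpz26"), common, "glue"),
         wavemaker = ";sp41:wvm:asap_mix: dipsi-2(40 ms; L2H)",
         body = c("; ASAP mixing (redistributes bulk 1H between modules)",
                  "p16:gp26", "d16", "(p41:sp41 ph5):f1", "4u"))
  } else {
    noah_abort(sprintf("unknown glue kind '%s'", kind), "noah_precondition")
  }
}

core_definition <- function() {
  if (!is.null(the$core_def)) return(the$core_def)
  common <- noah_registry()$common
  the$core_def <- list(name = "core",
       parameters = expand_param_list(list("d1"), common, "core"),
       phase_cycles = list(), gradients = NULL, wavemaker = character(0))
  the$core_def
}

# all contributing definition tables of a resolved sequence, named by source
contributions <- function(resolved) {
  out <- list(core = core_definition())
  for (i in seq_along(resolved$modules)) {
    def <- resolved$modules[[i]]
    out[[def$abbreviation]] <- def
  }
  glue <- resolved$glue
  if (!is.null(glue) && nrow(glue)) {
    for (kind in unique(glue$kind)) out[[kind]] <- glue_definition(kind)
  }
  out
}

# -- collation -------------------------------------------------------------

#' Collate the parameter tables of a resolved sequence
#'
#' Each `(kind, name)` slot appears once in the collated table; identical
#' duplicate definitions from different modules are merged, and differing
#' definitions for the same slot are an error naming both sources
#' (standardization conflicts are a registry bug, never silently
#' renumbered).
#'
#' @param resolved A [resolve_sequence()] result.
#' @return Data frame with columns `kind`, `name`, `definition`, `comment`,
#'   `source`, in canonical order (pulses, delays, constants, then local
#'   delays; numeric index within kind).
#' @export
collate_parameters <- function(resolved) {
  tabs <- contributions(resolved)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (src in names(tabs)) {
    params <- tabs[[src]]$parameters
    if (is.null(params)) next
    for (i in seq_len(nrow(params))) {
      key <- paste0(params$kind[i], ":", params$name[i])
      sig <- paste(params$definition[i], params$comment[i], sep = "\r")
      prev <- seen[[key]]
      if (is.null(prev)) {
        seen[[key]] <- list(sig = sig, src = src)
        rows[[key]] <- cbind(params[i, , drop = FALSE],
                             data.frame(source = src, stringsAsFactors = FALSE))
      } else if (!identical(prev$sig, sig)) {
        noah_abort(sprintf(
          "parameter %s defined differently by %s and %s",
          params$name[i], prev$src, src), "noah_parameter_conflict")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  idx <- suppressWarnings(as.numeric(sub("^[a-z]+", "", out$name)))
  ord <- order(match(out$kind, .kind_order), idx, out$name)
  out[ord, , drop = FALSE]
}

#' Merge the phase cycles of a resolved sequence
#'
#' ph indices are unique program-wide: modules may share an index only for
#' byte-identical cycles; the same index with different steps (or a
#' receiver/non-receiver mismatch) raises a conflict naming both modules.
#' Receiver cycles are collected into the program's receiver phase list
#' (one per acquired FID).
#'
#' @param resolved A [resolve_sequence()] result.
#' @return List of phase cycles (index, steps, receiver, source), sorted by
#'   index.
#' @export
merge_phase_cycles <- function(resolved) {
  tabs <- contributions(resolved)
  merged <- list()
  for (src in names(tabs)) {
    for (pc in tabs[[src]]$phase_cycles %||% list()) {
      key <- as.character(pc$index)
      prev <- merged[[key]]
      if (is.null(prev)) {
        pc$source <- src
        merged[[key]] <- pc
      } else if (!identical(prev$steps, pc$steps) ||
                 !identical(prev$receiver, pc$receiver)) {
        noah_abort(sprintf("phase cycle ph%d defined differently by %s and %s",
                           pc$index, prev$source, src), "noah_phase_conflict")
      }
    }
  }
  merged[order(as.integer(names(merged)))]
}

# merged gradient table (same sharing rule as parameters)
merge_gradients <- function(resolved) {
  tabs <- contributions(resolved)
  rows <- list()
  srcs <- list()
  for (src in names(tabs)) {
    g <- tabs[[src]]$gradients
    if (is.null(g) || !nrow(g)) next
    for (i in seq_len(nrow(g))) {
      key <- as.character(g$index[i])
      if (is.null(rows[[key]])) {
        rows[[key]] <- g[i, , drop = FALSE]
        srcs[[key]] <- src
      } else if (!isTRUE(all.equal(rows[[key]][, 1:5], g[i, 1:5],
                                   check.attributes = FALSE))) {
        noah_abort(sprintf("gradient gpz%s defined differently by %s and %s",
                           key, srcs[[key]], src), "noah_parameter_conflict")
      }
    }
  }
  out <- do.call(rbind, rows[order(as.integer(names(rows)))])
  rownames(out) <- NULL
  out
}

# -- annotation sections ---------------------------------------------------

format_amplitude <- function(amplitude, echo_antiecho) {
  a <- sub("\\.?0+$", "", sprintf("%.1f", abs(amplitude)))
  sign <- if (echo_antiecho) "+/-" else if (amplitude < 0) "-" else ""
  paste0(sign, a)
}

#' Render the annotation sections of a pulse program
#'
#' Produces the gradient comments (readable by TopSpin's gppp facility), the
#' WaveMaker shaped-pulse directives, and the ased parameter-description
#' comments for a resolved sequence.
#'
#' @param resolved A [resolve_sequence()] result.
#' @param strict Error (`MissingAnnotation`) if a parameter has no
#'   description comment; otherwise such parameters are skipped silently.
#' @return List with character-vector elements `gradients`, `wavemaker`,
#'   `ased`.
#' @export
render_annotations <- function(resolved, strict = TRUE, .params = NULL) {
  grads <- merge_gradients(resolved)
  glines <- character(0)
  if (!is.null(grads) && nrow(grads)) {
    glines <- vapply(seq_len(nrow(grads)), function(i) {
      extra <- if (grads$echo_antiecho[i]) ", echo-antiecho" else ""
      sprintf(";gpz%d: %s%% (%s ms, %s%s)", grads$index[i],
              format_amplitude(grads$amplitude[i], grads$echo_antiecho[i]),
              format(grads$duration_ms[i]), grads$shape[i], extra)
    }, "")
  }
  wvm <- unique(unlist(lapply(contributions(resolved),
                              function(t) t$wavemaker %||% character(0))))
  params <- .params %||% collate_parameters(resolved)
  missing <- !nzchar(params$comment)
  if (any(missing) && strict) {
    noah_abort(sprintf("parameter %s has no description comment",
                       params$name[which(missing)[1]]), "noah_missing_annotation")
  }
  params <- params[!missing, , drop = FALSE]
  ased <- sprintf(";%s: %s", params$name, params$comment)
  list(gradients = glines, wavemaker = wvm, ased = ased)
}

# -- assembly --------------------------------------------------------------

indent_body <- function(lines) {
  ifelse(grepl("^#", lines), lines, paste0("  ", lines))
}

preamble_lines <- function() {
  c("1 ze",
    "2 30m",
    "  4u",
    "#ifdef PRESAT",
    "  ; presaturation during the recovery delay",
    "  4u pl9:f1",
    "  d1 cw:f1",
    "  4u do:f1",
    "  4u pl1:f1",
    "#else",
    "  d1",
    "#endif",
    "  50u UNBLKGRAD")
}

#' Assemble a pulse program from a resolved sequence
#'
#' Concatenates the resolved module bodies with their glue blocks between
#' the collated parameter definitions, incrementation commands, merged phase
#' cycles, annotation sections and the reproducibility footer.  Output is
#' deterministic: the same resolved sequence and metadata give byte-identical
#' text.
#'
#' @param resolved A [resolve_sequence()] result (or anything coercible to a
#'   supersequence, which is resolved first).
#' @param metadata A [generator_metadata()] object.
#' @param couplings A [coupling_constants()] object; used for the informative
#'   transfer-delay header comment.
#' @return Object of class `noah_program`.
#' @export
#' @examples
#' prog <- assemble(resolve_sequence(c("Sp", "Cc")),
#'                  generator_metadata(timestamp = "2022-01-20T00:00:00Z"))
#' parse_footer(prog)$metadata$version
assemble <- function(resolved, metadata = generator_metadata(),
                     couplings = coupling_constants()) {
  if (!inherits(resolved, "noah_resolved")) {
    resolved <- resolve_sequence(resolved)
  }
  mods <- resolved$modules
  abbrs <- vapply(mods, `[[`, "", "abbreviation")
  n <- length(mods)

  params <- collate_parameters(resolved)
  cycles <- merge_phase_cycles(resolved)
  ann <- render_annotations(resolved, .params = params)
  delays <- compute_delays(couplings)

  flags_avail <- sort(unique(c("PRESAT", "NUS",
                               unlist(lapply(mods, `[[`, "supports_flags")))))
  header <- c(
    sprintf("; ngn_noah%d-%s", n, paste(abbrs, collapse = "")),
    sprintf("; NOAH-%d supersequence: %s", n,
            paste(vapply(mods, `[[`, "", "display_name"), collapse = " + ")),
    sprintf("; modules: %s", paste(abbrs, collapse = ",")),
    sprintf("; delta = %.4f ms (1J(CH) = %g Hz); delta_LR = %.4f ms (nJ(CH) = %g Hz); delta_N = %.4f ms (1J(NH) = %g Hz)",
            delays$delta * 1e3, couplings$one_bond_JCH,
            delays$delta_lr * 1e3, couplings$long_range_JCH,
            delays$delta_n * 1e3, couplings$one_bond_JNH),
    ";zgoptns: (none)",
    sprintf(";flags-available: %s", paste(flags_avail, collapse = ",")))

  locals <- params[params$kind == "LOCAL_DELAY", , drop = FALSE]
  local_lines <- unlist(lapply(seq_len(nrow(locals)), function(i) {
    c(sprintf("define delay %s", locals$name[i]),
      sprintf("\"%s\"", locals$definition[i]))
  }))
  relations <- params[params$kind != "LOCAL_DELAY" & nzchar(params$definition), ,
                      drop = FALSE]
  relation_lines <- sprintf("\"%s\"", relations$definition)

  main <- preamble_lines()
  glue <- resolved$glue
  for (i in seq_len(n)) {
    main <- c(main,
              sprintf("  ; --- module %d of %d: %s (%s) ---", i, n,
                      mods[[i]]$display_name, abbrs[i]),
              indent_body(mods[[i]]$body))
    if (!is.null(glue) && nrow(glue)) {
      k <- glue$kind[glue$position == i]
      if (length(k) == 1) main <- c(main, indent_body(glue_definition(k)$body))
    }
  }
  main <- c(main, "  100u BLKGRAD")

  incr <- character(0)
  for (m in mods) {
    if (!is.null(m$t1_delay)) {
      incr <- c(incr, sprintf("  1m i%s ; increment t1 of %s", m$t1_delay,
                              m$abbreviation))
    }
  }
  incr <- c(incr,
            "#ifdef NUS",
            "  ; nonuniform sampling: t1 increments are taken from the",
            "  ; sidecar schedule file (one increment index per line)",
            "#endif")
  for (m in mods) {
    for (g in m$ea_gradients) {
      incr <- c(incr, sprintf("  1m igrad gp%d ; echo-antiecho sign inversion (%s)",
                              g, m$abbreviation))
    }
  }
  incr <- c(incr, "  lo to 2 times td1", "exit")

  phase_lines <- vapply(cycles, function(pc) {
    sprintf("ph%d=%s%s", pc$index, paste(pc$steps, collapse = " "),
            if (pc$receiver) " ; receiver" else "")
  }, "")

  footer <- c(
    sprintf(";MODULES: %s", paste(abbrs, collapse = ",")),
    sprintf(";AUPROG: %s", paste(vapply(mods, `[[`, "", "au_program"),
                                 collapse = ",")),
    sprintf(";VERSION: %s", metadata$version),
    sprintf(";TIMESTAMP: %s", metadata$timestamp))

  structure(list(
    sections = list(header = header, local_delays = local_lines %||% character(0),
                    relations = relation_lines, main = main, increments = incr,
                    phases = phase_lines, gradients = ann$gradients,
                    wavemaker = ann$wavemaker, ased = ann$ased, footer = footer),
    metadata = metadata, modules = abbrs),
    class = "noah_program")
}

#' @export
as.character.noah_program <- function(x, ...) {
  out <- character(0)
  for (nm in names(.section_markers)) {
    out <- c(out, .section_markers[[nm]], x$sections[[nm]])
  }
  unname(out)
}

#' @export
print.noah_program <- function(x, ...) {
  cat(as.character(x), sep = "\n")
  invisible(x)
}

#' Write a pulse program to disk (UTF-8, LF line endings)
#'
#' @param program A `noah_program` (or character vector of lines).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pulse_program <- function(program, path) {
  lines <- if (inherits(program, "noah_program")) as.character(program) else program
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# normalise any program representation to lines
program_lines <- function(text) {
  if (inherits(text, "noah_program")) return(as.character(text))
  if (length(text) == 1 && grepl("\n", text)) {
    return(strsplit(text, "\n", fixed = TRUE)[[1]])
  }
  as.character(text)
}

#' Parse the reproducibility footer of a pulse program
#'
#' Recovers the module list, the per-module processing AU programs, the
#' generator version and the timestamp, exactly as written by [assemble()].
#' This is the contract used by the splitx-style processing script, which
#' reads the AU program list from the pulse program text rather than from
#' user-set processing parameters.
#'
#' @param text A `noah_program`, a character vector of lines, or a single
#'   string.
#' @return List with elements `metadata` (a [generator_metadata()] object),
#'   `modules` (character vector) and `au_programs` (character vector).
#' @export
parse_footer <- function(text) {
  lines <- program_lines(text)
  grab <- function(key) {
    hits <- grep(sprintf("^;%s: ", key), lines, value = TRUE)
    if (length(hits) != 1) {
      noah_abort(sprintf("footer line ;%s: missing or duplicated", key),
                 "noah_malformed_footer")
    }
    sub(sprintf("^;%s: ", key), "", hits)
  }
  modules <- strsplit(grab("MODULES"), ",", fixed = TRUE)[[1]]
  au <- strsplit(grab("AUPROG"), ",", fixed = TRUE)[[1]]
  if (length(au) != length(modules)) {
    noah_abort("footer AU program list does not match the module list",
               "noah_malformed_footer")
  }
  list(metadata = generator_metadata(version = grab("VERSION"),
                                     timestamp = grab("TIMESTAMP")),
       modules = modules, au_programs = au)
}
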