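# The module registry: one YAML document per NOAH module under
# inst/registry/, plus a shared dictionary (_common.yaml) holding the
# standardized parameter, phase-cycle and gradient tables.  Standardization
# is what makes direct concatenation of module bodies safe: a given p#/d#/
# cnst#/gpz#/ph# token means the same thing in every module, so module files
# reference shared entries by token and only carry module-specific entries
# (chiefly the named local delays) in full.

noah_pools <- c("BULK_1H", "C13_BOUND_1H", "N15_BOUND_1H")
noah_categories <- c("HET_13C", "HET_15N", "HOMONUCLEAR", "PURESHIFT_2DJ")
noah_slots <- c(HMBC = 1L, N15 = 2L, C13 = 3L, HOMO = 4L)

registry_path <- function() {
  p <- system.file("registry", package = "noahgen")
  if (!nzchar(p)) noah_abort("registry directory not found", "noah_registry_error")
  p
}

#' Load the NOAH module registry
#'
#' Reads (once per session; cached) the module definition files shipped with
#' the package, expands shared parameter/phase/gradient references against
#' the common dictionary, and validates the registry invariants.
#'
#' @param refresh Reload from disk even if a cached registry exists.
#' @param path Directory of registry files (defaults to the installed
#'   registry; exposed for testing with reduced or broken fixtures).
#' @return A list with elements `modules` (named list of module definitions)
#'   and `common` (the shared dictionary).
#' @export
noah_registry <- function(refresh = FALSE, path = NULL) {
  if (is.null(path)) {
    if (!refresh && !is.null(the$registry)) return(the$registry)
    reg <- load_registry(registry_path())
    the$registry <- reg
    return(reg)
  }
  load_registry(path)
}

load_registry <- function(dir) {
  common <- yaml::read_yaml(file.path(dir, "_common.yaml"))
  files <- sort(list.files(dir, pattern = "^[A-Za-z]+\\.yaml$", full.names = TRUE))
  mods <- lapply(files, function(f) expand_module(yaml::read_yaml(f), common, basename(f)))
  names(mods) <- vapply(mods, `[[`, "", "abbreviation")
  reg <- list(modules = mods, common = common)
  validate_registry(reg)
  reg
}

# -- expansion -------------------------------------------------------------

lookup_common_param <- function(token, common, where) {
  entry <- common$parameters[[token]]
  if (is.null(entry)) {
    noah_abort(sprintf("%s references unknown shared parameter '%s'", where, token),
               "noah_registry_error")
  }
  list(kind = entry$kind, name = token,
       definition = entry$definition %||% "",
       comment = entry$comment %||% "")
}

expand_param_list <- function(tokens, common, where) {
  rows <- lapply(tokens, function(p) {
    if (is.character(p) && length(p) == 1) {
      lookup_common_param(p, common, where)
    } else {
      list(kind = p$kind %||% "LOCAL_DELAY", name = p$name,
           definition = p$definition %||% "", comment = p$comment %||% "")
    }
  })
  do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r$kind, name = r$name, definition = r$definition,
               comment = r$comment, stringsAsFactors = FALSE)
  }))
}

expand_phases <- function(tokens, common, where) {
  lapply(tokens, function(tok) {
    entry <- common$phases[[tok]]
    if (is.null(entry)) {
      noah_abort(sprintf("%s references unknown shared phase '%s'", where, tok),
                 "noah_registry_error")
    }
    list(index = as.integer(sub("^ph", "", tok)),
         steps = as.character(unlist(entry$steps)),
         receiver = isTRUE(entry$receiver))
  })
}

expand_gradients <- function(tokens, common, where) {
  rows <- lapply(tokens, function(tok) {
    entry <- common$gradients[[tok]]
    if (is.null(entry)) {
      noah_abort(sprintf("%s references unknown shared gradient '%s'", where, tok),
                 "noah_registry_error")
    }
    data.frame(index = as.integer(sub("^gpz", "", tok)),
               amplitude = as.numeric(entry$amplitude),
               duration_ms = as.numeric(entry$duration_ms),
               shape = entry$shape %||% "SMSQ10.100",
               echo_antiecho = isTRUE(entry$echo_antiecho),
               comment = entry$comment %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

split_body <- function(text) {
  if (is.null(text)) return(character(0))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # drop a single trailing empty line from the YAML block scalar
  if (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  lines
}

expand_module <- function(raw, common, file) {
  where <- sprintf("module file '%s'", file)
  def <- list(
    abbreviation = raw$abbreviation,
    display_name = raw$display_name,
    category = raw$category,
    slot = raw$slot,
    au_program = raw$au_program,
    pools_required = as.character(unlist(raw$pools_required)),
    pools_consumed = as.character(unlist(raw$pools_consumed)),
    pools_preserved = as.character(unlist(raw$pools_preserved)),
    t1_delay = raw$t1_delay,
    ea_gradients = as.integer(unlist(raw$ea_gradients %||% list())),
    supports_flags = as.character(unlist(raw$supports_flags %||% list())),
    parameters = expand_param_list(raw$parameters, common, where),
    phase_cycles = expand_phases(raw$phase_cycles, common, where),
    gradients = expand_gradients(raw$gradients, common, where),
    wavemaker = as.character(unlist(raw$wavemaker %||% list())),
    body = split_body(raw$body),
    zip_block = if (!is.null(raw$zip_block)) split_body(raw$zip_block),
    variants = lapply(raw$variants %||% list(), function(v) {
      list(label = v$label, description = v$description %||% "",
           retains = as.character(unlist(v$retains %||% list())),
           block = split_body(v$block),
           extra_parameters = as.character(unlist(v$extra_parameters %||% list())))
    })
  )
  class(def) <- "noah_module"
  def
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# -- validation ------------------------------------------------------------

# tokens a module can legitimately reference in its body
module_defined_tokens <- function(def, extra_param_tokens = character(0), common = NULL) {
  params <- def$parameters$name
  if (length(extra_param_tokens) && !is.null(common)) {
    params <- c(params, extra_param_tokens)
  }
  phases <- paste0("ph", vapply(def$phase_cycles, `[[`, 0L, "index"))
  grads <- paste0("gpz", def$gradients$index)
  unique(c(params, phases, grads))
}

validate_registry <- function(reg) {
  mods <- reg$modules
  abbrs <- vapply(mods, `[[`, "", "abbreviation")
  if (anyDuplicated(abbrs)) {
    noah_abort("duplicate module abbreviations in registry", "noah_registry_error")
  }
  seen <- list()  # cross-module consistency of shared tokens
  for (def in mods) {
    who <- def$abbreviation
    if (!def$category %in% noah_categories) {
      noah_abort(sprintf("module %s: unknown category '%s'", who, def$category),
                 "noah_registry_error")
    }
    pools <- c(def$pools_required, def$pools_consumed, def$pools_preserved)
    if (!all(pools %in% noah_pools)) {
      noah_abort(sprintf("module %s: unknown magnetization pool", who),
                 "noah_registry_error")
    }
    # phase cycles: step count and alphabet; exactly one receiver
    n_rec <- 0L
    for (pc in def$phase_cycles) {
      if (!length(pc$steps) %in% c(1L, 2L, 4L, 8L, 16L)) {
        noah_abort(sprintf("module %s: ph%d has %d steps", who, pc$index,
                           length(pc$steps)), "noah_registry_error")
      }
      if (!all(pc$steps %in% c("x", "-x", "y", "-y"))) {
        noah_abort(sprintf("module %s: ph%d has invalid steps", who, pc$index),
                   "noah_registry_error")
      }
      n_rec <- n_rec + as.integer(pc$receiver)
    }
    if (n_rec != 1L) {
      noah_abort(sprintf("module %s: needs exactly one receiver cycle", who),
                 "noah_registry_error")
    }
    if (nrow(def$gradients)) {
      if (any(abs(def$gradients$amplitude) > 100) || any(def$gradients$duration_ms <= 0)) {
        noah_abort(sprintf("module %s: gradient amplitude/duration out of range", who),
                   "noah_registry_error")
      }
    }
    # local delay naming convention
    locals <- def$parameters$name[def$parameters$kind == "LOCAL_DELAY"]
    bad <- locals[!grepl("^D[A-Z]_[A-Z0-9]+[0-9]$", locals)]
    if (length(bad)) {
      noah_abort(sprintf("module %s: local delay name(s) %s violate D<X>_<NAME><n>",
                         who, paste(bad, collapse = ", ")), "noah_registry_error")
    }
    # registry completeness: every token in the body (incl. variant and ZIP
    # blocks) resolves in the module's own tables
    check_block <- function(lines, extra, label) {
      toks <- extract_tokens(lines)
      defined <- module_defined_tokens(def)
      if (length(extra)) {
        defined <- c(defined, vapply(extra, function(t) t, ""))
      }
      missing <- setdiff(toks, defined)
      if (length(missing)) {
        noah_abort(sprintf("module %s (%s): undefined token(s) %s", who, label,
                           paste(missing, collapse = ", ")), "noah_registry_error")
      }
    }
    base_body <- def$body[!grepl("^<<", def$body)]
    check_block(base_body, character(0), "body")
    if (!is.null(def$zip_block)) check_block(def$zip_block, character(0), "zip")
    for (v in def$variants) {
      check_block(v$block, v$extra_parameters, paste0("variant ", v$label))
      if (!all(v$retains %in% noah_pools)) {
        noah_abort(sprintf("module %s: variant %s retains unknown pool", who, v$label),
                   "noah_registry_error")
      }
    }
    # cross-module consistency of identically named entries
    for (i in seq_len(nrow(def$parameters))) {
      key <- paste0("param:", def$parameters$name[i])
      sig <- paste(def$parameters$kind[i], def$parameters$definition[i],
                   def$parameters$comment[i], sep = "\r")
      if (!is.null(seen[[key]]) && !identical(seen[[key]], sig)) {
        noah_abort(sprintf("registry: conflicting definitions for %s", key),
                   "noah_registry_error")
      }
      seen[[key]] <- sig
    }
  }
  invisible(TRUE)
}

# -- access ----------------------------------------------------------------

#' List the modules available in the registry
#'
#' @return A data frame with one row per module: abbreviation, display name,
#'   category and processing AU program.
#' @export
#' @examples
#' list_modules()
list_modules <- function() {
  mods <- noah_registry()$modules
  df <- do.call(rbind, lapply(mods, function(m) {
    data.frame(abbreviation = m$abbreviation, display_name = m$display_name,
               category = m$category, au_program = m$au_program,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[order(match(df$category, noah_categories), df$abbreviation), , drop = FALSE]
}

#' Retrieve a module definition from the registry
#'
#' @param abbreviation Module abbreviation (e.g. `"S"` for the 13C HSQC,
#'   `"B"` for the zz-HMBC).  Sub/superscripted names are flattened to ASCII
#'   (`"Sp"`, `"St"`, `"Pt"`, `"Jqf"`, ...).
#' @param variant Optional variant label.  For the HMBC module the labels
#'   name the form of the zz-filter (`"NONE"`, `"C"`, `"N"`, `"CN"`,
#'   according to which heteronucleus-bound 1H pools it retains).  An unknown
#'   variant is an error, never a fallback.
#' @return A module definition (class `noah_module`).  When `variant` is
#'   given, the variant block is substituted into the body and the variant's
#'   extra parameters and pool semantics are applied.
#' @export
#' @examples
#' get_module("S")$au_program          # "noah_hsqc"
#' get_module("B", "C")$pools_preserved
get_module <- function(abbreviation, variant = NULL) {
  mods <- noah_registry()$modules
  def <- mods[[abbreviation]]
  if (is.null(def)) {
    noah_abort(sprintf("unknown module '%s'", abbreviation), "noah_unknown_module")
  }
  if (!is.null(variant)) def <- apply_variant(def, variant)
  def
}

# substitute a variant's block into the module body and merge its tables
apply_variant <- function(def, label) {
  labels <- vapply(def$variants, `[[`, "", "label")
  i <- match(label, labels)
  if (is.na(i)) {
    noah_abort(sprintf("module %s: unknown variant '%s'", def$abbreviation, label),
               "noah_unknown_variant")
  }
  v <- def$variants[[i]]
  ph <- grep("^<<ZZFILTER>>$", def$body)
  if (length(ph) == 1) {
    def$body <- append(def$body[-ph], v$block, after = ph - 1L)
  }
  if (length(v$extra_parameters)) {
    common <- noah_registry()$common
    extra <- expand_param_list(as.list(v$extra_parameters), common,
                               sprintf("module %s variant %s", def$abbreviation, label))
    extra <- extra[!extra$name %in% def$parameters$name, , drop = FALSE]
    def$parameters <- rbind(def$parameters, extra)
  }
  het <- c("C13_BOUND_1H", "N15_BOUND_1H")
  def$pools_preserved <- union(setdiff(def$pools_preserved, het), v$retains)
  def$chosen_variant <- label
  def
}

#' @export
print.noah_module <- function(x, ...) {
  cat(sprintf("<noah module> %s: %s [%s]\n", x$abbreviation, x$display_name,
              x$category))
  cat(sprintf("  AU program: %s; flags: %s\n", x$au_program,
              if (length(x$supports_flags)) paste(x$supports_flags, collapse = ",") else "(none)"))
  cat(sprintf("  draws on: %s\n", paste(x$pools_required, collapse = ", ")))
  if (length(x$variants)) {
    cat(sprintf("  variants: %s\n",
                paste(vapply(x$variants, `[[`, "", "label"), collapse = ", ")))
  }
  invisible(x)
}

# fast attribute table used by the viability engine
module_attrs <- function(modules = NULL) {
  mods <- noah_registry()$modules
  if (!is.null(modules)) {
    unknown <- setdiff(modules, names(mods))
    if (length(unknown)) {
      noah_abort(sprintf("unknown module '%s'", unknown[[1]]), "noah_unknown_module")
    }
    mods <- mods[modules]
  }
  list(
    abbr = vapply(mods, `[[`, "", "abbreviation"),
    category = vapply(mods, `[[`, "", "category"),
    slot = vapply(mods, `[[`, "", "slot"),
    rank = noah_slots[vapply(mods, `[[`, "", "slot")],
    required = lapply(mods, `[[`, "pools_required"),
    consumed = lapply(mods, `[[`, "pools_consumed"),
    preserved = lapply(mods, `[[`, "pools_preserved")
  )
}
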