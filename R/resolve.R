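# Context-sensitive resolution: the adaptive HMBC zz-filter, ZIP insertion
# in sensitivity-enhanced HSQC modules, and the glue blocks placed between
# modules.  The output (a resolved sequence) is what the assembler renders.

#' Choose the zz-filter form for the HMBC module in a supersequence
#'
#' The form of the zz-filter depends on whether 13C-bound and/or 15N-bound
#' 1H magnetization must be retained for modules placed after the HMBC.
#' Needs are derived from the later modules' pool declarations, not from a
#' hand-list of modules.  In developer mode an explicit override
#' (`variant_overrides = c(B = label)`) wins verbatim, provided the label
#' exists.
#'
#' @param seq A [supersequence()] containing the HMBC module (`"B"`).
#' @return A variant label: `"NONE"`, `"C"`, `"N"` or `"CN"`.
#' @export
#' @examples
#' resolve_hmbc_filter(supersequence(c("B", "S", "C")))   # "C"
resolve_hmbc_filter <- function(seq) {
  seq <- as_supersequence(seq, developer_mode = TRUE)
  pos <- match("B", seq$modules)
  if (is.na(pos)) {
    noah_abort("supersequence contains no HMBC module", "noah_hmbc_not_present")
  }
  if (seq$developer_mode && !is.null(seq$variant_overrides) &&
      "B" %in% names(seq$variant_overrides)) {
    label <- seq$variant_overrides[["B"]]
    labels <- vapply(get_module("B")$variants, `[[`, "", "label")
    if (!label %in% labels) {
      noah_abort(sprintf("unknown HMBC variant '%s'", label), "noah_unknown_variant")
    }
    return(label)
  }
  later <- seq$modules[seq_along(seq$modules) > pos]
  needs <- unique(unlist(lapply(later, function(m) get_module(m)$pools_required)))
  need_c <- "C13_BOUND_1H" %in% needs
  need_n <- "N15_BOUND_1H" %in% needs
  if (need_c && need_n) "CN" else if (need_c) "C" else if (need_n) "N" else "NONE"
}

#' Decide whether the ZIP element is inserted in an seHSQC module
#'
#' The ZIP element preserves bulk 1H magnetization for later modules at a
#' small sensitivity cost; it is inserted exactly when some later module
#' draws on the bulk pool, and omitted when the seHSQC is last.
#'
#' @param seq A [supersequence()].
#' @param position Position (1-based) of an seHSQC module (`"Sp"`/`"SNp"`).
#' @return `TRUE` if the ZIP element is inserted.
#' @export
#' @examples
#' resolve_zip(supersequence(c("Sp", "Cc")), 1)   # TRUE
resolve_zip <- function(seq, position) {
  seq <- as_supersequence(seq, developer_mode = TRUE)
  mod <- seq$modules[position]
  if (is.na(mod) || !mod %in% c("Sp", "SNp")) {
    noah_abort(sprintf("module at position %s is not a sensitivity-enhanced HSQC",
                       position), "noah_not_sehsqc")
  }
  later <- seq$modules[seq_along(seq$modules) > position]
  any(vapply(later, function(m) "BULK_1H" %in% get_module(m)$pools_required, TRUE))
}

#' Determine the glue blocks placed between modules
#'
#' ASAP isotropic mixing is inserted immediately before the first
#' homonuclear (or pure shift / 2DJ) module when an HMBC precedes it, so
#' that the shared bulk magnetization is redistributed before the
#' homonuclear experiment; it is suppressed when that module is a NOESY
#' (mixing would perturb the NOE buildup) unless the `"ASAP"` option forces
#' it.  Every other internal module boundary receives a purge pulse + PFG.
#'
#' @param seq A [supersequence()].
#' @return Data frame with columns `position` (glue sits between modules
#'   `position` and `position + 1`) and `kind`
#'   (`"ASAP_MIXING"`/`"PURGE_PULSE_PFG"`); zero rows for a single module.
#' @export
#' @examples
#' resolve_glue(supersequence(c("B", "S", "C")))
resolve_glue <- function(seq) {
  seq <- as_supersequence(seq, developer_mode = TRUE)
  mods <- seq$modules
  n <- length(mods)
  if (n < 2) {
    return(data.frame(position = integer(0), kind = character(0),
                      stringsAsFactors = FALSE))
  }
  slots <- vapply(mods, function(m) get_module(m)$slot, "")
  kinds <- rep("PURGE_PULSE_PFG", n - 1)
  first_homo <- which(slots == "HOMO")[1]
  if (!is.na(first_homo) && first_homo > 1 &&
      any(slots[seq_len(first_homo - 1)] == "HMBC")) {
    if (mods[first_homo] != "N" || "ASAP" %in% seq$options) {
      kinds[first_homo - 1] <- "ASAP_MIXING"
    }
  }
  data.frame(position = seq_len(n - 1), kind = kinds, stringsAsFactors = FALSE)
}

#' Resolve a supersequence into assembly-ready module definitions
#'
#' Applies the adaptive zz-filter choice ([resolve_hmbc_filter()]), inserts
#' or omits ZIP elements ([resolve_zip()]), fixes inter-module glue
#' ([resolve_glue()]), and honours developer-mode variant overrides.
#'
#' @param seq A [supersequence()] or character vector of abbreviations.
#' @return An object of class `noah_resolved`: list with `modules` (resolved
#'   definitions), `variant_labels`, `glue`, `options` and the originating
#'   `request`.
#' @export
#' @examples
#' res <- resolve_sequence(c("Sp", "Cc"))
#' res$variant_labels
resolve_sequence <- function(seq) {
  seq <- as_supersequence(seq)
  mods <- seq$modules
  labels <- setNames(rep(NA_character_, length(mods)), mods)
  resolved <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    ab <- mods[i]
    def <- get_module(ab)
    if (length(def$variants)) {
      label <- if (ab == "B") resolve_hmbc_filter(seq) else {
        ov <- seq$variant_overrides[[ab]]
        if (seq$developer_mode && !is.null(ov)) ov else def$variants[[1]]$label
      }
      def <- apply_variant(get_module(ab), label)
      labels[i] <- label
    }
    if (ab %in% c("Sp", "SNp")) {
      zip <- resolve_zip(seq, i)
      ph <- grep("^<<ZIP>>$", def$body)
      if (length(ph) == 1) {
        repl <- if (zip) def$zip_block else
          "; (ZIP element omitted: no later module draws on bulk 1H)"
        def$body <- append(def$body[-ph], repl, after = ph - 1L)
      }
      labels[i] <- if (zip) "ZIP" else "NOZIP"
    }
    resolved[[i]] <- def
  }
  structure(list(modules = resolved, variant_labels = labels,
                 glue = resolve_glue(seq), options = seq$options,
                 request = seq),
            class = "noah_resolved")
}
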