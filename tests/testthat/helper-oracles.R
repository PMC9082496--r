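# Shared helpers: a brute-force enumeration oracle (independent of the
# pruned DFS in enumerate_viable) and minimal in-code module fixtures used
# to force collation conflicts.

# all ordered k-selections (no repetition) from `pool`
ordered_selections <- function(pool, k) {
  if (k == 0) return(list(character(0)))
  out <- list()
  for (i in seq_along(pool)) {
    for (tail in ordered_selections(pool[-i], k - 1)) {
      out[[length(out) + 1L]] <- c(pool[i], tail)
    }
  }
  out
}

# brute-force filter of every ordered selection through check_viability
brute_force_viable <- function(pool, min_len = 2, max_len = 5) {
  out <- character(0)
  for (k in min_len:max_len) {
    if (k > length(pool)) break
    for (sel in ordered_selections(pool, k)) {
      if (check_viability(sel)$viable) {
        out <- c(out, paste(sel, collapse = ","))
      }
    }
  }
  sort(out)
}

# minimal module-like fixture for collation tests
fake_module <- function(abbr, params = NULL, phases = list()) {
  if (is.null(params)) {
    params <- data.frame(kind = character(0), name = character(0),
                         definition = character(0), comment = character(0),
                         stringsAsFactors = FALSE)
  }
  list(abbreviation = abbr, display_name = abbr, category = "HOMONUCLEAR",
       slot = "HOMO", au_program = "noah_x", parameters = params,
       phase_cycles = phases, gradients = NULL, wavemaker = character(0),
       body = character(0), ea_gradients = integer(0), t1_delay = NULL,
       supports_flags = character(0), pools_required = "BULK_1H",
       pools_consumed = "BULK_1H", pools_preserved = "BULK_1H")
}

param_row <- function(name, definition, comment = "a comment",
                      kind = "CONSTANT") {
  data.frame(kind = kind, name = name, definition = definition,
             comment = comment, stringsAsFactors = FALSE)
}

fake_resolved <- function(mods) {
  structure(list(modules = mods, variant_labels = character(0),
                 glue = NULL, options = character(0)),
            class = "noah_resolved")
}

# reference metadata giving byte-reproducible programs in tests
test_metadata <- function() {
  generator_metadata(version = "2.1.0", timestamp = "2022-01-20T00:00:00Z")
}
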