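# Magnetization-pool bookkeeping and viability of module orderings.
#
# Model: three 1H magnetization pools (bulk/12C-bound, 13C-bound, 15N-bound).
# A module draws on its pools_required, destroys its pools_consumed, and
# leaves pools_preserved available; a pool both consumed and preserved
# survives only partially.  A module ordering is viable when no module
# destroys a pool that a later module draws on -- except where a documented
# tolerated-loss rule applies -- and when the slot ordering
# HMBC < 15N < 13C < homonuclear/pure-shift is respected.

#' Tolerated sensitivity-loss rules
#'
#' The fixed set of cases in which consuming a pool needed later is accepted
#' rather than fatal: (i) a homonuclear (or pure shift / 2DJ) module may
#' follow an HMBC, sharing the bulk pool, because its intrinsic sensitivity
#' is far greater; (ii) a second homonuclear module may follow a first with
#' tolerated partial loss of the bulk pool (the first preserves part of it).
#'
#' @return Data frame with columns `earlier_slot`, `later_slot`, `pool`,
#'   `rationale`.
#' @export
tolerated_loss_rules <- function() {
  data.frame(
    earlier_slot = c("HMBC", "HOMO"),
    later_slot = c("HOMO", "HOMO"),
    pool = c("BULK_1H", "BULK_1H"),
    rationale = c(
      "homonuclear modules have far greater intrinsic sensitivity than HMBC",
      "a second homonuclear module draws on the partially surviving bulk pool"
    ),
    stringsAsFactors = FALSE
  )
}

# is consuming `pool` at position i tolerated for the module at position j?
# Rule (ii) additionally requires that the earlier module actually lets part
# of the pool survive (pool in preserved(i)), which excludes pure shift /
# 2DJ modules as the *earlier* member of a homonuclear pair.
loss_tolerated <- function(attrs_i, attrs_j, pool) {
  rules <- tolerated_loss_rules()
  for (k in seq_len(nrow(rules))) {
    if (attrs_i$slot == rules$earlier_slot[k] &&
        attrs_j$slot == rules$later_slot[k] &&
        pool == rules$pool[k]) {
      if (rules$earlier_slot[k] == "HOMO" && !pool %in% attrs_i$preserved) next
      return(TRUE)
    }
  }
  FALSE
}

mod_attr <- function(at, i) {
  list(abbr = at$abbr[[i]], slot = at$slot[[i]], rank = at$rank[[i]],
       category = at$category[[i]], required = at$required[[i]],
       consumed = at$consumed[[i]], preserved = at$preserved[[i]])
}

#' Trace magnetization-pool states through a supersequence
#'
#' @param seq A [supersequence()] or character vector of abbreviations.
#' @return A character matrix with one row per module position (after that
#'   module has run) and one column per pool, entries in
#'   `INTACT`/`PARTIAL`/`CONSUMED`.  Zero rows for an empty sequence.
#' @export
#' @examples
#' magnetization_trace(c("S", "C"))
magnetization_trace <- function(seq) {
  mods <- if (inherits(seq, "noah_supersequence")) seq$modules else as.character(seq)
  state <- setNames(rep("INTACT", length(noah_pools)), noah_pools)
  out <- matrix(character(0), nrow = 0, ncol = length(noah_pools),
                dimnames = list(NULL, noah_pools))
  if (!length(mods)) return(out)
  at <- module_attrs(mods)
  for (i in seq_along(mods)) {
    a <- mod_attr(at, i)
    for (pool in noah_pools) {
      if (pool %in% a$consumed) {
        state[pool] <- if (pool %in% a$preserved && state[pool] != "CONSUMED")
          "PARTIAL" else "CONSUMED"
      }
    }
    out <- rbind(out, state)
  }
  rownames(out) <- mods
  out
}

#' Check whether a module ordering is viable
#'
#' A diagnostic is fatal when (a) a module consumes a magnetization pool that
#' a later module draws on and no tolerated-loss rule applies, or (b) the
#' ordering violates the slot ranking (HMBC, then 15N, then 13C, then
#' homonuclear/pure-shift modules), or (c) a slot is over-occupied (at most
#' one module per heteronuclear slot, at most two homonuclear/pure-shift
#' modules), or (d) a module is repeated.
#'
#' @param seq A [supersequence()] or character vector of abbreviations.
#' @return An object of class `noah_verdict`: list with `viable` (logical)
#'   and `diagnostics` (data frame: position, pool, message, fatal).
#' @export
#' @examples
#' check_viability(c("S", "C"))$viable   # TRUE
#' check_viability(c("C", "S"))$viable   # FALSE
check_viability <- function(seq) {
  sseq <- as_supersequence(seq, developer_mode = TRUE)
  mods <- sseq$modules
  at <- module_attrs(mods)
  diags <- list()
  add <- function(position, pool, message, fatal) {
    diags[[length(diags) + 1L]] <<- data.frame(
      position = position, pool = pool %||% NA_character_,
      message = message, fatal = fatal, stringsAsFactors = FALSE)
  }
  n <- length(mods)
  if (n < 2 || n > 5) {
    add(n, NULL, sprintf("supersequence length %d outside 2-5", n), TRUE)
  }
  dup <- duplicated(mods)
  if (any(dup)) {
    add(which(dup)[1], NULL,
        sprintf("module %s repeated", mods[which(dup)[1]]), TRUE)
  }
  # slot occupancy
  slot_count <- table(at$slot)
  caps <- c(HMBC = 1L, N15 = 1L, C13 = 1L, HOMO = 2L)
  for (s in names(slot_count)) {
    if (slot_count[[s]] > caps[[s]]) {
      add(NA_integer_, NULL,
          sprintf("slot %s holds %d modules (at most %d)", s, slot_count[[s]], caps[[s]]),
          TRUE)
    }
  }
  # slot ordering
  for (i in seq_len(max(n - 1, 0))) {
    if (at$rank[[i]] > at$rank[[i + 1]]) {
      add(i + 1L, NULL,
          sprintf("%s (%s) may not follow %s (%s): modules must be ordered HMBC, 15N, 13C, then homonuclear",
                  mods[i + 1], at$slot[[i + 1]], mods[i], at$slot[[i]]),
          TRUE)
    }
  }
  # pool consumption vs later needs
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ai <- mod_attr(at, i)
      for (j in (i + 1):n) {
        aj <- mod_attr(at, j)
        lost <- intersect(ai$consumed, aj$required)
        for (pool in lost) {
          if (loss_tolerated(ai, aj, pool)) {
            add(i, pool,
                sprintf("%s consumes %s needed by %s; loss tolerated (%s)",
                        mods[i], pool, mods[j], ai$slot), FALSE)
          } else {
            add(i, pool,
                sprintf("%s consumes %s magnetization needed by later module %s",
                        mods[i], pool, mods[j]), TRUE)
          }
        }
      }
    }
  }
  diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(position = integer(0), pool = character(0),
               message = character(0), fatal = logical(0))
  structure(list(viable = !any(diagnostics$fatal), diagnostics = diagnostics),
            class = "noah_verdict")
}

#' @export
print.noah_verdict <- function(x, ...) {
  cat(if (x$viable) "viable\n" else "NOT viable\n")
  d <- x$diagnostics
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  [%s] %s\n", if (d$fatal[i]) "fatal" else "note", d$message[i]))
  }
  invisible(x)
}

#' Enumerate all viable supersequences
#'
#' Depth-first enumeration over the registry (or a subset), pruned on the
#' prefix property: every viable sequence extends a valid shorter selection.
#' The result is identical to brute-force filtering of all ordered
#' no-repeat selections through [check_viability()].
#'
#' @param min_len,max_len Length bounds (2 to 5).
#' @param modules Optional character vector restricting the registry.
#' @param as_strings Return comma-joined strings instead of
#'   [supersequence()] objects (cheaper for large enumerations).
#' @return List of supersequences (or character vector if `as_strings`).
#' @export
#' @examples
#' length(enumerate_viable(modules = c("S", "C"), max_len = 2))  # 1: "S,C"
enumerate_viable <- function(min_len = 2, max_len = 5, modules = NULL,
                             as_strings = FALSE) {
  noah_stopifnot(min_len >= 2 && min_len <= max_len && max_len <= 5,
                 "need 2 <= min_len <= max_len <= 5")
  pool <- modules %||% names(noah_registry()$modules)
  at <- module_attrs(pool)
  n <- length(pool)
  out <- character(0)
  # partial validity: no repeats, slot caps, rank monotone, no intolerable
  # pool loss; all are preserved under truncation, so pruning is sound.
  recurse <- function(idx) {
    len <- length(idx)
    if (len >= min_len) out[[length(out) + 1L]] <<- paste(pool[idx], collapse = ",")
    if (len == max_len) return(invisible())
    for (k in seq_len(n)) {
      if (k %in% idx) next
      cand <- c(idx, k)
      if (partial_ok(at, cand)) recurse(cand)
    }
  }
  recurse(integer(0))
  out <- sort(out)
  if (as_strings) return(out)
  lapply(out, function(s) supersequence(strsplit(s, ",", fixed = TRUE)[[1]]))
}

# validity of a partial selection (indices into the attrs table)
partial_ok <- function(at, idx) {
  len <- length(idx)
  slots <- unlist(at$slot[idx])
  if (sum(slots == "HOMO") > 2) return(FALSE)
  if (anyDuplicated(slots[slots != "HOMO"])) return(FALSE)
  ranks <- unlist(at$rank[idx])
  if (len >= 2 && any(diff(ranks) < 0)) return(FALSE)
  if (len >= 2) {
    i <- len - 1L
    # only the new boundary needs checking: earlier pairs were checked before
    aj <- mod_attr(at, idx[len])
    for (ii in seq_len(len - 1L)) {
      ai <- mod_attr(at, idx[ii])
      lost <- intersect(ai$consumed, aj$required)
      for (pool in lost) {
        if (!loss_tolerated(ai, aj, pool)) return(FALSE)
      }
    }
  }
  TRUE
}
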