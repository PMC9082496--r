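# Nonuniform sampling schedules.  NOAH experiments cannot use the stock
# vendor NUS routine because every module shares the t1 loop, so the list of
# sampled increments is generated here and written to a sidecar file that
# the NUS-flagged pulse program reads.  Sampling law: uniform random without
# replacement, with increment 1 always included; deterministic given a seed.

# run `expr` under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a nonuniform sampling schedule
#'
#' Selects `round(fraction * td1_full)` unique t1 increment indices from
#' `1:td1_full`.  The first increment is always included (it anchors the
#' interferogram); the remainder are drawn uniformly at random without
#' replacement.  `fraction = 1` returns all increments in order.
#'
#' @param td1_full Full number of t1 increments (>= 2).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @return Object of class `noah_nus_schedule` with fields `td1_full`,
#'   `fraction`, `seed`, `increments` (sorted, unique, starting at 1).
#' @export
#' @examples
#' generate_nus_schedule(16, 0.25, seed = 1)$increments
generate_nus_schedule <- function(td1_full, fraction, seed) {
  noah_stopifnot(is.numeric(td1_full) && length(td1_full) == 1 &&
                   td1_full >= 2 && td1_full == as.integer(td1_full),
                 "td1_full must be an integer >= 2")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    noah_abort("fraction must lie in (0, 1]", "noah_bad_fraction")
  }
  td1_full <- as.integer(td1_full)
  n <- as.integer(round(fraction * td1_full))
  if (n < 1) {
    noah_abort(sprintf("fraction %g of %d increments rounds to an empty schedule",
                       fraction, td1_full), "noah_bad_fraction")
  }
  increments <- if (n == td1_full) seq_len(td1_full) else {
    with_seed(seed, sort(c(1L, sample(2:td1_full, n - 1L))))
  }
  structure(list(td1_full = td1_full, fraction = fraction,
                 seed = as.integer(seed), increments = as.integer(increments)),
            class = "noah_nus_schedule")
}

#' @export
print.noah_nus_schedule <- function(x, ...) {
  cat(sprintf("<NUS schedule> %d of %d increments (fraction %.3g, seed %d)\n",
              length(x$increments), x$td1_full, x$fraction, x$seed))
  cat(" ", paste(utils::head(x$increments, 16), collapse = " "),
      if (length(x$increments) > 16) "...\n" else "\n")
  invisible(x)
}

#' Write a NUS schedule to its sidecar list file
#'
#' One increment index per line, as read by the NUS-flagged pulse program.
#'
#' @param schedule A [generate_nus_schedule()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nus_schedule <- function(schedule, path) {
  noah_stopifnot(inherits(schedule, "noah_nus_schedule"),
                 "schedule must come from generate_nus_schedule()")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(schedule$increments), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
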