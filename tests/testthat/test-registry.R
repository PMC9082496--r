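# Module library: registry content, completeness invariants, delay formulas
# and CTP gradient arithmetic.

test_that("registry ships the fixed 15-module inventory", {
  df <- list_modules()
  expect_equal(nrow(df), 15)
  expect_setequal(df$abbreviation,
                  c("B", "S", "Sp", "SNp", "M", "C", "Cc", "T", "N", "R",
                    "St", "P", "Pt", "J", "Jqf"))
  expect_setequal(unique(df$category),
                  c("HET_13C", "HET_15N", "HOMONUCLEAR", "PURESHIFT_2DJ"))
})

test_that("module lookup returns definitions and rejects unknown keys", {
  s <- get_module("S")
  expect_s3_class(s, "noah_module")
  expect_identical(s$au_program, "noah_hsqc")
  expect_error(get_module("ZZZ"), class = "noah_unknown_module")
  expect_error(get_module("B", "NOPE"), class = "noah_unknown_variant")

  b <- get_module("B", "C")
  expect_true("C13_BOUND_1H" %in% b$pools_preserved)
  expect_false("N15_BOUND_1H" %in% b$pools_preserved)
  expect_false(any(grepl("<<ZZFILTER>>", b$body)))
  expect_true(any(grepl("retains 13C-bound", b$body)))
})

test_that("every body/variant/zip token resolves in the module's own tables", {
  # validate_registry() runs this check at load; force a reload so a broken
  # registry cannot hide behind the session cache
  expect_silent(reg <- noah_registry(refresh = TRUE))
  expect_length(reg$modules, 15)
  # and the check actually bites: a module body with a stray token fails
  dir <- tempfile("reg")
  dir.create(dir)
  file.copy(list.files(system.file("registry", package = "noahgen"),
                       full.names = TRUE), dir)
  m <- readLines(file.path(dir, "C.yaml"))
  writeLines(sub("p16:gp15", "p16:gp99", m), file.path(dir, "C.yaml"))
  expect_error(noah_registry(path = dir), class = "noah_registry_error")
})

test_that("each module owns exactly one receiver cycle and valid tables", {
  for (m in noah_registry()$modules) {
    recv <- vapply(m$phase_cycles, `[[`, TRUE, "receiver")
    expect_equal(sum(recv), 1, info = m$abbreviation)
    for (pc in m$phase_cycles) {
      expect_true(length(pc$steps) %in% c(1, 2, 4, 8, 16))
      expect_true(all(pc$steps %in% c("x", "-x", "y", "-y")))
    }
    expect_true(all(abs(m$gradients$amplitude) <= 100))
    expect_true(all(m$gradients$duration_ms > 0))
    locals <- m$parameters$name[m$parameters$kind == "LOCAL_DELAY"]
    expect_true(all(grepl("^D[A-Z]_[A-Z0-9]+[0-9]$", locals)),
                info = m$abbreviation)
  }
})

test_that("transfer delays follow the 1/(4J) and 1/(2J) formulas", {
  d <- compute_delays(coupling_constants(one_bond_JCH = 146,
                                         long_range_JCH = 5,
                                         one_bond_JNH = 90))
  expect_equal(d$delta, 1 / (4 * 146))          # 1.7123 ms
  expect_equal(d$delta * 1e3, 1.7123, tolerance = 1e-4)
  expect_equal(d$delta_lr, 0.1)                 # 1/(2*5) = 100 ms
  expect_equal(d$delta_n, 1 / 360)
  expect_error(coupling_constants(one_bond_JCH = 0),
               class = "noah_nonpositive_coupling")
  expect_error(compute_delays(list(one_bond_JCH = -5, long_range_JCH = 5,
                                   one_bond_JNH = 90)),
               class = "noah_nonpositive_coupling")
})

test_that("transfer delays are strictly decreasing in each coupling", {
  grid <- c(30, 60, 90, 146, 250, 900)
  for (field in c("one_bond_JCH", "long_range_JCH", "one_bond_JNH")) {
    vals <- vapply(grid, function(J) {
      args <- list(one_bond_JCH = 145, long_range_JCH = 5, one_bond_JNH = 90)
      args[[field]] <- J
      d <- compute_delays(do.call(coupling_constants, args))
      switch(field, one_bond_JCH = d$delta, long_range_JCH = d$delta_lr,
             one_bond_JNH = d$delta_n)
    }, 0)
    expect_true(all(diff(vals) < 0), info = field)
  }
})

test_that("CTP refocusing amplitudes scale with the gyromagnetic ratio", {
  expect_equal(ctp_gradient_amplitude(80, 0.10137, 1), 8.1)
  expect_equal(ctp_gradient_amplitude(80, 0.10137, 4), 32.4)   # 4 * 8.1
  r <- gyromagnetic_ratios()
  expect_equal(ctp_gradient_amplitude(80, r[["N15"]] / r[["H1"]], 1), 8.1)
  expect_equal(ctp_gradient_amplitude(80, r[["C13"]] / r[["H1"]], 1), 20.1)
  expect_error(ctp_gradient_amplitude(80, 0.1, 0), class = "noah_precondition")
  expect_error(ctp_gradient_amplitude(0, 0.1, 1), class = "noah_precondition")
  expect_error(ctp_gradient_amplitude(101, 0.1, 1), class = "noah_precondition")
})

test_that("13C HSQC-type refocusing gradient matches the analytic ratio", {
  r <- gyromagnetic_ratios()
  g <- get_module("S")$gradients
  expect_equal(g$amplitude[g$index == 7],
               ctp_gradient_amplitude(80, r[["C13"]] / r[["H1"]], 1))
})
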