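# Assembler: collation, phase merging, nine-section rendering, footer
# round trip.

test_that("shared parameters are merged once; conflicts name both sources", {
  res <- resolve_sequence(c("Sp", "Cc"))
  params <- collate_parameters(res)
  expect_equal(anyDuplicated(params$name), 0)
  expect_equal(sum(params$name == "d4"), 1)      # used by both modules

  # idempotence: a single module's table passes through unchanged
  one <- fake_resolved(list(fake_module("X", param_row("cnst2", "", "1J(CH)"))))
  p1 <- collate_parameters(one)
  expect_equal(p1$name[p1$source == "X"], "cnst2")

  # forced conflict fixture
  conflict <- fake_resolved(list(
    fake_module("X", param_row("cnst2", "cnst2=145", "1J(CH)")),
    fake_module("Y", param_row("cnst2", "cnst2=8", "something else"))))
  err <- expect_error(collate_parameters(conflict),
                      class = "noah_parameter_conflict")
  expect_match(conditionMessage(err), "X")
  expect_match(conditionMessage(err), "Y")
})

test_that("phase cycles merge by index; same index with different steps fails", {
  res <- resolve_sequence(c("B", "S", "C"))
  cycles <- merge_phase_cycles(res)
  idx <- vapply(cycles, `[[`, 0L, "index")
  expect_equal(anyDuplicated(idx), 0)
  # disjoint indices from different modules: union
  expect_true(all(c(1, 2, 5, 6, 29, 30) %in% idx))
  by_idx <- function(i) cycles[[match(i, idx)]]
  expect_equal(by_idx(1)$steps, c("x", "-x"))
  expect_equal(by_idx(2)$steps, c("x", "x", "-x", "-x"))
  expect_true(by_idx(30)$receiver)

  clash <- fake_resolved(list(
    fake_module("X", phases = list(list(index = 1L, steps = "x", receiver = FALSE))),
    fake_module("Y", phases = list(list(index = 1L, steps = c("x", "-x"),
                                        receiver = FALSE)))))
  expect_error(merge_phase_cycles(clash), class = "noah_phase_conflict")
})

test_that("assembly is byte-deterministic and lists all nine sections in order", {
  res <- resolve_sequence(c("Sp", "Cc"))
  a <- assemble(res, test_metadata())
  b <- assemble(resolve_sequence(c("Sp", "Cc")), test_metadata())
  expect_identical(as.character(a), as.character(b))

  txt <- as.character(a)
  markers <- grep("^; === ", txt)
  expect_length(markers, 10)
  expect_identical(txt[markers], unname(noahgen:::.section_markers))
  expect_true(all(diff(markers) > 0))
})

test_that("the footer encodes modules, AU programs, version and timestamp", {
  prog <- assemble(resolve_sequence(c("B", "S", "C")), test_metadata())
  pf <- parse_footer(prog)
  expect_identical(pf$modules, c("B", "S", "C"))
  expect_identical(pf$au_programs, c("noah_hmbc", "noah_hsqc", "noah_cosy"))
  expect_identical(pf$metadata$version, "2.1.0")
  expect_identical(pf$metadata$timestamp, "2022-01-20T00:00:00Z")

  # mutilated footer
  txt <- as.character(prog)
  expect_error(parse_footer(txt[!grepl("^;MODULES: ", txt)]),
               class = "noah_malformed_footer")
  # AU list must match module list
  bad <- sub("^;AUPROG: .*$", ";AUPROG: noah_hmbc", txt)
  expect_error(parse_footer(bad), class = "noah_malformed_footer")
})

test_that("the HMBC 13C purge pulse follows the zz-filter in assembled text", {
  txt <- as.character(assemble(resolve_sequence(c("B", "S", "C")),
                               test_metadata()))
  zz <- grep("zz-filter \\(retains 13C-bound 1H\\)", txt)
  purge <- grep("13C 90 degree purge pulse", txt)
  expect_length(zz, 1)
  expect_length(purge, 1)
  expect_gt(purge, zz)
})

test_that("annotation sections cover gradients, shaped pulses and parameters", {
  # HMBC alone: five gradient comment lines, one per printed PFG
  resB <- resolve_sequence(supersequence("B", developer_mode = TRUE))
  ann <- render_annotations(resB)
  expect_length(ann$gradients, 5)
  expect_match(ann$gradients[5], "^;gpz5: \\+/-40\\.2% \\(1 ms, SMSQ10\\.100, echo-antiecho\\)$")
  expect_true(all(grepl("^;", ann$ased)))

  # a module with no shaped pulses has an empty WaveMaker section
  resM <- resolve_sequence(supersequence("M", developer_mode = TRUE))
  expect_length(render_annotations(resM)$wavemaker, 0)

  # strict mode requires a description for every parameter
  bare <- fake_resolved(list(fake_module("X", param_row("cnst9", "", comment = ""))))
  expect_error(render_annotations(bare), class = "noah_missing_annotation")
  expect_silent(render_annotations(bare, strict = FALSE))
})

test_that("t1 incrementation and echo-antiecho commands cover every indirect dimension", {
  txt <- as.character(assemble(resolve_sequence(c("B", "Sp", "Cc")),
                               test_metadata()))
  expect_true(any(grepl("^  1m id0 ", txt)))    # HMBC t1
  expect_true(any(grepl("^  1m id10 ", txt)))   # seHSQC t1
  expect_true(any(grepl("^  1m id12 ", txt)))   # CLIP-COSY t1
  expect_true(any(grepl("igrad gp5", txt)))     # HMBC echo-antiecho
  expect_true(any(grepl("igrad gp7", txt)))     # seHSQC echo-antiecho
})

test_that("programs survive a disk round trip unchanged", {
  prog <- assemble(resolve_sequence(c("S", "C")), test_metadata())
  path <- tempfile(fileext = ".prog")
  write_pulse_program(prog, path)
  expect_identical(readLines(path), as.character(prog))
})
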