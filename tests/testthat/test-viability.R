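# Magnetization-pool bookkeeping, viability verdicts and enumeration.

test_that("supersequence construction enforces the 2-5 module cap", {
  expect_s3_class(supersequence(c("S", "C")), "noah_supersequence")
  expect_error(supersequence(c("B", "M", "S", "C", "N", "P")),
               class = "noah_bad_sequence")
  expect_error(supersequence("S"), class = "noah_bad_sequence")
  expect_s3_class(supersequence("S", developer_mode = TRUE),
                  "noah_supersequence")
  expect_s3_class(supersequence(c("B", "M", "S", "C", "N", "P"),
                                developer_mode = TRUE), "noah_supersequence")
  expect_error(supersequence(c("S", "XX")), class = "noah_unknown_module")
})

test_that("the magnetization trace tracks pool consumption per position", {
  tr <- magnetization_trace(c("S", "C"))
  expect_equal(tr["S", "BULK_1H"], "INTACT")
  expect_equal(tr["S", "C13_BOUND_1H"], "CONSUMED")
  expect_equal(tr["C", "C13_BOUND_1H"], "CONSUMED")
  # homonuclear excitation is nonselective
  tr2 <- magnetization_trace(c("C", "S"))
  expect_equal(tr2["C", "C13_BOUND_1H"], "CONSUMED")
  expect_equal(tr2["C", "BULK_1H"], "PARTIAL")
  # HMBC's zz-filter leaves part of the bulk and all heteronuclear pools
  tr3 <- magnetization_trace(c("B", "S", "C"))
  expect_equal(unname(tr3["B", ]), c("PARTIAL", "INTACT", "INTACT"))
  expect_equal(nrow(magnetization_trace(character(0))), 0)
})

test_that("SC and BSC are viable; CS and SBC are rejected", {
  expect_true(check_viability(c("S", "C"))$viable)
  expect_true(check_viability(c("B", "S", "C"))$viable)

  cs <- check_viability(c("C", "S"))
  expect_false(cs$viable)
  expect_true("C13_BOUND_1H" %in% cs$diagnostics$pool[cs$diagnostics$fatal])

  sbc <- check_viability(c("S", "B", "C"))
  expect_false(sbc$viable)
  # HMBC-before-homonuclear ordering violation, not a pool loss
  expect_true(any(grepl("ordered", sbc$diagnostics$message[sbc$diagnostics$fatal])))
})

test_that("tolerated-loss rules are the documented fixed set", {
  rules <- tolerated_loss_rules()
  expect_equal(nrow(rules), 2)
  expect_true(all(rules$pool == "BULK_1H"))
  # BSC: bulk loss for the COSY is tolerated, not fatal
  v <- check_viability(c("B", "S", "C"))
  expect_true(any(!v$diagnostics$fatal & v$diagnostics$pool == "BULK_1H"))
  # two homonuclear modules may share the bulk pool (COSY then NOESY)...
  expect_true(check_viability(c("S", "C", "N"))$viable)
  # ...but a pure shift module destroys it outright, so nothing may follow
  expect_true(check_viability(c("S", "C", "P"))$viable)
  expect_false(check_viability(c("S", "P", "C"))$viable)
})

test_that("repetition and slot over-occupancy are rejected", {
  expect_false(check_viability(c("S", "S"))$viable)
  expect_false(check_viability(c("M", "SNp", "C"))$viable)   # two 15N modules
  expect_false(check_viability(c("S", "Sp", "C"))$viable)    # two 13C modules
  expect_false(check_viability(c("C", "T", "N"))$viable)     # three homonuclear
})

test_that("enumeration on restricted registries matches hand-derived cases", {
  expect_length(enumerate_viable(modules = "S"), 0)
  only_sc <- enumerate_viable(modules = c("S", "C"), max_len = 2,
                              as_strings = TRUE)
  expect_identical(only_sc, "S,C")
})

test_that("pruned enumeration equals the brute-force oracle", {
  pool <- c("B", "M", "S", "C", "P")
  expect_identical(enumerate_viable(modules = pool, as_strings = TRUE),
                   brute_force_viable(pool))
  pool2 <- c("SNp", "Sp", "N", "Jqf")
  expect_identical(enumerate_viable(modules = pool2, as_strings = TRUE),
                   brute_force_viable(pool2))
})

test_that("full-registry enumeration matches the combinatorial closed form", {
  # independent oracle: under the slot rules the count factorises over the
  # slot occupancies (HMBC 0/1; one of the 15N modules 0/1; one of the 13C
  # modules 0/1; then 0-2 homonuclear/pure-shift modules, where only a
  # partially-preserving homonuclear module may be first of a pair)
  df <- list_modules()
  mods <- noah_registry()$modules
  n15 <- sum(df$category == "HET_15N")
  c13 <- sum(vapply(mods, function(m) m$slot == "C13", TRUE))
  homo <- sum(df$category == "HOMONUCLEAR")
  group <- homo + sum(df$category == "PURESHIFT_2DJ")
  hways <- c(`0` = 1, `1` = group, `2` = homo * (group - 1))
  total <- 0
  for (b in 0:1) for (nn in 0:1) for (cc in 0:1) for (h in 0:2) {
    len <- b + nn + cc + h
    if (len >= 2 && len <= 5) {
      total <- total + (if (nn) n15 else 1) * (if (cc) c13 else 1) *
        hways[[as.character(h)]]
    }
  }
  seqs <- enumerate_viable(as_strings = TRUE)
  expect_equal(length(seqs), total)
  expect_equal(anyDuplicated(seqs), 0)
})

test_that("every length >= 2 prefix of a viable sequence is viable", {
  seqs <- enumerate_viable(as_strings = TRUE)
  picked <- seqs[seq(1, length(seqs), by = 7)]  # systematic subsample
  for (s in picked) {
    mods <- strsplit(s, ",")[[1]]
    for (k in 2:length(mods)) {
      expect_true(check_viability(mods[seq_len(k)])$viable, info = s)
    }
  }
})

test_that("removing a module from the registry never increases the count", {
  full <- length(enumerate_viable(as_strings = TRUE))
  all_mods <- names(noah_registry()$modules)
  for (drop in c("B", "M", "S", "C", "P")) {
    reduced <- length(enumerate_viable(modules = setdiff(all_mods, drop),
                                       as_strings = TRUE))
    expect_lt(reduced, full)
  }
})

test_that("no homonuclear or pure shift module precedes a heteronuclear one", {
  seqs <- enumerate_viable(as_strings = TRUE)
  cats <- vapply(noah_registry()$modules, `[[`, "", "category")
  for (s in seqs) {
    cc <- cats[strsplit(s, ",")[[1]]]
    het_pos <- which(cc %in% c("HET_13C", "HET_15N"))
    homo_pos <- which(cc %in% c("HOMONUCLEAR", "PURESHIFT_2DJ"))
    if (length(het_pos) && length(homo_pos)) {
      expect_lt(max(het_pos), min(homo_pos))
    }
  }
})
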