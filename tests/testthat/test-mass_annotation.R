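test_that("formula parsing handles plain, underscored and degenerate inputs", {
  expect_equal(unclass(parse_formula("C15H10O5"))[c("C", "H", "O")],
               c(C = 15L, H = 10L, O = 5L))
  f <- parse_formula("C_21_H_20_O_14_S")
  expect_equal(unclass(f)[c("C", "H", "O", "S")],
               c(C = 21L, H = 20L, O = 14L, S = 1L))
  expect_equal(unclass(parse_formula("H")), c(H = 1L))
  expect_error(parse_formula("C3Xx2"), "unknown element|cannot parse")
  expect_error(parse_formula("15C"), "cannot parse")
})

test_that("parse and format round-trip every library formula", {
  lib <- ums_compound_library()
  for (f in lib$formula) {
    expect_identical(format_formula(parse_formula(f)), f)
  }
})

test_that("deprotonated m/z reproduces reference calculated masses", {
  expect_equal(round(deprotonated_mz("C15H10O5"), 4), 269.0450)
  expect_equal(round(deprotonated_mz("C30H26O12"), 4), 577.1346)
  expect_equal(round(deprotonated_mz("C15H10O7"), 4), 301.0348)
  # the proton convention sits one electron mass higher
  expect_equal(deprotonated_mz("C15H10O5", "proton") -
                 deprotonated_mz("C15H10O5"),
               1.00782503 - 1.00727646)
  expect_error(deprotonated_mz("C2"), "no hydrogen")
})

test_that("ppm error is signed relative deviation in parts per million", {
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(ppm_error(269.0454, 269.0450), 1.49, tolerance = 0.005)
  expect_equal(ppm_error(148.9235, 149.0086), -571, tolerance = 0.2)
  expect_error(ppm_error(100, -1), "calculated > 0")
})

test_that("peak annotation self-matches the library and ranks by ppm", {
  lib <- ums_compound_library()
  calc <- vapply(lib$formula, deprotonated_mz, numeric(1))
  # querying the calculated masses themselves matches every entry
  m <- annotate_peaks(calc, lib, tolerance_ppm = 0.1)
  expect_length(attr(m, "unmatched"), 0L)
  # observed masses match their own formulas for 92 of 104 rows at 10 ppm
  # (the remaining rows carry transcription-level mass errors)
  m10 <- annotate_peaks(lib$observed_mz, lib, tolerance_ppm = 10)
  expect_length(attr(m10, "unmatched"), 12L)
  # results ranked by absolute ppm within each peak
  for (pk in split(m10, m10$peak_mz)) {
    expect_false(is.unsorted(abs(pk$ppm)))
  }
  expect_error(annotate_peaks(100, lib[0, ]), "empty")
})

test_that("isobaric entries are both returned and decoys do not disturb matches", {
  lib <- data.frame(
    name = c("a", "b"), class = "other",
    formula = c("C6H12O6", "C6H12O6"),
    observed_mz = NA_real_, fragments = "", confidence = 2L)
  m <- annotate_peaks(deprotonated_mz("C6H12O6"), lib, tolerance_ppm = 5)
  expect_equal(nrow(m), 2L)

  full <- ums_compound_library()
  base <- annotate_peaks(full$observed_mz, full, tolerance_ppm = 5)
  decoy <- full[1, ]
  decoy$name <- "decoy"; decoy$formula <- "C99H160O2"
  with_decoy <- annotate_peaks(full$observed_mz, rbind(full, decoy),
                               tolerance_ppm = 5)
  expect_equal(base, with_decoy, ignore_attr = TRUE)
  # reordering the library leaves the match set unchanged
  shuffled <- annotate_peaks(full$observed_mz, full[rev(seq_len(104)), ],
                             tolerance_ppm = 5)
  expect_equal(base[order(base$peak_mz, base$name), c("peak_mz", "name", "ppm")],
               shuffled[order(shuffled$peak_mz, shuffled$name),
                        c("peak_mz", "name", "ppm")],
               ignore_attr = TRUE)
})

test_that("neutral-loss flagging recognizes the diagnostic losses", {
  glyc <- neutral_loss_flags(567.2084, c(405.15, 387.14))
  expect_true("hexosyl" %in% glyc$loss)
  # exact-mass pair: luteolin hexosyl sulfate -> kaempferol-hexoside ion
  sulf <- neutral_loss_flags(527.0495, 447.0927)
  expect_true("sulfate" %in% sulf$loss)
  # the 2-dp printed fragment drifts 0.043 Da off the exact loss and needs
  # a widened window
  printed <- neutral_loss_flags(527.0502, 447.05, tolerance_da = 0.05)
  expect_true("sulfate" %in% printed$loss)
  expect_false("sulfate" %in% neutral_loss_flags(527.0502, 447.05)$loss)
  none <- neutral_loss_flags(500, c(100, 200))
  expect_equal(nrow(none), 0L)
})

test_that("library annotation adds calculated masses and loss flags", {
  lib <- annotate_library(ums_compound_library())
  expect_true(all(c("calculated_mz", "ppm", "loss_flags") %in% names(lib)))
  expect_equal(lib$calculated_mz[lib$name == "Apigenin"], 269.045,
               tolerance = 1e-4)
  # the two lignan glucosides flag their glycosyl loss
  expect_match(lib$loss_flags[lib$name == "Citrusin B"], "hexosyl")
})
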