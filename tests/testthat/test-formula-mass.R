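test_that("formula parsing handles plain, typeset and repeated-token input", {
  expect_equal(unclass(parse_formula("C10H10O4")), c(C = 10L, H = 10L, O = 4L))
  expect_equal(unclass(parse_formula("C_10_H_10_O_4_")),
               c(C = 10L, H = 10L, O = 4L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  # repeated element tokens sum
  expect_equal(unclass(parse_formula("CH3CH3")), c(C = 2L, H = 6L))
  # single-count elements need no digit
  expect_equal(unclass(parse_formula("CHCl3")), c(C = 1L, H = 1L, Cl = 3L))
})

test_that("formula parsing rejects malformed or unknown input with position", {
  expect_error(parse_formula("C10X2"), "unknown element.*X.*position 4")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("10C"), "malformed.*position 1")
})

test_that("monoisotopic mass is additive over formula union", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "S", "P", "Cl")
  for (i in 1:50) {
    pick1 <- sample(els, sample(2:4, 1))
    pick2 <- sample(els, sample(2:4, 1))
    f1 <- paste0(pick1, sample(1:30, length(pick1)), collapse = "")
    f2 <- paste0(pick2, sample(1:30, length(pick2)), collapse = "")
    expect_equal(monoisotopic_mass(paste0(f1, f2)),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-12)
  }
})

test_that("monoisotopic masses reproduce the identification-table values", {
  expect_equal(monoisotopic_mass("H2"), 2.0157, tolerance = 5e-5)
  # the five internally consistent key-compound formulas, within one unit in
  # the last printed digit (the source table mixes rounding and truncation)
  expect_lt(abs(monoisotopic_mass("C30H44O4") - 468.324), 1e-3)  # isoglabrolide
  expect_lt(abs(monoisotopic_mass("C12H18O2") - 194.1307), 1e-4) # neocnidilide
  expect_lt(abs(monoisotopic_mass("C30H46O5") - 486.334), 1e-3)  # glabric acid
  expect_lt(abs(monoisotopic_mass("C30H46O4") - 470.3396), 1e-4) # liquiritic acid
  expect_lt(abs(monoisotopic_mass("C19H18O5") - 326.1154), 1e-4) # erybacin B
})

test_that("adduct labels parse to canonical protonation specs", {
  a <- parse_adduct("(M+H)+")
  expect_equal(a$protons_added, 1L)
  expect_equal(a$charge, 1L)
  expect_length(a$neutral_losses, 0)
  expect_equal(a$label, "(M+H)+")

  b <- parse_adduct("(M+H)^+^ [-H_2_O]")
  expect_equal(b$protons_added, 1L)
  expect_length(b$neutral_losses, 1)
  expect_equal(unclass(b$neutral_losses[[1]]), c(H = 2L, O = 1L))
  expect_equal(b$label, "(M+H)+[-H2O]")

  c2 <- parse_adduct("(M+2H)2+")
  expect_equal(c2$protons_added, 2L)
  expect_equal(c2$charge, 2L)

  expect_error(parse_adduct("(M+Na)+"), "unrecognized adduct")
})

test_that("adduct m/z follows proton and neutral-loss arithmetic", {
  # oracle: hand sums with proton mass 1.00727646 and H2O 18.0105646
  expect_equal(adduct_mz(468.32396, "(M+H)+"), 469.33124, tolerance = 1e-5)
  expect_equal(adduct_mz(194.05791, "(M+H)+[-H2O]"), 177.05462,
               tolerance = 1e-5)
  ident <- structure(list(protons_added = 0L, neutral_losses = list(),
                          charge = 1L, label = "(M)+"),
                     class = "adduct_spec")
  expect_equal(adduct_mz(100.0, ident), 100.0)
  expect_equal(adduct_mz(400, "(M+2H)2+"),
               (400 + 2 * 1.00727646) / 2, tolerance = 1e-9)
  expect_error(adduct_mz(10, "(M+H)+[-C30H44O4]"), "non-positive")
})

test_that("ppm error is the signed relative deviation in parts per million", {
  expect_equal(ppm_error(469.33124, 469.3317), 0.98, tolerance = 0.005)
  expect_equal(ppm_error(195.13796, 195.1372), -3.9, tolerance = 0.01)
  expect_identical(ppm_error(123.456, 123.456), 0)
  expect_error(ppm_error(0, 1), "positive")
  expect_error(ppm_error(-5, 1), "positive")
  # antisymmetric to first order under swapping the arguments
  t0 <- 500.123; m0 <- 500.125
  expect_equal(ppm_error(t0, m0), -ppm_error(m0, t0), tolerance = 1e-4)
})

test_that("mass_table recomputes the identification table end to end", {
  mt <- mass_table(key_compound_table())
  expect_equal(nrow(mt), 7)
  consistent <- c("Isoglabrolide", "Neocnidilide", "Glabric acid",
                  "Liquiritic acid", "Erybacin B")
  for (nm in consistent) {
    row <- mt[mt$name == nm, ]
    digits <- nchar(sub(".*\\.", "", as.character(row$calculated_mz_reported)))
    expect_lt(abs(row$calculated_M - row$calculated_mz_reported), 10^-digits,
              label = nm)
    # theoretical m/z within 1 mDa of the measured ion for a true identity
    expect_lt(abs(row$theoretical_mz - row$measured_mz), 0.002)
  }
})
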