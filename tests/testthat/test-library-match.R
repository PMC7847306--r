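test_that("ppm error is signed, symmetric, and exact at the 5 ppm boundary", {
  expect_identical(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.0005, 100), 5, tolerance = 1e-9)
  expect_equal(ppm_error(99.9995, 100), -5, tolerance = 1e-9)
  # antisymmetry of a fixed offset
  off <- 3.7e-4
  expect_equal(ppm_error(100 + off, 100), -ppm_error(100 - off, 100),
               tolerance = 1e-9)
  expect_error(ppm_error(-1, 100), "positive")
})

test_that("isotope patterns match the exhaustive convolution oracle", {
  # single carbon: M+1/M is the 13C/12C abundance ratio
  expect_equal(isotope_pattern("C", 1)[2], 0.0107 / 0.9893,
               tolerance = 1e-9)
  expect_identical(isotope_pattern("", 2), c(1, 0, 0))
  for (f in c("C6H12O6", "C5H11NO2S", "C10H16N5O13P3", "C2H3Cl",
              "C3H7NO2", "KH2PO4")) {
    expect_equal(isotope_pattern(f, 2), iso_oracle(f, 2), tolerance = 1e-6,
                 info = f)
  }
  expect_error(isotope_pattern("C6Xx2"), "unsupported element")
})

test_that("adduct m/z adds or removes one proton from the neutral mass", {
  # water via summed tabulated monoisotopic masses + proton
  h2o <- 2 * 1.00782503207 + 15.9949146196
  expect_equal(adduct_mz("H2O", "[M+H]+"), h2o + 1.007276, tolerance = 1e-4)
  expect_equal(adduct_mz("C6H12O6", "[M+H]+") - adduct_mz("C6H12O6", "[M-H]-"),
               2 * 1.007276, tolerance = 1e-9)
  expect_error(adduct_mz("", "[M+H]+"), "empty formula")
})

glucose_lib <- function() {
  metabolite_library(data.frame(
    metabolite_id = c("glc", "fru", "ala"),
    name = c("glucose", "fructose", "alanine"),
    formula = c("C6H12O6", "C6H12O6", "C3H7NO2"),
    adduct = "[M+H]+", polarity = "+",
    theoretical_mz = NA_real_,
    retention_time = c(7.2, 7.9, 3.1),
    stringsAsFactors = FALSE
  ))
}

test_that("library entries derive and validate theoretical m/z from formula", {
  lib <- glucose_lib()
  expect_equal(lib$theoretical_mz[1], monoisotopic_mass("C6H12O6") + 1.007276,
               tolerance = 1e-6)
  bad <- data.frame(metabolite_id = "x", name = "x", formula = "C6H12O6",
                    adduct = "[M+H]+", polarity = "+",
                    theoretical_mz = 181.3, retention_time = 1)
  expect_error(metabolite_library(bad), "inconsistent")
})

test_that("feature matching enforces ppm and RT windows and sorts by |ppm|", {
  lib <- glucose_lib()
  mz_glc <- lib$theoretical_mz[1]
  exact <- list(feature_id = "f1", mz = mz_glc, retention_time = 7.2,
                polarity = "+")
  hit <- match_feature(exact, lib)
  expect_identical(hit$metabolite_id[1], "glc")
  expect_true(hit$accepted[1])
  expect_equal(hit$ppm_error[1], 0)

  # 6 ppm off: listed with rejection reason "mass", not accepted
  off6 <- list(feature_id = "f2", mz = mz_glc * (1 + 6e-6),
               retention_time = 7.2, polarity = "+")
  near <- match_feature(off6, lib)
  expect_true("glc" %in% near$metabolite_id)
  row <- near[near$metabolite_id == "glc", ]
  expect_false(row$accepted)
  expect_match(row$rejection_reasons, "mass")

  # boundary inclusive: 5 ppm accepts, just beyond rejects
  at5 <- match_feature(list(mz = mz_glc * (1 + 4.9999e-6),
                            retention_time = 7.2, polarity = "+"), lib)
  expect_true(at5$accepted[at5$metabolite_id == "glc"])
  past5 <- match_feature(list(mz = mz_glc * (1 + 5.001e-6),
                              retention_time = 7.2, polarity = "+"), lib)
  expect_false(past5$accepted[past5$metabolite_id == "glc"])

  # two in-window entries ordered by |ppm error|
  lib2 <- metabolite_library(data.frame(
    metabolite_id = c("near1", "near3"), name = c("a", "b"),
    formula = NA_character_, adduct = "M", polarity = "+",
    theoretical_mz = c(200 / (1 + 1e-6), 200 / (1 + 3e-6)),
    retention_time = 5, stringsAsFactors = FALSE
  ))
  both <- match_feature(list(mz = 200, retention_time = 5, polarity = "+"),
                        lib2)
  expect_identical(both$metabolite_id, c("near1", "near3"))
  expect_true(all(diff(abs(both$ppm_error)) >= 0))

  # polarity mismatch and empty library give empty results
  expect_identical(nrow(match_feature(list(mz = mz_glc, retention_time = 7.2,
                                           polarity = "-"), lib)), 0L)
  expect_identical(nrow(match_feature(exact, lib[0, ])), 0L)
})

test_that("isotope envelope disagreement rejects an otherwise perfect match", {
  lib <- glucose_lib()[1, ]
  good <- match_feature(list(mz = lib$theoretical_mz, retention_time = 7.2,
                             polarity = "+",
                             isotope_envelope = isotope_pattern("C6H12O6")),
                        lib)
  expect_true(good$accepted)
  wrong <- match_feature(list(mz = lib$theoretical_mz, retention_time = 7.2,
                              polarity = "+",
                              isotope_envelope = c(1, 0.9, 0.8)),
                         lib)
  expect_false(wrong$accepted)
  expect_match(wrong$rejection_reasons, "isotope_pattern")
})

test_that("inclusion test requires intensity to rise with cell number", {
  cells <- c(10000, 20000, 30000, 50000, 100000)
  up <- inclusion_test(c(1, 2, 3, 5, 10) * 1e6, cells)
  expect_true(up$pass)

  flat <- inclusion_test(rep(2e6, 5), cells)
  expect_false(flat$pass)
  expect_true("not increasing" %in% flat$reasons)

  # one inversion: Spearman rho = 0.9 still clears the 0.8 threshold
  inv <- inclusion_test(c(1, 3, 2, 5, 10) * 1e6, cells)
  expect_equal(inv$spearman, 0.9, tolerance = 1e-12)
  expect_true(inv$pass)

  # scale invariance of the rank criterion
  expect_identical(inclusion_test(c(1, 3, 2, 5, 10) * 1e2, cells)$pass,
                   inv$pass)

  # misaligned retention times fail even when intensity rises
  drift <- inclusion_test(c(1, 2, 3, 5, 10) * 1e6, cells,
                          retention_time = c(5, 5.1, 5.2, 5.9, 5))
  expect_false(drift$pass)
  expect_true("not aligned" %in% drift$reasons)

  expect_error(inclusion_test(c(1, 2), c(10, 20)), ">= 3")
})

test_that("restricting a high-abundance library keeps detected entries in order", {
  n <- 590L
  lib <- metabolite_library(data.frame(
    metabolite_id = sprintf("met%03d", seq_len(n)),
    name = sprintf("met%03d", seq_len(n)),
    formula = NA_character_, adduct = "M", polarity = "+",
    theoretical_mz = 100 + seq_len(n), retention_time = 1,
    stringsAsFactors = FALSE
  ))
  set.seed(9)
  detected <- sample(lib$metabolite_id, 289L)
  low <- restrict_library(lib, detected)
  expect_identical(nrow(low), 289L)
  expect_identical(low$metabolite_id,
                   lib$metabolite_id[lib$metabolite_id %in% detected])

  expect_identical(nrow(restrict_library(lib, character(0))), 0L)
  expect_identical(restrict_library(lib, lib$metabolite_id)$metabolite_id,
                   lib$metabolite_id)
  expect_warning(restrict_library(lib, c("met001", "unknown")), "not in the library")
})
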