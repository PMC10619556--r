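# Elemental-composition algebra, monoisotopic mass, reaction deltas and
# combinatorial biotransformant enumeration.

test_that("formula parsing handles both dialects and round-trips", {
  expect_identical(parseFormula("C6 H8 O6"), c(C = 6L, H = 8L, O = 6L))
  expect_identical(parseFormula("C6H8O6"), parseFormula("C6 H8 O6"))
  expect_identical(parseFormula("O3 S"), c(O = 3L, S = 1L))
  expect_length(parseFormula(""), 0)
  # omitted count means 1; round trip through formatting is the identity
  for (f in c("C15 H12 I3 N O4", "H2 O", "C10 H15 N3 O6 S", "Cl", "")) {
    expect_identical(parseFormula(formatComposition(parseFormula(f))),
                     parseFormula(f))
  }
  expect_error(parseFormula("C6 Xx8"), "unknown element")
  expect_error(parseFormula("C6:H8"), "position")
})

test_that("signed composition-change strings parse and format", {
  d <- parseCompositionChange("-(H2 Cl2) +(O5 S)")
  expect_identical(d, c(H = -2L, Cl = -2L, O = 5L, S = 1L))
  expect_identical(parseCompositionChange(formatCompositionChange(d)), d)
  expect_identical(parseCompositionChange("+(C6 H8 O6)"),
                   parseFormula("C6 H8 O6"))
  # bare formula is a gain
  expect_identical(parseCompositionChange("O3 S"), c(O = 3L, S = 1L))
  expect_error(parseCompositionChange("+(O3 S) junk"), "unparsed")
})

test_that("monoisotopic mass matches hand-summed isotope values", {
  expect_equal(monoisotopicMass(parseFormula("C6 H8 O6")), 176.03209,
               tolerance = 1e-7)
  expect_equal(monoisotopicMass(c(H = 1L)), 1.007825, tolerance = 1e-6)
  expect_identical(monoisotopicMass(parseFormula("")), 0)
  expect_error(monoisotopicMass(c(C = -1L)), "negative")
})

test_that("mass is additive over composition sums", {
  set.seed(7)
  els <- names(ISOTOPE_MASSES)
  for (i in 1:25) {
    a <- setNames(sample(0:9, 4, replace = TRUE), sample(els, 4))
    b <- setNames(sample(0:9, 4, replace = TRUE), sample(els, 4))
    expect_equal(monoisotopicMass(compositionSum(a, b)),
                 monoisotopicMass(normalizeComposition(a)) +
                   monoisotopicMass(normalizeComposition(b)),
                 tolerance = 1e-10)
  }
})

test_that("net deltas reproduce published composition-change vectors", {
  lib <- defaultTransformations()
  cases <- list(
    list(c("Hydration", "Oxidation", "Reduction", "Methylation"), "+(C H6 O2)"),
    list(c("Oxidation", "Sulfation"), "+(O4 S)"),
    list(c("Hydration", "Nitro Reduction", "Reduction", "Arginine Conjugation"),
         "+(C6 H18 N4)"),
    list(c("Dehydration", "Desaturation", "Oxidative Debromination",
           "Taurine Conjugation"), "-(Br) +(C2 H2 N O2 S)"),
    list(c("Hydration", "Reductive Dechlorination", "Reductive Dechlorination",
           "Deiodination", "Arginine Conjugation"), "-(Cl2 I) +(C6 H17 N4 O2)"),
    list(c("Hydration", "Oxidative Dechlorination", "Deiodination",
           "Palmitoyl Conjugation"), "-(Cl I) +(C16 H34 O3)"),
    list(c("Nitro Reduction", "Nitro Reduction",
           "Oxidative Deamination to Alcohol", "Deiodination", "Deethylation"),
         "-(C2 I N O3)"),
    list(c("Desaturation", "Oxidation", "Oxidative Deamination to Ketone",
           "Arginine Conjugation", "Deethylation"), "+(C4 H3 N3 O3)")
  )
  for (cs in cases) {
    expect_identical(netDelta(cs[[1]], lib), parseCompositionChange(cs[[2]]),
                     label = paste(cs[[1]], collapse = "+"))
  }
  expect_error(netDelta("No Such Reaction", lib), "unknown transformation")
})

test_that("net delta is permutation-invariant", {
  lib <- defaultTransformations()
  set.seed(11)
  for (i in 1:20) {
    steps <- sample(lib$name, sample(2:5, 1), replace = TRUE)
    expect_identical(netDelta(steps, lib), netDelta(sample(steps), lib))
  }
})

test_that("single glucuronidation of bisphenol A gives the conjugate formula", {
  lib <- defaultTransformations()
  gluc <- lib[lib$name == "Glucuronide Conjugation", ]
  out <- enumerateBiotransformants("C15 H16 O2", gluc, maxTotal = 1,
                                   cache = FALSE)
  expect_equal(nrow(out), 1)
  expect_identical(out$formula, "C21 H24 O8")
  expect_equal(out$mass,
               monoisotopicMass(parseFormula("C15 H16 O2")) +
                 monoisotopicMass(parseFormula("C6 H8 O6")),
               tolerance = 1e-9)
  expect_error(enumerateBiotransformants("C15 H16 O2", gluc, maxTotal = 0),
               "maxTotal")
})

test_that("enumeration equals the exhaustive ordered-tuple oracle", {
  lib <- defaultTransformations()
  set.seed(3)
  for (rep in 1:4) {
    sub <- lib[sort(sample(nrow(lib), 4)), ]
    got <- enumerateBiotransformants("C10 H12 N2 O3 Cl", sub, maxTotal = 3,
                                     maxPhase2 = 1, cache = FALSE)
    want <- bruteForceEnumerate("C10 H12 N2 O3 Cl", sub, 3, 1)
    expect_identical(sort(got$formula), want)
  }
  # the phase II cap: with two conjugations available and maxPhase2 = 1,
  # no product carries both
  p2 <- lib[lib$name %in% c("Glucuronide Conjugation", "Sulfation"), ]
  got <- enumerateBiotransformants("C15 H16 O2", p2, maxTotal = 2,
                                   maxPhase2 = 1, cache = FALSE)
  expect_identical(sort(got$formula), sort(c("C21 H24 O8", "C15 H16 O5 S")))
})

test_that("negative-count pruning restricts dehalogenation to halogenated parents", {
  lib <- defaultTransformations()
  deiod <- lib[lib$name == "Deiodination", ]
  expect_equal(nrow(enumerateBiotransformants("C15 H16 O2", deiod,
                                              maxTotal = 1, cache = FALSE)), 0)
  one <- enumerateBiotransformants("C9 H11 I O3", deiod, maxTotal = 2,
                                   cache = FALSE)
  expect_identical(one$formula, "C9 H12 O3")  # a second deiodination is pruned
})

test_that("enumeration output is deterministic and deduplicated", {
  lib <- defaultTransformations()
  a <- enumerateBiotransformants("C15 H12 I3 N O4", lib, maxTotal = 2,
                                 maxPhase2 = 1, cache = FALSE)
  b <- enumerateBiotransformants("C15 H12 I3 N O4", lib, maxTotal = 2,
                                 maxPhase2 = 1, cache = FALSE)
  expect_identical(a, b)
  expect_false(anyDuplicated(a$formula) > 0)
  expect_false(is.unsorted(a$mass))
})

test_that("adduct m/z and ppm error follow the proton-mass arithmetic", {
  expect_equal(expectedMz(176.03209, "M+H"), 177.03937, tolerance = 1e-5)
  expect_equal(expectedMz(176.03209, "M-H"), 175.02481, tolerance = 1e-5)
  expect_error(expectedMz(0, "M+H"), "> 0")
  expect_equal(ppmError(100.0005, 100.0), 5.0)
  expect_equal(ppmError(42.42, 42.42), 0)
  expect_equal(ppmError(177.04026, 177.03937), 5.0, tolerance = 1e-2)
})
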