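# Feature-to-prediction matching, fragment-coverage scoring, merge filter.

predTable <- function(masses, paths = NULL) {
  if (is.null(paths)) paths <- paste0("P", seq_along(masses))
  data.frame(formula = paste0("F", seq_along(masses)), mass = masses,
             mzPos = masses + PROTON_MASS, mzNeg = masses - PROTON_MASS,
             nSteps = 1L, nPhase2 = 0L, path = paths,
             stringsAsFactors = FALSE)
}

test_that("features match predictions inside the ppm gate only", {
  pred <- predTable(400)
  mzIn <- pred$mzPos * (1 + 4e-6)
  mzOut <- pred$mzPos * (1 + 6e-6)
  fs <- makeFeatureSet(armAreas(c("in", "out"), c(1e6, 1e6), c(1e6, 1e6)),
                       mz = c(mzIn, mzOut), rt = c(5, 5))
  ann <- matchFeatures(fs, pred, ms1Ppm = 5)
  expect_identical(ann$feature_id, "in")
  expect_equal(ann$ppm, 4, tolerance = 1e-6)
  expect_false(ann$ambiguous)
})

test_that("isobaric predictions yield multiple flagged annotations", {
  m <- 400
  pred <- predTable(c(m, m * (1 + 2e-6)))  # 2 ppm apart
  fs <- makeFeatureSet(armAreas("X", 1e6, 1e6), mz = m + PROTON_MASS, rt = 5)
  ann <- matchFeatures(fs, pred, ms1Ppm = 5)
  expect_equal(nrow(ann), 2)
  expect_true(all(ann$ambiguous))
  expect_setequal(ann$formula, c("F1", "F2"))
})

test_that("features of one prediction share an RT group within tolerance", {
  pred <- predTable(400)
  mz <- pred$mzPos
  fs <- makeFeatureSet(armAreas(c("a", "b", "c"), rep(1e6, 3), rep(1e6, 3)),
                       mz = rep(mz, 3), rt = c(5.00, 5.05, 7.00))
  ann <- matchFeatures(fs, pred, ms1Ppm = 5, rtTol = 0.1)
  grp <- setNames(ann$rt_group, ann$feature_id)
  expect_identical(grp[["a"]], grp[["b"]])   # within 0.05 min
  expect_false(grp[["a"]] == grp[["c"]])     # 2 min apart
})

test_that("fragment coverage: identity, shifted conjugate, and partial match", {
  parent <- Ms2Spectrum("P", 400, c(100, 150, 200, 250, 300, 350),
                        c(1e5, 2e4, 8e4, 1e4, 5e4, 3e4))
  expect_equal(fishCoverage(parent, parent, integer(0)), 100)

  gluc <- parseCompositionChange("+(C6 H8 O6)")
  shifted <- Ms2Spectrum("S", 400 + deltaMass(gluc),
                         peaks(parent)[, 1] + deltaMass(gluc),
                         peaks(parent)[, 2])
  expect_equal(fishCoverage(shifted, parent, gluc), 100)

  # 3 of 6 equal-intensity centroids match a candidate -> 50%
  half <- Ms2Spectrum("H", 400, c(100, 200, 300, 411.13, 433.77, 455.01),
                      rep(1e4, 6))
  expect_equal(fishCoverage(half, parent, integer(0)), 50)

  # S/N floor: only centroids above snr x median intensity count; here the
  # floor (30) keeps the two strong peaks, of which one matches the parent
  strongWeak <- Ms2Spectrum("W", 400,
                            c(100, 410.5, 101.3, 150.7, 201.3, 250.9, 303.3, 404.4),
                            c(1e5, 1e5, 10, 10, 10, 10, 10, 10))
  expect_equal(fishCoverage(strongWeak, parent, integer(0)), 50)
})

test_that("fragment coverage is scale-invariant and absent without MS2", {
  parent <- Ms2Spectrum("P", 400, c(100, 150, 200, 250, 300, 350),
                        c(1e5, 2e4, 8e4, 1e4, 5e4, 3e4))
  feat <- Ms2Spectrum("F", 400, c(100, 150, 222.2), c(5e4, 9e4, 1e4))
  base <- fishCoverage(feat, parent, integer(0))
  scaledF <- Ms2Spectrum("F", 400, peaks(feat)[, 1], peaks(feat)[, 2] * 1000)
  scaledP <- Ms2Spectrum("P", 400, peaks(parent)[, 1], peaks(parent)[, 2] / 77)
  expect_equal(fishCoverage(scaledF, scaledP, integer(0)), base)
  empty <- Ms2Spectrum("E", 400, numeric(0), numeric(0))
  expect_true(is.na(fishCoverage(empty, parent, integer(0))))
})

test_that("composite paths add partial-sum fragment shifts", {
  parent <- Ms2Spectrum("P", 400, c(100, 200, 300), c(1e4, 1e4, 1e4))
  ox <- parseCompositionChange("+(O)")
  gluc <- parseCompositionChange("+(C6 H8 O6)")
  both <- compositionSum(ox, gluc)
  # fragments shifted by the oxidation-only partial sum are explained only
  # when the step list is supplied
  feat <- Ms2Spectrum("F", 400 + deltaMass(both),
                      peaks(parent)[, 1] + deltaMass(ox),
                      c(1e4, 1e4, 1e4))
  expect_equal(fishCoverage(feat, parent, both), 0)
  expect_equal(fishCoverage(feat, parent, both, steps = list(ox, gluc)), 100)
})

test_that("merge filter keeps annotations by area OR coverage", {
  fs <- makeFeatureSet(armAreas(c("big", "cov", "weak"),
                                c(2e5, 1e4, 1e4), c(1e5, 1e4, 1e4)),
                       mz = c(300, 301, 302))
  ann <- data.frame(feature_id = c("big", "cov", "weak"),
                    formula = "F", path = "P",
                    fish_coverage = c(NA, 60, 20),
                    stringsAsFactors = FALSE)
  out <- filterAnnotations(ann, fs)
  expect_setequal(out$feature_id, c("big", "cov"))
  expect_true(out$pass_area[out$feature_id == "big"])
  expect_false(out$pass_fish[out$feature_id == "big"])
  expect_true(out$pass_fish[out$feature_id == "cov"])
  expect_true(all(out$passed_filter))
})

test_that("planted features annotate and distant decoys never do", {
  set.seed(19)
  lib <- defaultTransformations()
  sim <- simulateExperiment(simConfig(seed = 19, maxTotal = 2))
  pred <- enumerateBiotransformants("C15 H12 I3 N O4", lib,
                                    maxTotal = 2, maxPhase2 = 1,
                                    includeParent = TRUE)
  ann <- matchFeatures(imputeMissing(sim$features), pred)
  planted <- sim$truth$planted
  hit <- vapply(seq_len(nrow(planted)), function(k) {
    any(ann$feature_id == planted$feature_id[k] &
          ann$formula == planted$formula[k])
  }, logical(1))
  expect_true(all(hit[planted$detected]))
  expect_equal(sum(ann$feature_id %in% sim$truth$decoys), 0)
})
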