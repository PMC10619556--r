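## Synthetic-experiment generator: control-vs-reaction feature tables with
## planted biotransformants, shifted-fragment MS2 spectra, decoy features,
## and saturating dose-response assay plates -- all with known ground truth.

#' Default planted reaction paths
#'
#' The conjugation/functionalization mix that dominates thyroid-hormone-like
#' biotransformation profiles: glucuronidation, sulfation,
#' oxidation-glucuronidation, deiodination and glutathione conjugation.
#'
#' @return List of character vectors of transformation names.
#' @export
defaultPlantedPaths <- function() {
  list(
    c("Glucuronide Conjugation"),
    c("Sulfation"),
    c("Oxidation", "Glucuronide Conjugation"),
    c("Deiodination"),
    c("GSH Conjugation")
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic experiment. Defaults emulate the
#' study design this generator stands in for: a triiodothyronine-like parent
#' (\code{C15 H12 I3 N O4}), n = 3 replicates per arm, log-normal
#' multiplicative area noise with CV 0.2, planted biotransformants at
#' |log2 fold change| >= 2, 50 unrelated decoy features, 12-peak MS2
#' spectra with 3 noise fragments, positive ionization, and a five-dose
#' saturating activity profile whose top-dose activity is largest in the
#' phase I+II arm.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param parentFormula Parent elemental formula string.
#' @param plantedPaths List of reaction paths (character vectors of
#'   transformation names); each is planted as one transformant feature.
#' @param plantedLog2fc Numeric vector (recycled) of true log2 fold changes
#'   reaction/control for the planted features.
#' @param detectProb Probability each planted transformant is detected at
#'   all (default 1).
#' @param nReplicates Replicates per arm (default 3).
#' @param noiseCv Coefficient of variation of the multiplicative log-normal
#'   area noise (default 0.2).
#' @param nDecoys Number of decoy features (default 50), each >= 20 ppm from
#'   every predicted biotransformant m/z.
#' @param decoyMzRange m/z range the decoys are drawn from.
#' @param ms2Peaks Fragments per spectrum (default 12).
#' @param fragNoisePeaks Extra random fragments added to transformant
#'   spectra (default 3).
#' @param baseArea Median control-arm area of planted features and parent.
#' @param metabolicRate True percent depletion of the parent in the
#'   reaction arm (default 3, a weakly metabolized parent).
#' @param ppmJitter Planted features are placed at the predicted m/z
#'   perturbed uniformly within +/- this many ppm (default 3, inside the
#'   5 ppm gate); set 6-10 for near-miss negative controls.
#' @param polarity Ionization mode (default \code{"pos"}).
#' @param doses Dose grid (molar) for the assay plate.
#' @param ec50 Dose of half-maximal activity for the saturating response.
#' @param trueActivity Named vector of true top-dose activities (% of PC)
#'   per arm.
#' @param plateNoiseSd Gaussian luminescence noise, as a fraction of the
#'   PC - VC window (default 0.02).
#' @param maxTotal,maxPhase2 Enumeration depth limits used to build the
#'   decoy exclusion list (workflow defaults 5 and 1).
#' @param library Transformation library.
#' @return A \code{simConfig} list.
#' @export
simConfig <- function(seed = 1,
                      parentFormula = "C15 H12 I3 N O4",
                      plantedPaths = defaultPlantedPaths(),
                      plantedLog2fc = c(3, 2.5, 2.2, 2, 2),
                      detectProb = 1,
                      nReplicates = 3,
                      noiseCv = 0.2,
                      nDecoys = 50,
                      decoyMzRange = c(100, 1000),
                      ms2Peaks = 12,
                      fragNoisePeaks = 3,
                      baseArea = 1e6,
                      metabolicRate = 3,
                      ppmJitter = 3,
                      polarity = c("pos", "neg"),
                      doses = c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5),
                      ec50 = 1e-8,
                      trueActivity = c(parent = 100, inactive_s9 = 100,
                                       phase1 = 150, phase1_2 = 309.1),
                      plateNoiseSd = 0.02,
                      maxTotal = 5, maxPhase2 = 1,
                      library = defaultTransformations()) {
  polarity <- match.arg(polarity)
  stopifnot(detectProb >= 0, detectProb <= 1, nReplicates >= 1,
            noiseCv >= 0, nDecoys >= 0)
  cfg <- list(seed = as.integer(seed), parentFormula = parentFormula,
              plantedPaths = plantedPaths,
              plantedLog2fc = rep_len(plantedLog2fc, length(plantedPaths)),
              detectProb = detectProb, nReplicates = nReplicates,
              noiseCv = noiseCv, nDecoys = nDecoys,
              decoyMzRange = decoyMzRange, ms2Peaks = ms2Peaks,
              fragNoisePeaks = fragNoisePeaks, baseArea = baseArea,
              metabolicRate = metabolicRate, ppmJitter = ppmJitter,
              polarity = polarity, doses = doses, ec50 = ec50,
              trueActivity = trueActivity, plateNoiseSd = plateNoiseSd,
              maxTotal = maxTotal, maxPhase2 = maxPhase2, library = library)
  # planted paths must respect the enumeration depth limits
  for (p in plantedPaths) {
    idx <- match(p, library$name)
    if (anyNA(idx)) stop("planted path uses unknown transformation(s): ",
                         paste(p[is.na(idx)], collapse = ", "))
    if (length(p) > maxTotal) {
      stop("planted path exceeds maxTotal steps: ", paste(p, collapse = ", "))
    }
    if (sum(library$phase[idx] == "phase2") > maxPhase2) {
      stop("planted path exceeds maxPhase2 conjugations: ",
           paste(p, collapse = ", "))
    }
  }
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a complete synthetic experiment
#'
#' Generates, under one seed: (i) a control-vs-reaction feature table with
#' the parent, the planted biotransformants (at their predicted adduct m/z
#' perturbed within \code{ppmJitter} ppm, reaction-arm areas scaled by
#' \code{2^log2fc}) and decoy features placed >= 20 ppm from every predicted
#' m/z; (ii) MS2 spectra in which each transformant spectrum is the parent
#' spectrum shifted by the net reaction-delta mass plus random noise
#' fragments; (iii) an assay plate with a saturating dose-response per arm;
#' and (iv) the ground truth needed to score recovery.
#'
#' @param config A \code{\link{simConfig}}.
#' @param outDir Optional directory; when given, the feature table
#'   (\code{features.csv}), spectra (\code{spectra.mgf}) and plate
#'   (\code{plate.csv}) are also written there.
#' @return List with \code{features} (\code{MsFeatureSet}), \code{spectra}
#'   (named list of \code{Ms2Spectrum}), \code{plate} (\code{data.frame}),
#'   \code{truth} (list: \code{planted} data.frame of feature id, path,
#'   formula, true m/z, log2fc, detected; \code{decoys} feature ids;
#'   \code{parent} feature id; \code{trueActivity}; \code{metabolicRate}),
#'   and \code{config}.
#' @export
simulateExperiment <- function(config = simConfig(), outDir = NULL) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  lib <- config$library
  parent <- parseFormula(config$parentFormula)
  parentMass <- monoisotopicMass(parent)
  adduct <- if (config$polarity == "pos") "M+H" else "M-H"
  parentMzTheo <- expectedMz(parentMass, adduct)
  nRep <- config$nReplicates
  sampleIds <- c(paste0("control_", seq_len(nRep)),
                 paste0("reaction_", seq_len(nRep)))
  arms <- rep(c("control", "reaction"), each = nRep)
  sdlog <- sqrt(log(1 + config$noiseCv^2))
  lnoise <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  # planted transformants
  nP <- length(config$plantedPaths)
  planted <- data.frame(
    feature_id = if (nP) paste0("T", seq_len(nP)) else character(0),
    path = vapply(config$plantedPaths, function(p) paste(sort(p), collapse = ", "),
                  character(1)),
    stringsAsFactors = FALSE
  )
  if (nP == 0) {
    planted$formula <- character(0)
    planted$delta_mass <- numeric(0)
    planted$mz_theo <- numeric(0)
    planted$log2fc <- numeric(0)
    planted$detected <- logical(0)
    planted$mz_obs <- numeric(0)
  }
  if (nP) {
    deltas <- lapply(config$plantedPaths, netDelta, library = lib)
    prods <- lapply(deltas, function(d) compositionSum(parent, d))
    bad <- vapply(prods, function(p) any(p < 0), logical(1))
    if (any(bad)) stop("planted path gives negative element counts for this parent")
    planted$formula <- vapply(prods, formatComposition, character(1))
    planted$delta_mass <- vapply(deltas, deltaMass, numeric(1))
    planted$mz_theo <- vapply(prods, function(p) {
      expectedMz(monoisotopicMass(p), adduct)
    }, numeric(1))
    planted$log2fc <- config$plantedLog2fc
    planted$detected <- stats::runif(nP) <= config$detectProb
    planted$mz_obs <- planted$mz_theo *
      (1 + stats::runif(nP, -config$ppmJitter, config$ppmJitter) * 1e-6)
  }

  # decoys: rejection-sample m/z at >= 20 ppm from every predicted adduct m/z
  predictions <- enumerateBiotransformants(parent, lib, config$maxTotal,
                                           config$maxPhase2,
                                           includeParent = TRUE)
  predMz <- if (config$polarity == "pos") predictions$mzPos else predictions$mzNeg
  drawDecoy <- function() {
    repeat {
      m <- stats::runif(1, config$decoyMzRange[1], config$decoyMzRange[2])
      if (all(ppmError(m, predMz) >= 20)) return(m)
    }
  }
  decoyMz <- if (config$nDecoys) {
    vapply(seq_len(config$nDecoys), function(i) drawDecoy(), numeric(1))
  } else numeric(0)
  decoyIds <- if (config$nDecoys) paste0("D", seq_len(config$nDecoys)) else character(0)

  # areas: parent depleted by metabolicRate in the reaction arm; planted
  # transformants scaled by 2^log2fc; decoys null
  mkAreas <- function(ctrlMean, rxnMean) {
    c(ctrlMean * lnoise(nRep), rxnMean * lnoise(nRep))
  }
  ids <- c("PARENT", planted$feature_id[planted$detected], decoyIds)
  mzs <- c(parentMzTheo * (1 + stats::runif(1, -config$ppmJitter, config$ppmJitter) * 1e-6),
           planted$mz_obs[planted$detected], decoyMz)
  rts <- stats::runif(length(ids), 1, 20)
  area <- matrix(NA_real_, length(ids), 2 * nRep,
                 dimnames = list(ids, sampleIds))
  area["PARENT", ] <- mkAreas(config$baseArea,
                              config$baseArea * (1 - config$metabolicRate / 100))
  for (k in which(planted$detected)) {
    base <- config$baseArea / 2
    area[planted$feature_id[k], ] <- mkAreas(base, base * 2^planted$log2fc[k])
  }
  for (d in decoyIds) {
    base <- config$baseArea * stats::runif(1, 0.2, 2)
    area[d, ] <- mkAreas(base, base)
  }
  features <- MsFeatureSet(area, mz = mzs, rt = rts, arm = arms,
                           replicate = rep(seq_len(nRep), 2),
                           polarity = config$polarity)

  # MS2: parent fragments at fixed fractions of the precursor; transformant
  # spectra are the parent fragments shifted by the net delta mass
  nPk <- config$ms2Peaks
  parentFragMz <- sort(stats::runif(nPk, 60, parentMzTheo - 10))
  parentFragInt <- stats::rlnorm(nPk, log(1e4), 1)
  spectra <- list()
  spectra[["PARENT"]] <- Ms2Spectrum("PARENT", mzs[1], parentFragMz, parentFragInt)
  for (k in which(planted$detected)) {
    fid <- planted$feature_id[k]
    mzF <- parentFragMz + planted$delta_mass[k]
    keep <- mzF > 50
    intF <- parentFragInt[keep] * lnoise(sum(keep))
    mzF <- mzF[keep]
    if (config$fragNoisePeaks > 0) {
      mzF <- c(mzF, stats::runif(config$fragNoisePeaks, 60, planted$mz_obs[k] - 10))
      intF <- c(intF, stats::rlnorm(config$fragNoisePeaks, log(2e3), 0.5))
    }
    spectra[[fid]] <- Ms2Spectrum(fid, planted$mz_obs[k], mzF, intF)
  }
  for (i in seq_along(decoyIds)) {
    fid <- decoyIds[i]
    mzD <- sort(stats::runif(nPk, 60, max(decoyMz[i] - 10, 70)))
    spectra[[fid]] <- Ms2Spectrum(fid, decoyMz[i], mzD,
                                  stats::rlnorm(nPk, log(1e4), 1))
  }

  plate <- .simulatePlate(config)

  truth <- list(planted = planted, decoys = decoyIds, parent = "PARENT",
                trueActivity = config$trueActivity,
                metabolicRate = config$metabolicRate)
  out <- list(features = features, spectra = spectra, plate = plate,
              truth = truth, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(features, file.path(outDir, "features.csv"))
    writeMgf(spectra, file.path(outDir, "spectra.mgf"))
    utils::write.csv(plate, file.path(outDir, "plate.csv"), row.names = FALSE)
    out$paths <- list(features = file.path(outDir, "features.csv"),
                      spectra = file.path(outDir, "spectra.mgf"),
                      plate = file.path(outDir, "plate.csv"))
  }
  out
}

# luminescence = VC + activity% x (PC - VC) x dose saturation + noise
.simulatePlate <- function(config) {
  pcLum <- 10000; vcLum <- 1000
  window <- pcLum - vcLum
  noise <- function(n) stats::rnorm(n, 0, config$plateNoiseSd * window)
  nRep <- config$nReplicates
  rows <- list(
    data.frame(well_id = paste0("PC_", seq_len(nRep)), role = "PC",
               arm = NA_character_, compound = "PC", dose_molar = 1e-7,
               luminescence = pcLum + noise(nRep), replicate = seq_len(nRep)),
    data.frame(well_id = paste0("VC_", seq_len(nRep)), role = "VC_control",
               arm = NA_character_, compound = "VC", dose_molar = 0,
               luminescence = vcLum + noise(nRep), replicate = seq_len(nRep))
  )
  sat <- function(dose) dose / (dose + config$ec50)
  topSat <- sat(max(config$doses))
  for (arm in names(config$trueActivity)) {
    rows[[length(rows) + 1]] <-
      data.frame(well_id = paste0("VCt_", arm, "_", seq_len(nRep)),
                 role = "VC_test", arm = arm, compound = "TEST",
                 dose_molar = 0, luminescence = vcLum + noise(nRep),
                 replicate = seq_len(nRep))
    for (dose in config$doses) {
      act <- config$trueActivity[[arm]] * sat(dose) / topSat
      lum <- vcLum + act / 100 * window
      rows[[length(rows) + 1]] <-
        data.frame(well_id = paste0(arm, "_", format(dose, scientific = TRUE),
                                    "_", seq_len(nRep)),
                   role = "test", arm = arm, compound = "TEST",
                   dose_molar = dose, luminescence = pmax(lum + noise(nRep), 0),
                   replicate = seq_len(nRep))
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  assayPlate(plate)
}
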