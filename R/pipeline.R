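## End-to-end orchestration: predict -> annotate -> filter -> network ->
## subnetwork-annotate -> stats -> assay -> verdicts, with a flat config and
## a reproducible run manifest.

#' Default pipeline parameters
#'
#' The workflow defaults: 5 ppm MS1 tolerance, 0.1 min RT tolerance, 10 ppm
#' MS2 tolerance with S/N 3 for fragment-coverage scoring, 0.05 Da
#' networking fragment tolerance, cosine > 0.5 with >= 6 matched ions,
#' 500 m/z maximum precursor shift, 10 neighbors maximum, 1e5 area / 50%
#' coverage merge filter, alpha 0.05, 10% agonist threshold, and at most 5
#' total reactions with at most 1 phase II conjugation.
#'
#' @return Named list of parameter defaults.
#' @export
defaultParams <- function() {
  list(ms1_ppm = 5, rt_tol = 0.1, ms2_ppm = 10, snr = 3, frag_tol = 0.05,
       min_cosine = 0.5, min_matched = 6, max_shift = 500, top_k = 10,
       min_area = 1e5, min_fish = 50, alpha = 0.05, rta_threshold = 10,
       max_total = 5, max_phase2 = 1, impute_fraction = 0.10)
}

#' Run the full evaluation workflow
#'
#' Executes the complete pipeline on a feature table, MS2 spectra, and an
#' assay plate: biotransformant prediction for the parent formula, missing
#' value imputation, feature-to-prediction matching with fragment-coverage
#' scoring, the area/coverage merge filter, molecular networking with
#' annotation of the parent subnetwork, per-feature fold-change/volcano
#' statistics and parent metabolic rate, and reporter-assay normalization
#' with agonist verdicts. When \code{outDir} is given, all result tables, a
#' GraphML network and a JSON manifest of the resolved parameters are
#' written there.
#'
#' @param features \code{\linkS4class{MsFeatureSet}} or path to a feature
#'   CSV.
#' @param spectra Named list of \code{\linkS4class{Ms2Spectrum}} or an MGF
#'   path.
#' @param plate Plate \code{data.frame} or CSV path (optional; \code{NULL}
#'   skips the assay stage).
#' @param parentFormula Parent compound elemental formula.
#' @param parentFeatureId Feature id of the parent in the feature table
#'   (default \code{"PARENT"}).
#' @param params Named list overriding entries of
#'   \code{\link{defaultParams}}.
#' @param library Transformation library.
#' @param statsMethod,statsContinuity Passed to \code{\link{featureStats}}.
#' @param outDir Optional output directory.
#' @return List with \code{predictions}, \code{annotations} (filtered, with
#'   coverage), \code{network}, \code{componentSummary}, \code{subnetwork},
#'   \code{stats}, \code{volcano}, \code{metabolicRate}, \code{rta},
#'   \code{verdicts}, \code{manifest}.
#' @export
runPipeline <- function(features, spectra, plate = NULL, parentFormula,
                        parentFeatureId = "PARENT", params = list(),
                        library = defaultTransformations(),
                        statsMethod = "auto", statsContinuity = TRUE,
                        outDir = NULL) {
  p <- utils::modifyList(defaultParams(), params)
  if (is.character(features)) features <- readFeatureTable(features)
  if (is.character(spectra)) spectra <- readMgf(spectra)
  if (is.character(plate)) plate <- readPlate(plate)

  ## 1. predict
  predictions <- enumerateBiotransformants(parentFormula, library,
                                           maxTotal = p$max_total,
                                           maxPhase2 = p$max_phase2,
                                           includeParent = TRUE)
  ## 2. impute
  features <- imputeMissing(features, fraction = p$impute_fraction)

  ## 3. annotate + coverage
  annotations <- matchFeatures(features, predictions,
                               ms1Ppm = p$ms1_ppm, rtTol = p$rt_tol)
  parentMs2 <- spectra[[parentFeatureId]]
  parentComp <- parseFormula(parentFormula)
  annotations$fish_coverage <- vapply(seq_len(nrow(annotations)), function(i) {
    sp <- spectra[[annotations$feature_id[i]]]
    if (is.null(sp) || is.null(parentMs2)) return(NA_real_)
    delta <- compositionSum(parseFormula(annotations$formula[i]),
                            -parentComp)
    fishCoverage(sp, parentMs2, delta, ms2Ppm = p$ms2_ppm, snr = p$snr)
  }, numeric(1))

  ## 4. filter
  annotations <- filterAnnotations(annotations, features,
                                   minArea = p$min_area, minFish = p$min_fish)

  ## 5. network + 6. subnetwork annotation
  network <- buildNetwork(spectra, minCosine = p$min_cosine,
                          minMatched = p$min_matched,
                          maxShift = p$max_shift, topK = p$top_k,
                          fragTol = p$frag_tol)
  subnetwork <- NULL
  if (parentFeatureId %in% networkNodes(network)$feature_id) {
    subnetwork <- annotateSubnetwork(network, parentFeatureId, predictions,
                                     ms1Ppm = p$ms1_ppm,
                                     polarity = samplePolarity(features))
  }

  ## 7. stats
  statsTab <- featureStats(features, alpha = p$alpha, method = statsMethod,
                           continuity = statsContinuity)
  volcano <- volcanoTable(statsTab, alpha = p$alpha)
  mrate <- if (parentFeatureId %in% featureIds(features)) {
    metabolicRate(featureAreas(features)[parentFeatureId, ],
                  sampleArms(features))
  } else NA_real_

  compSummary <- {
    nodes <- networkNodes(network)
    nodes$annotated <- nodes$feature_id %in% annotations$feature_id
    nodes$log2fc <- statsTab$log2fc[match(nodes$feature_id,
                                          statsTab$feature_id)]
    net2 <- network
    net2@nodes <- nodes
    componentSummary(net2, minSize = 10)
  }

  ## 8. assay
  rtaTab <- NULL; verdicts <- NULL
  if (!is.null(plate)) {
    rtaTab <- rta(plate)
    verdicts <- callAgonist(rtaTab, threshold = p$rta_threshold)
  }

  manifest <- list(parent_formula = parentFormula,
                   parent_feature_id = parentFeatureId,
                   polarity = samplePolarity(features),
                   n_features = nrow(features),
                   n_spectra = length(spectra),
                   params = p)

  result <- list(predictions = predictions, annotations = annotations,
                 network = network, componentSummary = compSummary,
                 subnetwork = subnetwork, stats = statsTab,
                 volcano = volcano, metabolicRate = mrate,
                 rta = rtaTab, verdicts = verdicts, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAnnotations(annotations, file.path(outDir, "annotations.csv"))
    writeStats(statsTab, file.path(outDir, "stats.csv"))
    utils::write.csv(compSummary, file.path(outDir, "component_summary.csv"),
                     row.names = FALSE)
    nd <- data.frame(feature_id = statsTab$feature_id,
                     log2fc = statsTab$log2fc, p_value = statsTab$p,
                     significant = statsTab$significant,
                     annotated = statsTab$feature_id %in% annotations$feature_id)
    writeNetwork(network, file.path(outDir, "network.graphml"),
                 format = "graphml", nodeData = nd)
    writeNetwork(network, file.path(outDir, "edges.tsv"), format = "tsv")
    if (!is.null(subnetwork)) {
      utils::write.csv(subnetwork, file.path(outDir, "subnetwork.csv"),
                       row.names = FALSE)
    }
    if (!is.null(verdicts)) {
      utils::write.csv(rtaTab, file.path(outDir, "rta.csv"), row.names = FALSE)
      utils::write.csv(verdicts, file.path(outDir, "verdicts.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
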