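## Matching detected features to predicted biotransformants, FISh-style
## fragment-coverage scoring, and the area/coverage merge filter.

#' Match features to predicted biotransformants
#'
#' Pairs every feature whose m/z lies within \code{ms1Ppm} of a prediction's
#' adduct m/z (\code{mzPos} for positive runs, \code{mzNeg} for negative)
#' with that prediction. A feature may match several isobaric predictions;
#' the ambiguity is preserved and flagged. Features matching the same
#' prediction within \code{rtTol} minutes of each other share an
#' \code{rt_group}.
#'
#' @param x Features (\code{\linkS4class{MsFeatureSet}}).
#' @param predictions Prediction table from
#'   \code{\link{enumerateBiotransformants}}.
#' @param ms1Ppm MS1 mass tolerance in ppm (default 5).
#' @param rtTol RT grouping tolerance in minutes (default 0.1).
#' @return \code{data.frame} of annotations: \code{feature_id}, \code{mz},
#'   \code{rt}, \code{formula}, \code{path}, \code{nSteps}, \code{adduct},
#'   \code{ppm}, \code{rt_group}, \code{ambiguous}.
#' @export
matchFeatures <- function(x, predictions, ms1Ppm = 5, rtTol = 0.1) {
  stopifnot(ms1Ppm > 0, rtTol > 0)
  pol <- samplePolarity(x)
  if (is.null(pol) || !pol %in% c("pos", "neg")) {
    stop("feature set polarity must be 'pos' or 'neg'")
  }
  predMz <- if (pol == "pos") predictions$mzPos else predictions$mzNeg
  adduct <- if (pol == "pos") "M+H" else "M-H"
  fmz <- featureMz(x); frt <- featureRt(x)
  # ppm window around each predicted m/z (tolerance scales with the
  # theoretical m/z, so the matrix is built column-wise)
  tolM <- matrix(ms1Ppm * 1e-6 * predMz, nrow = length(fmz),
                 ncol = length(predMz), byrow = TRUE)
  hits <- which(abs(outer(fmz, predMz, "-")) <= tolM, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), formula = character(0),
                      path = character(0), nSteps = integer(0),
                      adduct = character(0), ppm = numeric(0),
                      rt_group = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  ann <- data.frame(
    feature_id = names(fmz)[hits[, 1]],
    mz = unname(fmz[hits[, 1]]),
    rt = unname(frt[hits[, 1]]),
    formula = predictions$formula[hits[, 2]],
    path = predictions$path[hits[, 2]],
    nSteps = predictions$nSteps[hits[, 2]],
    adduct = adduct,
    ppm = ppmError(fmz[hits[, 1]], predMz[hits[, 2]]),
    stringsAsFactors = FALSE
  )
  nMatch <- tapply(ann$formula, ann$feature_id, function(f) length(unique(f)))
  ann$ambiguous <- unname(nMatch[ann$feature_id] > 1)
  # RT groups: per prediction, single-linkage clustering of feature RTs with
  # gaps > rtTol splitting groups
  ann$rt_group <- NA_character_
  for (f in unique(ann$formula)) {
    sel <- which(ann$formula == f)
    ord <- sel[order(ann$rt[sel], ann$feature_id[sel])]
    grp <- cumsum(c(1, diff(ann$rt[ord]) > rtTol))
    ann$rt_group[ord] <- paste0(f, "#", grp)
  }
  ann <- ann[order(ann$feature_id, ann$ppm, ann$formula), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Fragment-coverage (FISh-style) score
#'
#' Scores how much of a biotransformant's MS2 spectrum is explainable from
#' the parent's MS2 spectrum under a shifted-fragment model: candidate
#' fragment m/z values are the parent peaks plus each parent peak shifted by
#' the reaction-delta mass (and, for multi-step paths supplied via
#' \code{steps}, by each cumulative partial-sum shift). Coverage is the
#' percentage of feature centroids above the signal-to-noise floor that
#' match any candidate within \code{ms2Ppm}. The S/N floor is \code{snr}
#' times the median centroid intensity of the feature spectrum; if no
#' centroid clears the floor (flat spectra), all centroids are scored.
#'
#' @param featureMs2 \code{Ms2Spectrum} of the candidate biotransformant.
#' @param parentMs2 \code{Ms2Spectrum} of the parent compound.
#' @param delta Signed composition delta (vector or delta string) between
#'   parent and candidate; the empty delta scores the spectrum against the
#'   parent peaks alone.
#' @param ms2Ppm MS2 mass tolerance in ppm (default 10).
#' @param snr Signal-to-noise threshold (default 3).
#' @param steps Optional list of per-step signed deltas; adds the partial-sum
#'   shifts of the path to the candidate set.
#' @return Coverage percentage in [0, 100], or \code{NA} if either spectrum
#'   is empty (a feature without MS2 has no score, not a zero score).
#' @export
fishCoverage <- function(featureMs2, parentMs2, delta, ms2Ppm = 10, snr = 3,
                         steps = NULL) {
  fp <- peaks(featureMs2); pp <- peaks(parentMs2)
  if (nrow(fp) == 0 || nrow(pp) == 0) return(NA_real_)
  if (is.character(delta)) delta <- parseCompositionChange(delta)
  shifts <- deltaMass(delta)
  if (!is.null(steps)) {
    stepMass <- vapply(steps, function(s) {
      if (is.character(s)) s <- parseCompositionChange(s)
      deltaMass(s)
    }, numeric(1))
    shifts <- c(shifts, cumsum(stepMass))
  }
  shifts <- unique(c(0, shifts))
  candidates <- sort(unique(as.vector(outer(pp[, 1], shifts, "+"))))
  candidates <- candidates[candidates > 0]

  floorInt <- snr * stats::median(fp[, 2])
  keep <- fp[, 2] > floorInt
  if (!any(keep)) keep <- rep(TRUE, nrow(fp))  # degenerate flat spectrum
  mzv <- fp[keep, 1]
  matched <- vapply(mzv, function(m) {
    any(abs(m - candidates) <= ms2Ppm * 1e-6 * m)
  }, logical(1))
  100 * sum(matched) / length(matched)
}

#' Filter annotations by peak area or fragment coverage
#'
#' Keeps an annotation iff its feature's maximum per-sample area reaches
#' \code{minArea} (default 1e5) OR its fragment-coverage score reaches
#' \code{minFish} (default 50 percent). Both criteria are recorded per
#' annotation (\code{pass_area}, \code{pass_fish}) for auditability; an
#' absent coverage score fails the coverage criterion without failing the
#' annotation when the area criterion holds.
#'
#' @param annotations Annotation \code{data.frame} from
#'   \code{\link{matchFeatures}}, optionally with a \code{fish_coverage}
#'   column.
#' @param x The \code{MsFeatureSet} the annotations refer to.
#' @param minArea Minimum maximum-per-sample area (default \code{1e5}).
#' @param minFish Minimum coverage percentage (default 50).
#' @return The filtered annotations with columns \code{max_area},
#'   \code{pass_area}, \code{pass_fish}, \code{passed_filter} added
#'   (\code{passed_filter} is TRUE for every retained row).
#' @export
filterAnnotations <- function(annotations, x, minArea = 1e5, minFish = 50) {
  if (nrow(annotations) == 0) {
    annotations$max_area <- numeric(0)
    annotations$pass_area <- logical(0)
    annotations$pass_fish <- logical(0)
    annotations$passed_filter <- logical(0)
    return(annotations)
  }
  a <- featureAreas(x)
  maxArea <- apply(a, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  annotations$max_area <- unname(maxArea[annotations$feature_id])
  annotations$pass_area <- !is.na(annotations$max_area) &
    annotations$max_area >= minArea
  fc <- if ("fish_coverage" %in% colnames(annotations)) {
    annotations$fish_coverage
  } else rep(NA_real_, nrow(annotations))
  annotations$pass_fish <- !is.na(fc) & fc >= minFish
  annotations$passed_filter <- annotations$pass_area | annotations$pass_fish
  out <- annotations[annotations$passed_filter, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotations to CSV
#'
#' @param annotations Annotation \code{data.frame}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, na = "")
  invisible(path)
}
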