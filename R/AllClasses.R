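#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assay<- rowData colData rowData<- colData<-
NULL

## ---------------------------------------------------------------------------
## Ms2Spectrum
## ---------------------------------------------------------------------------

#' MS2 spectrum of an LC-MS feature
#'
#' Centroided fragment list keyed by the feature it belongs to. Peaks are
#' kept sorted by m/z with strictly positive intensities.
#'
#' @slot featureId Feature identifier (character scalar).
#' @slot precursorMz Precursor m/z.
#' @slot charge Integer charge (sign by polarity convention; 1 by default).
#' @slot peaks Two-column numeric matrix (\code{mz}, \code{intensity}).
#'
#' @export
setClass("Ms2Spectrum",
  representation(featureId = "character", precursorMz = "numeric",
                 charge = "integer", peaks = "matrix"))

setValidity("Ms2Spectrum", function(object) {
  msg <- character(0)
  if (length(object@featureId) != 1) msg <- c(msg, "featureId must be a scalar")
  if (length(object@precursorMz) != 1 || object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a positive scalar")
  p <- object@peaks
  if (ncol(p) != 2) msg <- c(msg, "peaks must have columns mz, intensity")
  if (nrow(p) > 0) {
    if (is.unsorted(p[, 1])) msg <- c(msg, "peaks must be sorted ascending by m/z")
    if (any(p[, 2] <= 0)) msg <- c(msg, "peak intensities must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Ms2Spectrum
#'
#' @param featureId Feature identifier.
#' @param precursorMz Precursor m/z (> 0).
#' @param mz,intensity Numeric vectors of equal length; peaks are sorted by
#'   m/z on construction.
#' @param charge Charge state (default 1).
#' @return An \code{\linkS4class{Ms2Spectrum}}.
#' @export
Ms2Spectrum <- function(featureId, precursorMz, mz, intensity, charge = 1L) {
  stopifnot(length(mz) == length(intensity))
  ord <- order(mz)
  peaks <- cbind(mz = as.numeric(mz)[ord], intensity = as.numeric(intensity)[ord])
  new("Ms2Spectrum", featureId = as.character(featureId),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      peaks = peaks)
}

#' @rdname Ms2Spectrum-class
#' @param x An \code{Ms2Spectrum}.
#' @export
setGeneric("featureId", function(x) standardGeneric("featureId"))
#' @rdname Ms2Spectrum-class
#' @export
setMethod("featureId", "Ms2Spectrum", function(x) x@featureId)

#' @rdname Ms2Spectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname Ms2Spectrum-class
#' @export
setMethod("precursorMz", "Ms2Spectrum", function(x) x@precursorMz)

#' @rdname Ms2Spectrum-class
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname Ms2Spectrum-class
#' @export
setMethod("peaks", "Ms2Spectrum", function(x) x@peaks)

setMethod("show", "Ms2Spectrum", function(object) {
  cat("Ms2Spectrum '", object@featureId, "': precursor m/z ",
      format(object@precursorMz, digits = 8), ", ",
      nrow(object@peaks), " peaks\n", sep = "")
})

## ---------------------------------------------------------------------------
## MsFeatureSet
## ---------------------------------------------------------------------------

#' Aligned LC-MS feature table
#'
#' A \code{SummarizedExperiment} with one \code{area} assay (features x
#' samples; \code{NA} marks a missing area, never zero), rowData columns
#' \code{mz} (m/z) and \code{rt} (minutes), colData columns \code{arm}
#' (\code{control}/\code{reaction}, or \code{NA} when no design is attached)
#' and \code{replicate}, and the run polarity (\code{"pos"}/\code{"neg"}) in
#' \code{metadata()}.
#'
#' @export
setClass("MsFeatureSet", contains = "SummarizedExperiment")

setValidity("MsFeatureSet", function(object) {
  msg <- character(0)
  if (!"area" %in% names(assays(object))) msg <- c(msg, "missing 'area' assay")
  rd <- rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  } else {
    if (any(rd$mz <= 0)) msg <- c(msg, "mz must be > 0")
    if (any(rd$rt < 0)) msg <- c(msg, "rt must be >= 0")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids (rownames) must be unique and non-NULL")
  if (length(msg)) msg else TRUE
})

#' Construct an MsFeatureSet
#'
#' @param area Numeric matrix of per-sample peak areas (features x samples),
#'   \code{NA} for missing values. Rownames are feature ids.
#' @param mz,rt Numeric vectors, one per feature.
#' @param arm Optional character vector of sample arms
#'   (\code{"control"}/\code{"reaction"}), one per column.
#' @param replicate Optional integer vector of replicate indices per column.
#' @param polarity Run polarity, \code{"pos"} or \code{"neg"}.
#' @return An \code{\linkS4class{MsFeatureSet}}.
#' @export
MsFeatureSet <- function(area, mz, rt, arm = NULL, replicate = NULL,
                         polarity = c("pos", "neg")) {
  polarity <- match.arg(polarity)
  area <- as.matrix(area)
  if (is.null(arm)) arm <- rep(NA_character_, ncol(area))
  if (is.null(replicate)) replicate <- rep(NA_integer_, ncol(area))
  se <- SummarizedExperiment(
    assays = list(area = area),
    rowData = DataFrame(mz = as.numeric(mz), rt = as.numeric(rt)),
    colData = DataFrame(arm = as.character(arm),
                        replicate = as.integer(replicate),
                        row.names = colnames(area)))
  md <- metadata(se)
  md$polarity <- polarity
  metadata(se) <- md
  new("MsFeatureSet", se)
}

#' @rdname MsFeatureSet-class
#' @param x An \code{MsFeatureSet}.
#' @export
featureIds <- function(x) rownames(x)

#' @rdname MsFeatureSet-class
#' @export
featureMz <- function(x) stats::setNames(rowData(x)$mz, rownames(x))

#' @rdname MsFeatureSet-class
#' @export
featureRt <- function(x) stats::setNames(rowData(x)$rt, rownames(x))

#' @rdname MsFeatureSet-class
#' @export
featureAreas <- function(x) assay(x, "area")

#' @rdname MsFeatureSet-class
#' @export
samplePolarity <- function(x) metadata(x)$polarity

#' @rdname MsFeatureSet-class
#' @export
sampleArms <- function(x) stats::setNames(colData(x)$arm, colnames(x))

## ---------------------------------------------------------------------------
## MolecularNetwork
## ---------------------------------------------------------------------------

#' Spectral-similarity molecular network
#'
#' Node/edge graph over MS2 features: edges carry the modified-cosine score,
#' the matched-ion count and the precursor shift; nodes carry precursor m/z
#' plus any annotation metadata; \code{membership} maps every node to its
#' connected-component id.
#'
#' @slot nodes \code{data.frame} with at least \code{feature_id} and
#'   \code{precursor_mz}.
#' @slot edges \code{data.frame} with columns \code{node_a}, \code{node_b},
#'   \code{cosine}, \code{matched_ions}, \code{precursor_shift}.
#' @slot membership Named integer vector, node -> component id.
#' @slot params Named list of the thresholds the network was built under.
#'
#' @export
setClass("MolecularNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 membership = "integer", params = "list"))

setValidity("MolecularNetwork", function(object) {
  msg <- character(0)
  if (!all(c("feature_id", "precursor_mz") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes need feature_id and precursor_mz")
  need <- c("node_a", "node_b", "cosine", "matched_ions", "precursor_shift")
  if (!all(need %in% colnames(object@edges)))
    msg <- c(msg, paste("edges need", paste(need, collapse = ", ")))
  if (!all(names(object@membership) %in% object@nodes$feature_id))
    msg <- c(msg, "membership names must be node feature ids")
  if (nrow(object@edges) > 0) {
    bad <- !(object@edges$node_a %in% object@nodes$feature_id) |
           !(object@edges$node_b %in% object@nodes$feature_id)
    if (any(bad)) msg <- c(msg, "edge endpoints must be known nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MolecularNetwork-class
#' @param net A \code{MolecularNetwork}.
#' @export
networkNodes <- function(net) net@nodes

#' @rdname MolecularNetwork-class
#' @export
networkEdges <- function(net) net@edges

#' @rdname MolecularNetwork-class
#' @export
componentMembership <- function(net) net@membership

setMethod("show", "MolecularNetwork", function(object) {
  cat("MolecularNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges,",
      length(unique(object@membership)), "components\n")
})
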