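## Feature-based molecular networking: modified-cosine spectral similarity,
## constrained edge construction with mutual top-K pruning, components, and
## parent-subnetwork annotation.

#' Modified cosine similarity between two MS2 spectra
#'
#' Intensities are square-root transformed and each spectrum normalized to
#' unit vector norm. A peak pair is eligible when the fragment m/z values
#' agree within \code{fragTol}, directly or after offsetting by the
#' precursor-mass difference (the "modified" channel that lets a conjugated
#' metabolite match its parent). A one-to-one matching is chosen greedily by
#' descending pair score (product of normalized weights); the cosine is the
#' sum of matched pair scores, in [0, 1].
#'
#' @param a,b \code{\linkS4class{Ms2Spectrum}} objects.
#' @param fragTol Fragment (and precursor) tolerance in Da (default 0.05).
#' @return List with \code{cosine} and \code{matched_ions}.
#' @export
modifiedCosine <- function(a, b, fragTol = 0.05) {
  pa <- peaks(a); pb <- peaks(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(list(cosine = 0, matched_ions = 0L))
  wa <- sqrt(pa[, 2]); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(pb[, 2]); wb <- wb / sqrt(sum(wb^2))
  shift <- precursorMz(a) - precursorMz(b)
  dm <- outer(pa[, 1], pb[, 1], "-")
  elig <- abs(dm) <= fragTol | abs(dm - shift) <= fragTol
  idx <- which(elig, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(cosine = 0, matched_ions = 0L))
  score <- wa[idx[, 1]] * wb[idx[, 2]]
  ord <- order(-score, idx[, 1], idx[, 2])
  usedA <- logical(nrow(pa)); usedB <- logical(nrow(pb))
  cosine <- 0; matched <- 0L
  for (k in ord) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      cosine <- cosine + score[k]
      matched <- matched + 1L
    }
  }
  list(cosine = min(cosine, 1), matched_ions = matched)
}

#' Build a molecular network from MS2 spectra
#'
#' Computes modified-cosine similarity for every spectrum pair, keeps
#' candidate edges with \code{cosine > minCosine} (strict), at least
#' \code{minMatched} matched fragment ions, and an absolute precursor shift
#' of at most \code{maxShift}, then applies mutual top-K pruning: an edge
#' survives only if it ranks within the top \code{topK} edges (by cosine,
#' ties by the partner id) of both endpoints. Connected components are
#' computed on the surviving edges; isolated nodes form singleton
#' components.
#'
#' @param spectra Named list of \code{\linkS4class{Ms2Spectrum}} (>= 2).
#' @param minCosine Cosine threshold, edges require \code{cosine >
#'   minCosine} (default 0.5).
#' @param minMatched Minimum matched fragment ions (default 6).
#' @param maxShift Maximum absolute precursor shift in m/z (default 500).
#' @param topK Maximum number of neighbors per node (default 10).
#' @param fragTol Fragment tolerance in Da (default 0.05).
#' @param mutual If \code{TRUE} (default) both endpoints must retain the
#'   edge in their top-K; if \code{FALSE} one side suffices.
#' @return A \code{\linkS4class{MolecularNetwork}}.
#' @export
buildNetwork <- function(spectra, minCosine = 0.5, minMatched = 6,
                         maxShift = 500, topK = 10, fragTol = 0.05,
                         mutual = TRUE) {
  stopifnot(length(spectra) >= 2)
  ids <- vapply(spectra, featureId, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids among spectra")
  names(spectra) <- ids
  prec <- vapply(spectra, precursorMz, numeric(1))
  n <- length(spectra)

  ea <- character(0); eb <- character(0)
  ecos <- numeric(0); emat <- integer(0); eshift <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shift <- prec[i] - prec[j]
      if (abs(shift) > maxShift) next
      mc <- modifiedCosine(spectra[[i]], spectra[[j]], fragTol)
      if (mc$cosine > minCosine && mc$matched_ions >= minMatched) {
        ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
        ecos <- c(ecos, mc$cosine); emat <- c(emat, mc$matched_ions)
        eshift <- c(eshift, shift)
      }
    }
  }
  edges <- data.frame(node_a = ea, node_b = eb, cosine = ecos,
                      matched_ions = emat, precursor_shift = eshift,
                      stringsAsFactors = FALSE)
  edges <- .pruneTopK(edges, topK, mutual)

  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  membership <- as.integer(comp[ids])
  names(membership) <- ids

  nodes <- data.frame(feature_id = unname(ids), precursor_mz = unname(prec),
                      stringsAsFactors = FALSE)
  new("MolecularNetwork", nodes = nodes, edges = edges,
      membership = membership,
      params = list(minCosine = minCosine, minMatched = minMatched,
                    maxShift = maxShift, topK = topK, fragTol = fragTol,
                    mutual = mutual))
}

# rank edges at each endpoint by cosine (desc), tie-break on partner id;
# keep an edge iff its rank <= topK at both (mutual) or either endpoint
.pruneTopK <- function(edges, topK, mutual = TRUE) {
  if (nrow(edges) == 0) return(edges)
  # each edge appears once; compute its rank in a's list and in b's list
  longNode <- c(edges$node_a, edges$node_b)
  longPartner <- c(edges$node_b, edges$node_a)
  longCos <- rep(edges$cosine, 2)
  longEdge <- rep(seq_len(nrow(edges)), 2)
  keepRank <- rep(NA_integer_, length(longNode))
  for (v in unique(longNode)) {
    sel <- which(longNode == v)
    keepRank[sel] <- order(order(-longCos[sel], longPartner[sel]))
  }
  within <- keepRank <= topK
  byEdge <- tapply(within, longEdge, if (mutual) all else any)
  out <- edges[as.logical(byEdge[as.character(seq_len(nrow(edges)))]), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize network components
#'
#' Per connected component: node count, number of annotated nodes and mean
#' log2 fold change (when the corresponding node metadata columns
#' \code{annotated} / \code{log2fc} are present). The full table is always
#' returned; \code{headline} flags components larger than \code{minSize}
#' for the headline report.
#'
#' @param net A \code{\linkS4class{MolecularNetwork}}.
#' @param minSize Headline size cutoff; components with more than this many
#'   nodes are flagged (default 10).
#' @return \code{data.frame} with \code{component}, \code{n_nodes},
#'   \code{n_annotated}, \code{mean_log2fc}, \code{headline}.
#' @export
componentSummary <- function(net, minSize = 10) {
  memb <- componentMembership(net)
  if (length(memb) == 0) {
    return(data.frame(component = integer(0), n_nodes = integer(0),
                      n_annotated = integer(0), mean_log2fc = numeric(0),
                      headline = logical(0)))
  }
  nodes <- networkNodes(net)
  ann <- if ("annotated" %in% colnames(nodes)) nodes$annotated else rep(NA, nrow(nodes))
  lfc <- if ("log2fc" %in% colnames(nodes)) nodes$log2fc else rep(NA_real_, nrow(nodes))
  comp <- memb[nodes$feature_id]
  out <- data.frame(
    component = sort(unique(as.integer(comp))),
    stringsAsFactors = FALSE
  )
  out$n_nodes <- as.integer(table(comp)[as.character(out$component)])
  out$n_annotated <- vapply(out$component, function(k) {
    sum(ann[comp == k], na.rm = TRUE)
  }, numeric(1))
  out$mean_log2fc <- vapply(out$component, function(k) {
    v <- lfc[comp == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out$headline <- out$n_nodes > minSize
  out <- out[order(-out$n_nodes, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate the parent-containing subnetwork
#'
#' Within the connected component that contains the parent feature, tests
#' every node's precursor m/z against the predicted biotransformant adduct
#' masses at \code{ms1Ppm}. Matched nodes are tagged with the reaction path;
#' unmatched nodes are tagged \code{candidate-novel} and reported with their
#' precursor m/z difference from the parent (the lead for manual follow-up).
#'
#' @param net A \code{\linkS4class{MolecularNetwork}}.
#' @param parentFeatureId Feature id of the parent node (must be in the
#'   network).
#' @param predictions Prediction table from
#'   \code{\link{enumerateBiotransformants}}.
#' @param ms1Ppm MS1 tolerance in ppm (default 5).
#' @param polarity Adduct polarity of the run (\code{"pos"}/\code{"neg"}).
#' @return \code{data.frame} with one row per node of the parent component:
#'   \code{feature_id}, \code{precursor_mz}, \code{delta_mz} (vs parent),
#'   \code{status} (\code{parent}/\code{annotated}/\code{candidate-novel}),
#'   \code{formula}, \code{path}, \code{ppm}.
#' @export
annotateSubnetwork <- function(net, parentFeatureId, predictions, ms1Ppm = 5,
                               polarity = c("pos", "neg")) {
  polarity <- match.arg(polarity)
  memb <- componentMembership(net)
  if (!parentFeatureId %in% names(memb)) {
    stop("parent feature '", parentFeatureId, "' is not in the network")
  }
  nodes <- networkNodes(net)
  inComp <- names(memb)[memb == memb[parentFeatureId]]
  sel <- nodes[nodes$feature_id %in% inComp, , drop = FALSE]
  parentMz <- sel$precursor_mz[sel$feature_id == parentFeatureId]
  predMz <- if (polarity == "pos") predictions$mzPos else predictions$mzNeg

  out <- data.frame(feature_id = sel$feature_id,
                    precursor_mz = sel$precursor_mz,
                    delta_mz = sel$precursor_mz - parentMz,
                    status = "candidate-novel",
                    formula = NA_character_, path = NA_character_,
                    ppm = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    err <- ppmError(out$precursor_mz[i], predMz)
    j <- which.min(err)
    if (err[j] <= ms1Ppm) {
      out$status[i] <- "annotated"
      out$formula[i] <- predictions$formula[j]
      out$path[i] <- predictions$path[j]
      out$ppm[i] <- err[j]
    }
  }
  isParent <- out$feature_id == parentFeatureId
  out$status[isParent] <- "parent"
  out$delta_mz[isParent] <- 0
  out <- out[order(out$status != "parent", out$delta_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML (Cytoscape-loadable) or TSV edge list
#'
#' Node attributes include precursor m/z plus any extra node metadata
#' columns; edge attributes are the cosine, matched-ion count and precursor
#' shift.
#'
#' @param net A \code{\linkS4class{MolecularNetwork}}.
#' @param path Output path.
#' @param format \code{"graphml"} (default) or \code{"tsv"} (edge list).
#' @param nodeData Optional \code{data.frame} of extra node attributes with
#'   a \code{feature_id} column.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "tsv"),
                         nodeData = NULL) {
  format <- match.arg(format)
  edges <- networkEdges(net)
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  nodes <- networkNodes(net)
  nodes$component <- unname(componentMembership(net)[nodes$feature_id])
  if (!is.null(nodeData)) {
    stopifnot("feature_id" %in% colnames(nodeData))
    nodes <- merge(nodes, nodeData, by = "feature_id", all.x = TRUE,
                   sort = FALSE)
  }
  vert <- nodes
  colnames(vert)[colnames(vert) == "feature_id"] <- "name"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
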