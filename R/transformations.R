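## Phase I/II transformation library and combinatorial enumeration of
## predicted biotransformants.

#' Read a transformation library
#'
#' A library file is a YAML (or JSON) list of records with fields
#' \code{name}, \code{phase} (\code{phase1}/\code{phase2}) and \code{delta}
#' (signed composition-change string, e.g. \code{"-(Cl) +(H O)"}).
#'
#' @param path Path to a YAML/JSON library file.
#' @return A \code{data.frame} with columns \code{name}, \code{phase},
#'   \code{delta} (the string) and a list-column \code{deltaComp} of parsed
#'   signed compositions.
#' @export
readTransformationLibrary <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("empty transformation library: ", path)
  lib <- data.frame(
    name  = vapply(raw, function(r) as.character(r$name), character(1)),
    phase = vapply(raw, function(r) as.character(r$phase), character(1)),
    delta = vapply(raw, function(r) as.character(r$delta), character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(lib$name)) {
    stop("duplicate transformation name(s): ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "))
  }
  if (!all(lib$phase %in% c("phase1", "phase2"))) {
    stop("phase must be 'phase1' or 'phase2'")
  }
  lib$deltaComp <- lapply(lib$delta, parseCompositionChange)
  if (any(vapply(lib$deltaComp, length, integer(1)) == 0)) {
    stop("transformation with empty (zero) delta is not allowed")
  }
  lib
}

#' The shipped phase I/II transformation library
#'
#' Default hepatic reaction library covering the common phase I
#' functionalizations (oxidation, reduction, (de)saturation, (de)hydration,
#' (de)methylation, deethylation, acetylation, decarboxylation, ring opening,
#' hydrolysis, nitro reduction, dehalogenations including deiodination, and
#' oxidative deaminations) and phase II conjugations (glucuronide, sulfate,
#' glutathione, glucoside, taurine, glutamine, arginine, palmitoyl, stearyl).
#'
#' @return Library \code{data.frame}; see
#'   \code{\link{readTransformationLibrary}}.
#' @export
defaultTransformations <- function() {
  readTransformationLibrary(
    system.file("extdata", "transformations.yaml", package = "TDCscreen",
                mustWork = TRUE))
}

#' Net composition delta of a reaction path
#'
#' Element-wise sum of the step deltas of an (unordered) reaction path;
#' permutation-invariant by construction.
#'
#' @param steps Character vector of transformation names (repeats allowed).
#' @param library Transformation library \code{data.frame}.
#' @return Signed composition vector.
#' @examples
#' lib <- defaultTransformations()
#' netDelta(c("Oxidation", "Sulfation"), lib)
#' @export
netDelta <- function(steps, library = defaultTransformations()) {
  stopifnot(length(steps) >= 1)
  idx <- match(steps, library$name)
  if (anyNA(idx)) {
    stop("unknown transformation(s): ",
         paste(unique(steps[is.na(idx)]), collapse = ", "))
  }
  do.call(compositionSum, library$deltaComp[idx])
}

## memoised enumeration results (deterministic; keyed by parent + library +
## depth limits)
.enum_cache <- new.env(parent = emptyenv())

#' Enumerate predicted biotransformants
#'
#' Generates every distinct product formula reachable from a parent by an
#' unordered multiset of at most \code{maxTotal} library reactions with at
#' most \code{maxPhase2} phase II (conjugation) steps. Products with any
#' negative element count are pruned, which automatically restricts
#' dehalogenations to parents that carry the halogen. Output is deduplicated
#' on the product formula, keeping one canonical representative path (fewest
#' steps, then lexicographically smallest path string), and ordered by
#' product mass then path.
#'
#' @param parent Parent elemental composition (vector or formula string),
#'   all counts >= 0.
#' @param library Transformation library \code{data.frame}.
#' @param maxTotal Maximum total number of reaction steps (>= 1).
#' @param maxPhase2 Maximum number of phase II steps (>= 0).
#' @param includeParent If \code{TRUE}, prepend a zero-step row for the
#'   parent itself (path \code{"(parent)"}).
#' @param cache Memoise results for repeated identical calls (the full
#'   default library at depth 5 enumerates ~1e5 paths).
#' @return \code{data.frame} with columns \code{formula}, \code{mass},
#'   \code{mzPos} (\code{[M+H]+}), \code{mzNeg} (\code{[M-H]-}),
#'   \code{nSteps}, \code{nPhase2}, \code{path} (comma-separated step names).
#' @export
enumerateBiotransformants <- function(parent, library = defaultTransformations(),
                                      maxTotal = 5, maxPhase2 = 1,
                                      includeParent = FALSE, cache = TRUE) {
  if (is.character(parent)) parent <- parseFormula(parent)
  parent <- normalizeComposition(parent)
  if (any(parent < 0)) stop("parent composition must have all counts >= 0")
  stopifnot(maxTotal >= 1, maxPhase2 >= 0)

  key <- paste(formatComposition(parent), maxTotal, maxPhase2,
               paste(library$name, library$delta, library$phase, collapse = ";"),
               sep = "|")
  key <- paste0("k", digestKey(key))
  if (cache && !is.null(.enum_cache[[key]])) {
    res <- .enum_cache[[key]]
  } else {
    res <- .enumerate(parent, library, maxTotal, maxPhase2)
    if (cache) .enum_cache[[key]] <- res
  }

  if (includeParent) {
    pm <- monoisotopicMass(parent)
    res <- rbind(
      data.frame(formula = formatComposition(parent), mass = pm,
                 mzPos = pm + PROTON_MASS, mzNeg = pm - PROTON_MASS,
                 nSteps = 0L, nPhase2 = 0L, path = "(parent)",
                 stringsAsFactors = FALSE),
      res)
  }
  res
}

# cheap deterministic string key (sum of char codes + length); collisions are
# acceptable only because the full key string is also compared
digestKey <- function(s) {
  paste0(nchar(s), "x", sum(utf8ToInt(s)))
}

.enumerate <- function(parent, library, maxTotal, maxPhase2) {
  nT <- nrow(library)
  elements <- Reduce(union, c(list(names(parent)), lapply(library$deltaComp, names)))
  elements <- .ELEMENT_ORDER[.ELEMENT_ORDER %in% elements]
  nE <- length(elements)
  p0 <- integer(nE); names(p0) <- elements
  p0[names(parent)] <- parent
  D <- matrix(0L, nrow = nT, ncol = nE, dimnames = list(library$name, elements))
  for (i in seq_len(nT)) {
    d <- library$deltaComp[[i]]
    D[i, names(d)] <- d
  }
  isP2 <- library$phase == "phase2"
  elMass <- ISOTOPE_MASSES[elements]

  found <- new.env(parent = emptyenv(), hash = TRUE, size = 4096L)

  record <- function(cur, path) {
    key <- paste(cur, collapse = ",")
    old <- found[[key]]
    pstr <- paste(sort(library$name[path]), collapse = ", ")
    if (is.null(old) || length(path) < old$nSteps ||
        (length(path) == old$nSteps && pstr < old$path)) {
      found[[key]] <- list(counts = cur, nSteps = length(path),
                           nPhase2 = sum(isP2[path]), path = pstr)
    }
  }

  # multisets are built in nondecreasing library-index order, so each
  # distinct multiset is constructed (and recorded) exactly once
  rec <- function(i, slots, slots2, cur, path) {
    if (i > nT || slots == 0L) return(invisible(NULL))
    rec(i + 1L, slots, slots2, cur, path)  # branch: no (more) of reaction i
    if (!isP2[i] || slots2 > 0L) {         # branch: one more of reaction i
      cur2 <- cur + D[i, ]
      path2 <- c(path, i)
      if (all(cur2 >= 0L)) record(cur2, path2)
      # keep recursing even through negative intermediates: a later reaction
      # in index order may restore the element (only final products matter)
      rec(i, slots - 1L, slots2 - (isP2[i]), cur2, path2)
    }
    invisible(NULL)
  }
  rec(1L, as.integer(maxTotal), as.integer(maxPhase2), p0, integer(0))

  recs <- as.list(found)
  if (length(recs) == 0) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      mzPos = numeric(0), mzNeg = numeric(0),
                      nSteps = integer(0), nPhase2 = integer(0),
                      path = character(0), stringsAsFactors = FALSE))
  }
  counts <- do.call(rbind, lapply(recs, `[[`, "counts"))
  mass <- as.numeric(counts %*% elMass)
  res <- data.frame(
    formula = apply(counts, 1, function(x) {
      formatComposition(stats::setNames(x, elements))
    }),
    mass = mass,
    mzPos = mass + PROTON_MASS,
    mzNeg = mass - PROTON_MASS,
    nSteps = vapply(recs, `[[`, integer(1), "nSteps"),
    nPhase2 = vapply(recs, function(r) as.integer(r$nPhase2), integer(1)),
    path = vapply(recs, `[[`, character(1), "path"),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$mass, res$path), , drop = FALSE]
  rownames(res) <- NULL
  res
}
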