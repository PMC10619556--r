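## Elemental-composition algebra and monoisotopic mass.
##
## Compositions are plain named integer vectors (element symbol -> signed
## count), normalized so that zero counts are dropped and elements appear in
## canonical order (C, H, then alphabetical). Signed compositions represent
## reaction deltas; non-negative ones represent molecules.

.ELEMENT_ORDER <- c("C", "H", setdiff(sort(names(ISOTOPE_MASSES)), c("C", "H")))

#' Normalize an elemental composition
#'
#' Collapses duplicate element entries, drops zero counts and orders elements
#' canonically (C, H, then alphabetically). All composition-returning
#' functions in the package emit normalized vectors, so equal compositions
#' are \code{identical()}.
#'
#' @param comp Named numeric vector of signed element counts.
#' @return Named integer vector in canonical element order.
#' @export
normalizeComposition <- function(comp) {
  if (length(comp) == 0) {
    x <- integer(0)
    names(x) <- character(0)
    return(x)
  }
  stopifnot(!is.null(names(comp)))
  unknown <- setdiff(names(comp), names(ISOTOPE_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  tot <- tapply(as.integer(round(comp)), names(comp), sum)
  tot <- tot[tot != 0]
  ord <- .ELEMENT_ORDER[.ELEMENT_ORDER %in% names(tot)]
  x <- as.integer(tot[ord])
  names(x) <- ord
  x
}

#' Parse an elemental formula string
#'
#' Accepts both the spaced dialect used in composition-change tables
#' (\code{"C6 H8 O6"}) and the compact dialect (\code{"C6H8O6"}). An omitted
#' count means 1. The empty string parses to the empty composition.
#'
#' @param text Formula string.
#' @return Named integer composition vector.
#' @examples
#' parseFormula("C6 H8 O6")
#' parseFormula("O3 S")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) return(normalizeComposition(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    # locate the first character not covered by any token
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
    bad <- which(!covered)[1]
    stop(sprintf("malformed formula '%s': cannot parse at position %d ('%s')",
                 text, bad, substr(s, bad, bad)))
  }
  els <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(els, names(ISOTOPE_MASSES))
  if (length(unknown) > 0) {
    stop(sprintf("malformed formula '%s': unknown element symbol(s) %s",
                 text, paste(unknown, collapse = ", ")))
  }
  names(cnt) <- els
  normalizeComposition(cnt)
}

#' Format a composition as a spaced formula string
#'
#' Inverse of \code{\link{parseFormula}} for non-negative compositions:
#' \code{parseFormula(formatComposition(x))} is identical to
#' \code{normalizeComposition(x)}.
#'
#' @param comp Composition vector (all counts must share one sign; use
#'   \code{\link{formatCompositionChange}} for mixed-sign deltas).
#' @param compact If \code{TRUE}, emit the compact dialect without spaces.
#' @return Character scalar, \code{""} for the empty composition.
#' @export
formatComposition <- function(comp, compact = FALSE) {
  comp <- normalizeComposition(comp)
  if (length(comp) == 0) return("")
  if (any(comp < 0)) stop("negative counts; use formatCompositionChange()")
  parts <- ifelse(comp == 1, names(comp), paste0(names(comp), comp))
  paste(parts, collapse = if (compact) "" else " ")
}

#' Format a signed composition delta
#'
#' Writes a reaction delta in the table dialect, e.g.
#' \code{"-(H2 Cl2) +(O5 S)"}. The gain group is written after the loss
#' group; either is omitted when empty, and the empty delta formats as
#' \code{"+()"}.
#'
#' @param delta Signed composition vector.
#' @return Character scalar.
#' @export
formatCompositionChange <- function(delta) {
  delta <- normalizeComposition(delta)
  loss <- -delta[delta < 0]
  gain <- delta[delta > 0]
  parts <- character(0)
  if (length(loss)) parts <- c(parts, paste0("-(", formatComposition(loss), ")"))
  if (length(gain)) parts <- c(parts, paste0("+(", formatComposition(gain), ")"))
  if (!length(parts)) parts <- "+()"
  paste(parts, collapse = " ")
}

#' Parse a signed composition delta
#'
#' Accepts the table dialect \code{"-(H2 Cl2) +(O5 S)"} (any number of signed
#' groups, in any order) as well as a bare unsigned formula, which is read as
#' a gain.
#'
#' @param text Delta string.
#' @return Signed composition vector.
#' @export
parseCompositionChange <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  s <- trimws(text)
  if (!nzchar(s)) return(normalizeComposition(integer(0)))
  if (!grepl("[()]", s)) return(parseFormula(s))
  m <- gregexpr("([+-])\\s*\\(([^()]*)\\)", s, perl = TRUE)[[1]]
  if (m[1] == -1) stop(sprintf("malformed composition change '%s'", text))
  groups <- regmatches(s, list(m))[[1]]
  rest <- gsub("([+-])\\s*\\(([^()]*)\\)", "", s, perl = TRUE)
  if (grepl("[^[:space:]]", rest)) {
    stop(sprintf("malformed composition change '%s': unparsed text '%s'",
                 text, trimws(rest)))
  }
  delta <- integer(0)
  for (g in groups) {
    sign <- if (startsWith(g, "-")) -1L else 1L
    inner <- sub("^[+-]\\s*\\(", "", sub("\\)$", "", g))
    part <- parseFormula(inner)
    delta <- c(delta, sign * part)
  }
  normalizeComposition(delta)
}

#' Sum compositions element-wise
#'
#' @param ... Composition vectors (possibly signed).
#' @return Normalized signed composition vector.
#' @export
compositionSum <- function(...) {
  normalizeComposition(unlist(list(...)))
}

#' Monoisotopic mass of a composition
#'
#' Sum of count times the most-abundant-isotope mass from the embedded
#' table (\code{\link{ISOTOPE_MASSES}}). Refuses signed compositions: a
#' reaction delta has no mass of its own until applied to a parent.
#'
#' @param comp Non-negative composition vector.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("C6 H8 O6"))
#' @export
monoisotopicMass <- function(comp) {
  comp <- normalizeComposition(comp)
  if (any(comp < 0)) {
    stop("negative element count: signed deltas must be applied to a parent before massing")
  }
  if (length(comp) == 0) return(0)
  sum(comp * ISOTOPE_MASSES[names(comp)])
}

#' Mass shift of a signed delta
#'
#' Signed mass difference implied by a reaction delta (gains minus losses).
#' Unlike \code{\link{monoisotopicMass}} this accepts negative counts; it is
#' the precursor shift expected between a parent and its biotransformant.
#'
#' @param delta Signed composition vector.
#' @return Signed mass shift in Da.
#' @export
deltaMass <- function(delta) {
  delta <- normalizeComposition(delta)
  if (length(delta) == 0) return(0)
  sum(delta * ISOTOPE_MASSES[names(delta)])
}

#' Expected adduct m/z for a neutral mass
#'
#' Singly charged protonation/deprotonation only: \code{[M+H]+} adds and
#' \code{[M-H]-} subtracts one proton mass.
#'
#' @param neutralMass Neutral monoisotopic mass in Da (> 0).
#' @param adduct \code{"M+H"} or \code{"M-H"}.
#' @return m/z value.
#' @export
expectedMz <- function(neutralMass, adduct = c("M+H", "M-H")) {
  stopifnot(is.numeric(neutralMass), length(neutralMass) >= 1)
  if (any(neutralMass <= 0)) stop("neutral mass must be > 0")
  adduct <- match.arg(adduct)
  if (adduct == "M+H") neutralMass + PROTON_MASS else neutralMass - PROTON_MASS
}

#' Relative mass error in ppm
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return \code{1e6 * |observed - theoretical| / theoretical}.
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * abs(observed - theoretical) / theoretical
}
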