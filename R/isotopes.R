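#' Monoisotopic masses of the most abundant isotopes
#'
#' Named numeric vector of exact masses (Da) of the most abundant stable
#' isotope of each supported element (IUPAC/AME values). These are the masses
#' used throughout the package for neutral monoisotopic mass and m/z
#' arithmetic; the table is embedded so the package needs no external lookup.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @export
ISOTOPE_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  F  = 18.99840322,
  Na = 22.9897692809,
  K  = 38.96370668,
  Si = 27.9769265325
)

#' Mass of a proton in Da
#'
#' Used for singly-charged adduct m/z: \code{[M+H]+ = M + PROTON_MASS},
#' \code{[M-H]- = M - PROTON_MASS}.
#'
#' @export
PROTON_MASS <- 1.007276466879
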