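# Independent brute-force oracles and small fixture builders shared across
# the test files. These deliberately re-derive results by exhaustive
# enumeration, never by calling the package code paths they check.

# random centroid spectrum using the current RNG state
randomSpectrum <- function(id, nPeaks = 6, mzRange = c(100, 900),
                           precursor = NULL) {
  mz <- sort(runif(nPeaks, mzRange[1], mzRange[2]))
  if (is.null(precursor)) precursor <- runif(1, mzRange[2], mzRange[2] + 100)
  Ms2Spectrum(id, precursor, mz, rlnorm(nPeaks, log(1e4), 1))
}

# exhaustive optimal one-to-one matching for the modified cosine: maximizes
# the sum of pair products over all matchings of eligible peak pairs
bruteForceCosine <- function(a, b, fragTol = 0.05) {
  pa <- peaks(a); pb <- peaks(b)
  wa <- sqrt(pa[, 2]); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(pb[, 2]); wb <- wb / sqrt(sum(wb^2))
  shift <- precursorMz(a) - precursorMz(b)
  dm <- outer(pa[, 1], pb[, 1], "-")
  elig <- which(abs(dm) <= fragTol | abs(dm - shift) <= fragTol,
                arr.ind = TRUE)
  if (nrow(elig) == 0) return(list(cosine = 0, matched_ions = 0L))
  best <- list(score = 0, n = 0L)
  nPair <- nrow(elig)
  rec <- function(k, usedA, usedB, score, n) {
    if (score > best$score + 1e-15 ||
        (abs(score - best$score) <= 1e-15 && n > best$n)) {
      best <<- list(score = score, n = n)
    }
    if (k > nPair) return(invisible(NULL))
    rec(k + 1, usedA, usedB, score, n)  # skip pair k
    i <- elig[k, 1]; j <- elig[k, 2]
    if (!(i %in% usedA) && !(j %in% usedB)) {
      rec(k + 1, c(usedA, i), c(usedB, j),
          score + wa[i] * wb[j], n + 1L)
    }
    invisible(NULL)
  }
  rec(1L, integer(0), integer(0), 0, 0L)
  list(cosine = best$score, matched_ions = best$n)
}

# exhaustive biotransformant enumeration over ordered reaction tuples
bruteForceEnumerate <- function(parent, lib, maxTotal, maxPhase2) {
  if (is.character(parent)) parent <- parseFormula(parent)
  products <- character(0)
  nT <- nrow(lib)
  for (depth in seq_len(maxTotal)) {
    tuples <- as.matrix(expand.grid(rep(list(seq_len(nT)), depth)))
    for (r in seq_len(nrow(tuples))) {
      idx <- tuples[r, ]
      if (sum(lib$phase[idx] == "phase2") > maxPhase2) next
      prod <- parent
      for (i in idx) prod <- compositionSum(prod, lib$deltaComp[[i]])
      if (all(prod >= 0)) products <- c(products, formatComposition(prod))
    }
  }
  sort(unique(products))
}

# two-sided exact Mann-Whitney by direct enumeration of group assignments,
# with U defined by pair counting (not rank sums)
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  uOf <- function(xs, ys) {
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys), numeric(1)))
  }
  u <- uOf(x, y)
  splits <- utils::combn(length(pooled), n1)
  uAll <- apply(splits, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(uAll <= u + 1e-9), mean(uAll >= u - 1e-9)))
}

# minimal two-arm feature set
makeFeatureSet <- function(area, mz = NULL, rt = NULL, polarity = "pos") {
  n <- nrow(area)
  if (is.null(mz)) mz <- seq(200, 200 + n - 1)
  if (is.null(rt)) rt <- rep(5, n)
  arm <- ifelse(grepl("^control", colnames(area)), "control", "reaction")
  MsFeatureSet(area, mz = mz, rt = rt, arm = arm,
               replicate = as.integer(sub("^.*_", "", colnames(area))),
               polarity = polarity)
}

# balanced two-arm area matrix from per-arm means (exact values, no noise)
armAreas <- function(ids, controlMean, reactionMean, nRep = 3) {
  a <- cbind(matrix(rep(controlMean, nRep), ncol = nRep),
             matrix(rep(reactionMean, nRep), ncol = nRep))
  dimnames(a) <- list(ids, c(paste0("control_", 1:nRep),
                             paste0("reaction_", 1:nRep)))
  a
}

# simple assay plate from anchor means and per-dose test luminescence
makePlate <- function(pc = 1000, vc = 100, vcTest = NULL, arm = "phase1_2",
                      tests = list(), nRep = 3) {
  if (is.null(vcTest)) vcTest <- vc
  rows <- list(
    data.frame(well_id = paste0("PC_", 1:nRep), role = "PC",
               arm = NA_character_, compound = "PC", dose_molar = 1e-7,
               luminescence = rep(pc, nRep), replicate = 1:nRep),
    data.frame(well_id = paste0("VC_", 1:nRep), role = "VC_control",
               arm = NA_character_, compound = "VC", dose_molar = 0,
               luminescence = rep(vc, nRep), replicate = 1:nRep),
    data.frame(well_id = paste0("VCt_", 1:nRep), role = "VC_test",
               arm = arm, compound = "X", dose_molar = 0,
               luminescence = rep(vcTest, nRep), replicate = 1:nRep)
  )
  for (d in names(tests)) {
    rows[[length(rows) + 1]] <-
      data.frame(well_id = paste0("t", d, "_", 1:nRep), role = "test",
                 arm = arm, compound = "X", dose_molar = as.numeric(d),
                 luminescence = rep_len(tests[[d]], nRep), replicate = 1:nRep)
  }
  do.call(rbind, rows)
}
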