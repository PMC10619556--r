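## Univariate statistics of biotransformant profiles: Mann-Whitney tests,
## fold changes, volcano tables, metabolic rate.

#' Two-sided Mann-Whitney U test
#'
#' With \code{method = "auto"} (the default) the exact permutation
#' distribution is enumerated whenever the combined sample size is at most
#' \code{exactLimit} (ties handled by ranking, every group assignment
#' enumerated); larger samples use the tie-corrected normal approximation.
#' The exact two-sided p-value is \code{2 * min(P(U <= u), P(U >= u))}
#' capped at 1. Note that with 3 vs 3 observations the smallest exact
#' two-sided p-value is 0.1, so no feature can reach p < 0.05 at that
#' design size; the normal approximation without continuity correction can
#' (p = 0.0495 under complete separation) at the cost of an inflated
#' type-I error, which is why \code{continuity = TRUE} is the default.
#'
#' @param x,y Numeric vectors (each length >= 1).
#' @param method \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default \code{TRUE}).
#' @param exactLimit Maximum combined sample size for exact enumeration in
#'   \code{"auto"} mode (default 12).
#' @return Two-sided p-value. Identical pooled values give p = 1.
#' @export
mannWhitney <- function(x, y, method = c("auto", "exact", "normal"),
                        continuity = TRUE, exactLimit = 12) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  if (method == "auto") {
    method <- if (length(pooled) <= exactLimit) "exact" else "normal"
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "exact") {
    combs <- utils::combn(N, n1)
    uAll <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    pLe <- mean(uAll <= u + 1e-9)
    pGe <- mean(uAll >= u - 1e-9)
    return(min(1, 2 * min(pLe, pGe)))
  }
  mu <- n1 * n2 / 2
  tie <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  if (continuity) z <- sign(z) * max(0, abs(z) - 0.5)
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Per-feature fold change and test statistics
#'
#' For every feature, the fold change is the mean area in the reaction arm
#' over the mean area in the control arm (areas should be imputed first so
#' both means are positive), with a two-sided Mann-Whitney p-value.
#'
#' @param x Imputed \code{\linkS4class{MsFeatureSet}} whose colData
#'   \code{arm} contains \code{"control"} and \code{"reaction"}.
#' @param alpha Significance level for the \code{significant} flag
#'   (default 0.05).
#' @param method,continuity Passed to \code{\link{mannWhitney}}.
#' @return \code{data.frame} with \code{feature_id}, \code{fc},
#'   \code{log2fc}, \code{p}, \code{significant}, \code{direction}
#'   (\code{up}/\code{down}/\code{ns}).
#' @export
featureStats <- function(x, alpha = 0.05, method = "auto", continuity = TRUE) {
  arms <- sampleArms(x)
  if (!all(c("control", "reaction") %in% arms)) {
    stop("feature set needs 'control' and 'reaction' samples")
  }
  a <- featureAreas(x)
  ctrl <- a[, arms == "control", drop = FALSE]
  rxn <- a[, arms == "reaction", drop = FALSE]
  mc <- rowMeans(ctrl, na.rm = TRUE)
  mr <- rowMeans(rxn, na.rm = TRUE)
  if (any(!is.finite(mc)) || any(mc == 0)) {
    stop("zero or undefined control mean; impute areas first")
  }
  fc <- mr / mc
  p <- vapply(seq_len(nrow(a)), function(i) {
    mannWhitney(rxn[i, !is.na(rxn[i, ])], ctrl[i, !is.na(ctrl[i, ])],
                method = method, continuity = continuity)
  }, numeric(1))
  sig <- p < alpha
  data.frame(
    feature_id = rownames(a),
    fc = unname(fc),
    log2fc = unname(log2(fc)),
    p = p,
    significant = sig,
    direction = ifelse(!sig, "ns", ifelse(fc > 1, "up", "down")),
    stringsAsFactors = FALSE
  )
}

#' Fold change of a single feature
#'
#' Mean reaction area over mean control area.
#'
#' @param areas Named numeric vector of per-sample areas.
#' @param arms Character vector (same length/order) of sample arms.
#' @return List with \code{fc} and \code{log2fc}.
#' @export
foldChange <- function(areas, arms) {
  stopifnot(length(areas) == length(arms))
  mc <- mean(areas[arms == "control"], na.rm = TRUE)
  mr <- mean(areas[arms == "reaction"], na.rm = TRUE)
  if (!is.finite(mc) || mc == 0) stop("zero or undefined control mean")
  list(fc = mr / mc, log2fc = log2(mr / mc))
}

#' Volcano table with up/down counts
#'
#' Classifies every feature as \code{up} (fc > 1 and p < alpha),
#' \code{down} (fc < 1 and p < alpha) or \code{ns}; the partition is
#' exhaustive and mutually exclusive.
#'
#' @param stats Table from \code{\link{featureStats}} (needs \code{fc} and
#'   \code{p}).
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg correction to the p-values before
#'   thresholding (default \code{FALSE}; no multiplicity correction).
#' @return List with \code{table} (per-feature \code{log2fc},
#'   \code{neg_log10_p}, \code{direction}) and counts \code{n_up},
#'   \code{n_down}, \code{n_ns}.
#' @export
volcanoTable <- function(stats, alpha = 0.05, fdr = FALSE) {
  p <- if (fdr) stats::p.adjust(stats$p, method = "BH") else stats$p
  sig <- p < alpha
  dir <- ifelse(!sig, "ns", ifelse(stats$fc > 1, "up", "down"))
  tab <- data.frame(feature_id = stats$feature_id,
                    log2fc = log2(stats$fc),
                    neg_log10_p = -log10(stats$p),
                    direction = dir,
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_up = sum(dir == "up"), n_down = sum(dir == "down"),
       n_ns = sum(dir == "ns"))
}

#' Metabolic rate of a parent compound
#'
#' Percent depletion of the parent after the enzymatic reaction:
#' \code{100 * (1 - mean(reaction) / mean(control))}. Negative values mean
#' the parent increased.
#'
#' @param areas Named numeric vector of parent per-sample areas.
#' @param arms Character vector of sample arms (\code{control} /
#'   \code{reaction}).
#' @return Metabolic rate in percent.
#' @export
metabolicRate <- function(areas, arms) {
  stopifnot(length(areas) == length(arms))
  mc <- mean(areas[arms == "control"], na.rm = TRUE)
  mr <- mean(areas[arms == "reaction"], na.rm = TRUE)
  if (!is.finite(mc) || mc == 0) stop("zero or undefined control mean")
  100 * (1 - mr / mc)
}

#' Write a feature statistics table to CSV
#'
#' @param stats Table from \code{\link{featureStats}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeStats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
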