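## Readers/writers for feature tables and MGF spectra; QC alignment and
## missing-value imputation.

#' Read an aligned feature table from CSV
#'
#' Expected header: \code{feature_id}, \code{mz}, \code{rt}, then one column
#' per sample. Blank cells are read as missing (\code{NA}), never as zero.
#'
#' @param path CSV path.
#' @param arm Optional named character vector mapping sample column names to
#'   arms (\code{"control"}/\code{"reaction"}); samples not named get
#'   \code{NA}. Alternatively arms are inferred from sample names of the form
#'   \code{<arm>_<replicate>} when \code{inferDesign = TRUE}.
#' @param polarity Run polarity stored in the object metadata.
#' @param inferDesign Infer \code{arm}/\code{replicate} from sample names
#'   like \code{control_2} (default TRUE).
#' @return An \code{\linkS4class{MsFeatureSet}}.
#' @export
readFeatureTable <- function(path, arm = NULL, polarity = c("pos", "neg"),
                             inferDesign = TRUE) {
  polarity <- match.arg(polarity)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% colnames(df))) {
    stop("feature table must have columns feature_id, mz, rt: ", path)
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id in ", path, ": ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  }
  sampleCols <- setdiff(colnames(df), need)
  if (length(sampleCols) == 0) stop("no sample columns in ", path)
  area <- matrix(NA_real_, nrow(df), length(sampleCols),
                 dimnames = list(df$feature_id, sampleCols))
  for (j in seq_along(sampleCols)) {
    v <- df[[sampleCols[j]]]
    blank <- is.na(v) | !nzchar(trimws(v))
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric area '%s' at row %d, column '%s' of %s",
                   v[bad[1]], bad[1], sampleCols[j], path))
    }
    num[blank] <- NA_real_
    area[, j] <- num
  }
  armVec <- rep(NA_character_, length(sampleCols))
  repVec <- rep(NA_integer_, length(sampleCols))
  if (!is.null(arm)) {
    armVec <- unname(arm[sampleCols])
  } else if (inferDesign) {
    m <- regmatches(sampleCols, regexec("^(.*)_([0-9]+)$", sampleCols))
    ok <- lengths(m) == 3
    armVec[ok] <- vapply(m[ok], `[`, character(1), 2)
    repVec[ok] <- as.integer(vapply(m[ok], `[`, character(1), 3))
  }
  MsFeatureSet(area, mz = as.numeric(df$mz), rt = as.numeric(df$rt),
               arm = armVec, replicate = repVec, polarity = polarity)
}

#' Write a feature table to CSV
#'
#' Counterpart of \code{\link{readFeatureTable}}; missing areas are written
#' as empty cells so the round trip preserves missingness.
#'
#' @param x An \code{MsFeatureSet}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  a <- featureAreas(x)
  df <- data.frame(feature_id = rownames(a),
                   mz = rowData(x)$mz, rt = rowData(x)$rt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(a)) df[[s]] <- a[, s]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' Parses \code{BEGIN IONS}/\code{END IONS} blocks. \code{PEPMASS} (first
#' token) is required per block; \code{FEATURE_ID}, else \code{SCANS}, else
#' \code{TITLE} provides the feature id. Peak lines are m/z and intensity;
#' peaks are sorted by m/z on read and zero-intensity centroids dropped.
#'
#' @param path MGF path.
#' @return Named list of \code{\linkS4class{Ms2Spectrum}} (names are feature
#'   ids).
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN IONS/END IONS blocks in ", path)
  }
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1):(ends[b] - 1)]
    isParam <- grepl("=", block, fixed = TRUE)
    params <- block[isParam]
    keys <- toupper(sub("=.*$", "", params))
    vals <- sub("^[^=]*=", "", params)
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF block %d of %s has no PEPMASS", b, path))
    }
    pep <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    id <- if ("FEATURE_ID" %in% keys) vals[match("FEATURE_ID", keys)]
          else if ("SCANS" %in% keys) vals[match("SCANS", keys)]
          else if ("TITLE" %in% keys) vals[match("TITLE", keys)]
          else as.character(b)
    charge <- 1L
    if ("CHARGE" %in% keys) {
      charge <- as.integer(sub("[+-]\\s*$", "", trimws(vals[match("CHARGE", keys)])))
    }
    pk <- block[!isParam]
    pk <- pk[nzchar(trimws(pk))]
    mzv <- numeric(0); inty <- numeric(0)
    if (length(pk) > 0) {
      fields <- strsplit(trimws(pk), "\\s+")
      mzv <- as.numeric(vapply(fields, `[`, character(1), 1))
      inty <- as.numeric(vapply(fields, `[`, character(1), 2))
      if (anyNA(mzv) || anyNA(inty)) {
        stop(sprintf("unparseable peak line in MGF block %d of %s", b, path))
      }
      keep <- inty > 0
      mzv <- mzv[keep]; inty <- inty[keep]
    }
    out[[b]] <- Ms2Spectrum(id, pep, mzv, inty, charge)
  }
  names(out) <- vapply(out, featureId, character(1))
  out
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of \code{\linkS4class{Ms2Spectrum}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    p <- peaks(sp)
    writeLines(c(
      "BEGIN IONS",
      paste0("FEATURE_ID=", featureId(sp)),
      paste0("PEPMASS=", format(precursorMz(sp), digits = 10, scientific = FALSE)),
      paste0("CHARGE=", sp@charge, "+"),
      sprintf("%.6f %.4f", p[, 1], p[, 2]),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' Align features to pooled-QC reference features
#'
#' Greedy nearest-m/z matching: candidate (feature, QC) pairs within both
#' the m/z and RT tolerances are accepted in order of increasing m/z
#' distance (ties broken by feature id), each feature and each QC feature
#' used at most once. Aligned features adopt the QC consensus m/z and RT;
#' unmatched features are retained unchanged and flagged.
#'
#' @param x Features (\code{MsFeatureSet}).
#' @param qc QC reference features (\code{MsFeatureSet}).
#' @param rtTol RT tolerance in minutes (default 0.1).
#' @param mzTol m/z tolerance in Da (default 0.02).
#' @return \code{x} with rowData columns \code{aligned} (logical) and
#'   \code{qc_id} (matched QC feature id or \code{NA}), m/z and RT replaced
#'   by the QC values for aligned features.
#' @export
alignToQc <- function(x, qc, rtTol = 0.1, mzTol = 0.02) {
  stopifnot(rtTol > 0, mzTol > 0)
  fmz <- featureMz(x); frt <- featureRt(x)
  qmz <- featureMz(qc); qrt <- featureRt(qc)
  cand <- which(outer(fmz, qmz, function(a, b) abs(a - b)) <= mzTol &
                outer(frt, qrt, function(a, b) abs(a - b)) <= rtTol,
                arr.ind = TRUE)
  qcId <- rep(NA_character_, nrow(x))
  if (nrow(cand) > 0) {
    dmz <- abs(fmz[cand[, 1]] - qmz[cand[, 2]])
    ord <- order(dmz, rownames(x)[cand[, 1]], names(qmz)[cand[, 2]])
    usedF <- logical(nrow(x)); usedQ <- logical(length(qmz))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedF[i] && !usedQ[j]) {
        usedF[i] <- TRUE; usedQ[j] <- TRUE
        qcId[i] <- names(qmz)[j]
      }
    }
  }
  rd <- rowData(x)
  hit <- !is.na(qcId)
  rd$mz[hit] <- qmz[qcId[hit]]
  rd$rt[hit] <- qrt[qcId[hit]]
  rd$aligned <- hit
  rd$qc_id <- qcId
  rowData(x) <- rd
  validObject(x)
  x
}

#' Impute missing feature areas
#'
#' Per feature, each missing area is replaced by \code{fraction} times the
#' minimum observed area of that feature over all samples (the standard
#' minimum-fraction rule; default 10 percent). Observed values are never
#' altered. Features with no observed value at all are dropped with a
#' message.
#'
#' @param x An \code{MsFeatureSet}.
#' @param fraction Fraction of the per-feature minimum (0 < fraction < 1).
#' @return Imputed \code{MsFeatureSet}.
#' @export
imputeMissing <- function(x, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 1)
  a <- featureAreas(x)
  allMissing <- apply(a, 1, function(r) all(is.na(r)))
  if (any(allMissing)) {
    message("dropping ", sum(allMissing),
            " feature(s) with no observed value: ",
            paste(utils::head(rownames(a)[allMissing], 5), collapse = ", "))
    x <- x[!allMissing, ]
    a <- featureAreas(x)
  }
  for (i in which(apply(a, 1, anyNA))) {
    r <- a[i, ]
    r[is.na(r)] <- fraction * min(r, na.rm = TRUE)
    a[i, ] <- r
  }
  SummarizedExperiment::assay(x, "area") <- a
  x
}
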