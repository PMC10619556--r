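## Reporter-gene (luciferase) assay normalization: relative transcriptional
## activity (RTA) anchored at the positive control (100%) and vehicle
## control (0%), and the agonist positivity call.

.PLATE_COLS <- c("well_id", "role", "arm", "compound", "dose_molar",
                 "luminescence", "replicate")
.PLATE_ROLES <- c("PC", "VC_control", "VC_test", "test")

#' Validate an assay plate table
#'
#' A plate is a \code{data.frame} with columns \code{well_id}, \code{role}
#' (\code{PC}, \code{VC_control}, \code{VC_test}, \code{test}), \code{arm}
#' (\code{parent}, \code{inactive_s9}, \code{phase1}, \code{phase1_2} for
#' test/VC_test wells), \code{compound}, \code{dose_molar},
#' \code{luminescence} (RLU, >= 0) and \code{replicate}.
#'
#' @param plate Plate \code{data.frame}.
#' @return The validated plate, invisibly usable downstream.
#' @export
assayPlate <- function(plate) {
  miss <- setdiff(.PLATE_COLS, colnames(plate))
  if (length(miss)) stop("plate is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(plate$role %in% .PLATE_ROLES)) {
    stop("plate roles must be one of ", paste(.PLATE_ROLES, collapse = ", "))
  }
  if (any(plate$luminescence < 0)) stop("luminescence must be >= 0")
  if (sum(plate$role == "PC") < 1 || sum(plate$role == "VC_control") < 1) {
    stop("plate needs at least one PC and one VC_control well")
  }
  testArms <- unique(plate$arm[plate$role == "test"])
  vcArms <- unique(plate$arm[plate$role == "VC_test"])
  if (!all(testArms %in% vcArms)) {
    stop("every test arm needs a VC_test well; missing for: ",
         paste(setdiff(testArms, vcArms), collapse = ", "))
  }
  plate
}

#' Read an assay plate CSV
#'
#' @param path CSV path with the columns described in
#'   \code{\link{assayPlate}}.
#' @return Validated plate \code{data.frame}.
#' @export
readPlate <- function(path) {
  assayPlate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Relative transcriptional activity (% of positive control)
#'
#' Per compound/arm/dose, each replicate's RTA is
#' \code{100 * (test - mean(VC_test of its arm)) / (mean(PC) -
#' mean(VC_control))}; by construction the positive control anchors at 100%
#' and the vehicle control at 0%. Replicate RTAs are summarized as mean,
#' spread and n. The spread is the standard deviation by default, or the
#' standard error of the mean with \code{sem = TRUE}.
#'
#' @param plate Plate \code{data.frame} (see \code{\link{assayPlate}}).
#' @param sem Report SEM instead of SD (default \code{FALSE}).
#' @param tol Minimum PC - VC_control separation, as a fraction of the PC
#'   mean, below which the assay is declared invalid (default 1e-6).
#' @param qcFold Optional QC warning threshold: warn when the PC/VC_control
#'   induction fold is below this value (e.g. 4.8); \code{NULL} disables the
#'   check.
#' @return \code{data.frame} with \code{compound}, \code{arm},
#'   \code{dose_molar}, \code{rta_percent}, \code{sd_percent}, \code{n}.
#' @export
rta <- function(plate, sem = FALSE, tol = 1e-6, qcFold = NULL) {
  plate <- assayPlate(plate)
  pc <- mean(plate$luminescence[plate$role == "PC"])
  vc <- mean(plate$luminescence[plate$role == "VC_control"])
  denom <- pc - vc
  if (abs(denom) <= tol * max(abs(pc), 1)) {
    stop("assay invalid: PC and VC_control are indistinguishable")
  }
  if (!is.null(qcFold) && vc > 0 && pc / vc < qcFold) {
    warning(sprintf("PC/VC induction %.2f-fold is below the QC threshold %.1f",
                    pc / vc, qcFold))
  }
  vcTest <- tapply(plate$luminescence[plate$role == "VC_test"],
                   plate$arm[plate$role == "VC_test"], mean)
  tests <- plate[plate$role == "test", , drop = FALSE]
  if (nrow(tests) == 0) {
    return(data.frame(compound = character(0), arm = character(0),
                      dose_molar = numeric(0), rta_percent = numeric(0),
                      sd_percent = numeric(0), n = integer(0)))
  }
  anchor <- vcTest[tests$arm]
  anchor[is.na(anchor)] <- vc  # arm without its own VC falls back to VC_control
  tests$rta_rep <- 100 * (tests$luminescence - anchor) / denom
  key <- interaction(tests$compound, tests$arm, tests$dose_molar, drop = TRUE)
  agg <- lapply(split(tests, key), function(d) {
    spread <- stats::sd(d$rta_rep)
    if (sem) spread <- spread / sqrt(nrow(d))
    data.frame(compound = d$compound[1], arm = d$arm[1],
               dose_molar = d$dose_molar[1],
               rta_percent = mean(d$rta_rep),
               sd_percent = spread, n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$compound, out$arm, out$dose_molar), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agonist positivity call
#'
#' A compound/arm is called agonist-positive when its RTA reaches the
#' threshold (default 10% of the positive control) at any dose — the call is
#' inclusive (greater than or equal). The verdict records the dose of
#' maximal activity.
#'
#' @param results RTA table from \code{\link{rta}}.
#' @param threshold Positivity threshold in % of PC (default 10).
#' @return \code{data.frame} with \code{compound}, \code{arm},
#'   \code{positive}, \code{max_rta_percent}, \code{max_rta_dose}.
#' @export
callAgonist <- function(results, threshold = 10) {
  stopifnot(nrow(results) > 0)
  key <- interaction(results$compound, results$arm, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    j <- which.max(d$rta_percent)
    data.frame(compound = d$compound[1], arm = d$arm[1],
               positive = any(d$rta_percent >= threshold),
               max_rta_percent = d$rta_percent[j],
               max_rta_dose = d$dose_molar[j],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare activity between two treatment arms
#'
#' Per compound/dose, the RTA difference \code{arm_b - arm_a} with the
#' spread of the difference propagated from the per-arm spreads
#' (\code{sqrt(sd_a^2 + sd_b^2)}).
#'
#' @param results RTA table from \code{\link{rta}}.
#' @param armA,armB Arm labels to compare (delta is B minus A).
#' @return \code{data.frame} with \code{compound}, \code{dose_molar},
#'   \code{rta_a}, \code{rta_b}, \code{delta_rta}, \code{sd_delta}.
#' @export
compareArms <- function(results, armA, armB) {
  a <- results[results$arm == armA, , drop = FALSE]
  b <- results[results$arm == armB, , drop = FALSE]
  if (nrow(a) == 0) stop("arm '", armA, "' not present in results")
  if (nrow(b) == 0) stop("arm '", armB, "' not present in results")
  m <- merge(a, b, by = c("compound", "dose_molar"),
             suffixes = c("_a", "_b"))
  out <- data.frame(compound = m$compound, dose_molar = m$dose_molar,
                    rta_a = m$rta_percent_a, rta_b = m$rta_percent_b,
                    delta_rta = m$rta_percent_b - m$rta_percent_a,
                    sd_delta = sqrt(m$sd_percent_a^2 + m$sd_percent_b^2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound, out$dose_molar), , drop = FALSE]
  rownames(out) <- NULL
  out
}
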