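#' Log-transformed colony counts with detection-limit censoring
#'
#' Converts a plate count to log10 cfu/mL. Zero counts are reported at
#' the assay detection limit with a lower-censoring flag; the sentinel
#' `"TMTC"` (too many to count) gives an upper-censored result with no
#' numeric value.
#'
#' @param count colony count (non-negative number) or `"TMTC"`.
#' @param volume plated volume in mL (> 0).
#' @param dilution dilution factor applied to the plated aliquot (e.g.
#'   `1e-3`).
#' @param detectionLimit assay detection limit in cfu/mL.
#' @return list `value` (log10 cfu/mL, `NA` for TMTC) and `censored`
#'   (`"none"`, `"lower"`, `"upper"`).
#' @examples
#' logCfu(100, 0.1, 1e-3, 100)  # log10(1e6) = 6
#' @export
logCfu <- function(count, volume, dilution, detectionLimit = 100) {
  if (volume <= 0) stop("volume must be > 0")
  if (dilution <= 0) stop("dilution must be > 0")
  if (identical(count, "TMTC"))
    return(list(value = NA_real_, censored = "upper"))
  count <- as.numeric(count)
  if (is.na(count) || count < 0) stop("count must be a non-negative number or 'TMTC'")
  if (count == 0)
    return(list(value = log10(detectionLimit), censored = "lower"))
  list(value = log10(count / (volume * dilution)), censored = "none")
}

#' Efficiency of plaquing (EOP)
#'
#' Fold change in plaque-forming units of a test condition relative to a
#' reference (the reference defines EOP = 1). A censored test titer
#' propagates as a bound.
#'
#' @param pfuTest,pfuRef titers (pfu/mL); `pfuRef` must be positive.
#' @param testCensored was the test titer at/below the detection limit?
#' @return list `eop` and `bound` (`"eq"`, or `"le"` when censored).
#' @export
eop <- function(pfuTest, pfuRef, testCensored = FALSE) {
  if (pfuRef <= 0) stop("reference titer must be > 0")
  list(eop = pfuTest / pfuRef, bound = if (testCensored) "le" else "eq")
}

mpnLogLik <- function(conc, positives, tubes, volumes) {
  pPos <- 1 - exp(-conc * volumes)
  pPos <- pmin(pmax(pPos, 1e-300), 1 - 1e-15)
  sum(positives * log(pPos) - (tubes - positives) * conc * volumes)
}

#' Most Probable Number titer from a dilution series
#'
#' Maximum-likelihood concentration under the Poisson single-hit model:
#' a tube inoculated with volume v at concentration c turns positive with
#' probability 1 - exp(-c v). The likelihood is maximized numerically
#' over log-concentration. An all-negative series is censored at zero
#' (upper bound set by the design); an all-positive series only bounds
#' the titer from below.
#'
#' @param positives integer vector, positive tubes per dilution level.
#' @param tubes integer vector, tubes inoculated per level.
#' @param volumes numeric vector, effective inoculum volume per tube at
#'   each level in mL (dilution factor times plated volume).
#' @return list `titer` (per mL), `censored` (`"none"`, `"upper"` when
#'   all-negative, `"lower"` when all-positive), `loglik`.
#' @examples
#' mpn(1, 3, 1)$titer  # -log(1 - 1/3) ~ 0.405
#' @export
mpn <- function(positives, tubes, volumes) {
  stopifnot(length(positives) == length(tubes),
            length(volumes) == length(tubes))
  if (any(positives > tubes) || any(positives < 0)) stop("positives must be in [0, tubes]")
  if (any(volumes <= 0)) stop("volumes must be > 0")
  if (all(positives == 0))
    return(list(titer = 0, censored = "upper", loglik = 0))
  if (all(positives == tubes)) {
    lo <- -log(1 - (sum(tubes) - 0.5) / sum(tubes)) / min(volumes)
    return(list(titer = lo, censored = "lower",
                loglik = mpnLogLik(lo, positives, tubes, volumes)))
  }
  opt <- stats::optimize(function(x) mpnLogLik(10^x, positives, tubes, volumes),
                         interval = c(-10, 12), maximum = TRUE, tol = 1e-10)
  list(titer = 10^opt$maximum, censored = "none", loglik = opt$objective)
}

#' Relative protospacer transcript level
#'
#' The log10 count of RNA-derived reads for a construct normalized to the
#' log10 count of identical DNA-derived reads. This is a relative
#' incidence across constructs, not a per-cell transcript-to-template
#' ratio (doubling both counts changes the value). Counts below the floor
#' (default 10, guarding the log of small counts) give an undefined
#' result with a flag.
#'
#' @param rnaReads,dnaReads read counts.
#' @param floor minimum count for a defined result.
#' @return list `value` (log10(rna)/log10(dna), `NA` when undefined) and
#'   `defined`.
#' @export
relativeTranscriptLevel <- function(rnaReads, dnaReads, floor = 10) {
  if (rnaReads < floor || dnaReads < floor)
    return(list(value = NA_real_, defined = FALSE))
  list(value = log10(rnaReads) / log10(dnaReads), defined = TRUE)
}
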