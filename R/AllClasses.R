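#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges strand start end width seqnames
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

VALID_PAM_CONVENTIONS <- c("five_prime_of_protospacer", "three_prime_of_protospacer")

#' Run configuration for the cross-system CRISPR pipeline
#'
#' Holds the fixed constants of the analysis: the canonical PAM and which
#' side of the protospacer it is read from, the PAM-proximal seed window,
#' mismatch ceilings, the repeat-derived 5' handle length, the 5-nt anchor
#' and 12-nt junction cutoff used by the small-RNA read classifier, and the
#' Monte Carlo sampling design (sample size and trial count) for the
#' acquisition null envelope.
#'
#' @slot seed integer master seed; every stochastic stage forks a stream
#'   from it by stage name (see [stageSeed()]).
#' @slot pamConvention which flank of the protospacer carries the PAM, on
#'   the protospacer-containing strand.
#' @slot pamCanonical canonical PAM dinucleotide (type I-F uses GG).
#' @slot seedRegion 1-based inclusive position range within the
#'   protospacer, counted from the PAM-proximal end.
#' @slot maxMismatches maximum Hamming mismatches for a reportable match.
#' @slot minTrimmedJunctionLen trimmed reads shorter than this are tested
#'   for a spacer-repeat junction instead of being accepted directly.
#' @slot repeatAnchorLen length of the repeat 5' prefix used as the anchor
#'   when trimming small-RNA reads.
#' @slot handleLen length of the repeat-derived 5' crRNA handle.
#' @slot susSampleSize,susTrials stochastic universal sampling design for
#'   the null envelope (spacers per trial, number of trials).
#' @slot structuralMinLen indel length at or above which an event is
#'   classed as structural.
#' @slot foldThreshold fold enrichment of the modal trimmed-length bin
#'   (test over control) required to call processing detected.
#' @slot flankIdentityMin number of identical positions (out of handleLen)
#'   required to call a protospacer flank "self".
#' @slot geneOverlapFrac fraction of a spacer that must lie inside a gene
#'   for orientation assignment.
#' @slot orfMinLen minimum ORF length (nt) for the fallback 6-frame caller.
#' @slot detectionLimits named numeric of per-assay detection limits.
#' @export
setClass("RunConfig", representation(
  seed = "integer",
  pamConvention = "character",
  pamCanonical = "character",
  seedRegion = "integer",
  maxMismatches = "integer",
  minTrimmedJunctionLen = "integer",
  repeatAnchorLen = "integer",
  handleLen = "integer",
  susSampleSize = "integer",
  susTrials = "integer",
  structuralMinLen = "integer",
  foldThreshold = "numeric",
  flankIdentityMin = "integer",
  geneOverlapFrac = "numeric",
  orfMinLen = "integer",
  detectionLimits = "numeric"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (!object@pamConvention %in% VALID_PAM_CONVENTIONS)
    msg <- c(msg, sprintf("pamConvention must be one of: %s",
                          paste(VALID_PAM_CONVENTIONS, collapse = ", ")))
  if (!grepl("^[ACGT]{2}$", object@pamCanonical))
    msg <- c(msg, "pamCanonical must be a 2-letter DNA string over ACGT")
  if (length(object@seedRegion) != 2L || object@seedRegion[1] < 1L ||
      object@seedRegion[2] < object@seedRegion[1])
    msg <- c(msg, "seedRegion must be an ordered 1-based range c(first, last) with first >= 1")
  if (object@maxMismatches < 0L) msg <- c(msg, "maxMismatches must be >= 0")
  if (object@repeatAnchorLen < 1L) msg <- c(msg, "repeatAnchorLen must be >= 1")
  if (object@handleLen < 1L) msg <- c(msg, "handleLen must be >= 1")
  if (object@susSampleSize < 1L || object@susTrials < 1L)
    msg <- c(msg, "susSampleSize and susTrials must be >= 1")
  if (object@flankIdentityMin > object@handleLen)
    msg <- c(msg, "flankIdentityMin cannot exceed handleLen")
  if (object@geneOverlapFrac <= 0 || object@geneOverlapFrac > 1)
    msg <- c(msg, "geneOverlapFrac must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' All arguments default to the values of the study system: a GG PAM read
#' 5' of the protospacer, seed positions 1-8 from the PAM-proximal end, up
#' to 5 mismatches, an 8-nt crRNA handle, a 5-nt repeat anchor with a
#' 12-nt junction cutoff for read trimming, and a 500-spacer x 1000-trial
#' sampling design for the Monte Carlo null.
#'
#' @param seed integer master seed.
#' @param pamConvention `"five_prime_of_protospacer"` (default) or
#'   `"three_prime_of_protospacer"`.
#' @param pamCanonical canonical PAM dinucleotide.
#' @param seedRegion integer length-2, 1-based inclusive PAM-proximal range.
#' @param maxMismatches,minTrimmedJunctionLen,repeatAnchorLen,handleLen
#'   integer scalars, see slot docs.
#' @param susSampleSize,susTrials Monte Carlo design.
#' @param structuralMinLen structural-variant length threshold (bp).
#' @param foldThreshold processing-detection fold threshold.
#' @param flankIdentityMin identical flank positions required for "self".
#' @param geneOverlapFrac spacer-in-gene overlap fraction for orientation.
#' @param orfMinLen minimum ORF length for the fallback ORF caller.
#' @param detectionLimits named numeric of assay detection limits.
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- runConfig(seed = 1)
#' pamCanonical(cfg)
#' @export
runConfig <- function(seed = 1L,
                      pamConvention = "five_prime_of_protospacer",
                      pamCanonical = "GG",
                      seedRegion = c(1L, 8L),
                      maxMismatches = 5L,
                      minTrimmedJunctionLen = 12L,
                      repeatAnchorLen = 5L,
                      handleLen = 8L,
                      susSampleSize = 500L,
                      susTrials = 1000L,
                      structuralMinLen = 50L,
                      foldThreshold = 5,
                      flankIdentityMin = handleLen,
                      geneOverlapFrac = 0.5,
                      orfMinLen = 150L,
                      detectionLimits = c(cfu = 100, pfu = 100)) {
  new("RunConfig",
      seed = as.integer(seed),
      pamConvention = pamConvention,
      pamCanonical = toupper(pamCanonical),
      seedRegion = as.integer(seedRegion),
      maxMismatches = as.integer(maxMismatches),
      minTrimmedJunctionLen = as.integer(minTrimmedJunctionLen),
      repeatAnchorLen = as.integer(repeatAnchorLen),
      handleLen = as.integer(handleLen),
      susSampleSize = as.integer(susSampleSize),
      susTrials = as.integer(susTrials),
      structuralMinLen = as.integer(structuralMinLen),
      foldThreshold = foldThreshold,
      flankIdentityMin = as.integer(flankIdentityMin),
      geneOverlapFrac = geneOverlapFrac,
      orfMinLen = as.integer(orfMinLen),
      detectionLimits = detectionLimits)
}

#' @describeIn runConfig canonical PAM accessor
#' @param x a `RunConfig`
#' @export
setGeneric("pamCanonical", function(x) standardGeneric("pamCanonical"))

#' @export
setMethod("pamCanonical", "RunConfig", function(x) x@pamCanonical)

#' @describeIn runConfig seed-region accessor
#' @export
setGeneric("seedRegion", function(x) standardGeneric("seedRegion"))

#' @export
setMethod("seedRegion", "RunConfig", function(x) x@seedRegion)

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  PAM:", object@pamCanonical, "(", object@pamConvention, ")\n")
  cat("  seed region:", object@seedRegion[1], "-", object@seedRegion[2],
      " max mismatches:", object@maxMismatches, "\n")
  cat("  handle:", object@handleLen, "nt  anchor:", object@repeatAnchorLen,
      "nt  junction cutoff:", object@minTrimmedJunctionLen, "nt\n")
  cat("  SUS design:", object@susSampleSize, "spacers x",
      object@susTrials, "trials\n")
})

#' CRISPR array: repeat plus ordered spacers
#'
#' A CRISPR array is a run of identical direct repeats separated by the
#' ordered spacers acquired by the host. Both the type I-F-like and the
#' type III-B-like arrays of the study host are instances.
#'
#' @slot arrayName identifier, e.g. `"CRISPR04"`.
#' @slot repeatSeq the direct repeat ([Biostrings::DNAString]).
#' @slot spacers ordered spacers ([Biostrings::DNAStringSet]), unique
#'   within the array.
#' @export
setClass("CrisprArray", representation(
  arrayName = "character",
  repeatSeq = "DNAString",
  spacers = "DNAStringSet"
))

setValidity("CrisprArray", function(object) {
  msg <- character(0)
  if (length(object@arrayName) != 1L) msg <- c(msg, "arrayName must be a single string")
  if (length(object@repeatSeq) < 1L) msg <- c(msg, "repeat must be non-empty")
  sp <- as.character(object@spacers)
  if (anyDuplicated(sp)) msg <- c(msg, "spacer sequences must be unique within an array")
  if (length(msg)) msg else TRUE
})

#' Construct a CrisprArray
#'
#' @param arrayName identifier string.
#' @param repeatSeq direct repeat (character or DNAString).
#' @param spacers spacers (character vector or DNAStringSet), ordered.
#' @return A [CrisprArray-class].
#' @examples
#' arr <- crisprArray("CRISPR04", strrep("ACGT", 7),
#'                    c(s1 = paste(rep("A", 32), collapse = "")))
#' repeatSeq(arr)
#' @export
crisprArray <- function(arrayName, repeatSeq, spacers) {
  sp <- DNAStringSet(toupper(as.character(spacers)))
  if (is.null(names(sp)))
    names(sp) <- sprintf("%s_sp%02d", arrayName, seq_along(sp))
  new("CrisprArray", arrayName = arrayName,
      repeatSeq = DNAString(toupper(as.character(repeatSeq))),
      spacers = sp)
}

#' @describeIn crisprArray repeat accessor
#' @param x a `CrisprArray`
#' @export
setGeneric("repeatSeq", function(x) standardGeneric("repeatSeq"))

#' @export
setMethod("repeatSeq", "CrisprArray", function(x) x@repeatSeq)

#' @describeIn crisprArray spacer accessor
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' @export
setMethod("spacers", "CrisprArray", function(x) x@spacers)

#' @describeIn crisprArray array-name accessor
#' @export
setGeneric("arrayName", function(x) standardGeneric("arrayName"))

#' @export
setMethod("arrayName", "CrisprArray", function(x) x@arrayName)

setMethod("show", "CrisprArray", function(object) {
  cat("CrisprArray", object@arrayName, "\n")
  cat("  repeat (", length(object@repeatSeq), " nt): ",
      as.character(object@repeatSeq), "\n", sep = "")
  cat("  spacers:", length(object@spacers), "\n")
})

#' Annotated genome: sequence plus stranded gene features
#'
#' The reference against which acquired spacers and protospacers are
#' interpreted: a genome sequence and its gene annotation (with an
#' optional per-gene expression value in the `expr` metadata column).
#'
#' @slot genome a [Biostrings::DNAStringSet] (one or more sequences).
#' @slot genes a [GenomicRanges::GRanges] with `gene_id` and optionally
#'   `expr` metadata columns; 1-based inclusive coordinates.
#' @export
setClass("AnnotatedGenome", representation(
  genome = "DNAStringSet",
  genes = "GRanges"
))

setValidity("AnnotatedGenome", function(object) {
  msg <- character(0)
  if (length(object@genome) < 1L) msg <- c(msg, "genome must contain at least one sequence")
  if (is.null(names(object@genome))) msg <- c(msg, "genome sequences must be named")
  if (length(object@genes)) {
    sq <- as.character(seqnames(object@genes))
    if (!all(sq %in% names(object@genome)))
      msg <- c(msg, "gene seqnames must name genome sequences")
    lens <- width(object@genome)[match(sq, names(object@genome))]
    if (any(end(object@genes) > lens) || any(start(object@genes) < 1L))
      msg <- c(msg, "gene coordinates must lie within the genome")
    if (is.null(mcols(object@genes)$gene_id))
      msg <- c(msg, "genes must carry a gene_id metadata column")
    if (any(!as.character(strand(object@genes)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be + or -")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param genome DNAStringSet (or character vector) of genome sequences.
#' @param genes GRanges of gene features with a `gene_id` metadata column
#'   and optionally `expr`.
#' @return An [AnnotatedGenome-class].
#' @export
annotatedGenome <- function(genome, genes = GRanges()) {
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(toupper(genome))
  new("AnnotatedGenome", genome = genome, genes = genes)
}

#' @describeIn annotatedGenome genome sequence accessor
#' @param x an `AnnotatedGenome`
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @export
setMethod("genomeSeq", "AnnotatedGenome", function(x) x@genome)

#' @describeIn annotatedGenome gene annotation accessor
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @export
setMethod("geneRanges", "AnnotatedGenome", function(x) x@genes)

#' @describeIn annotatedGenome fraction of genome bases inside annotated
#'   genes (union of gene footprints; the complement is the intergenic
#'   fraction that denies strand assignment to spacers).
#' @export
setGeneric("annotatedFraction", function(x) standardGeneric("annotatedFraction"))

#' @export
setMethod("annotatedFraction", "AnnotatedGenome", function(x) {
  if (!length(x@genes)) return(0)
  covered <- sum(width(GenomicRanges::reduce(x@genes, ignore.strand = TRUE)))
  covered / sum(width(x@genome))
})

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@genome), "sequence(s),",
      sum(width(object@genome)), "bp\n")
  cat("  genes:", length(object@genes),
      sprintf(" (%.1f%% of bases annotated)\n", 100 * annotatedFraction(object)))
})
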