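#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
NULL

longestIncreasingIdx <- function(x) {
  # indices of a longest strictly increasing subsequence (patience sorting)
  n <- length(x)
  if (!n) return(integer(0))
  if (all(diff(x) > 0)) return(seq_len(n))
  tailsVal <- rep(Inf, n)   # padded so findInterval never needs subsetting
  tailsIdx <- integer(n); prev <- integer(n); m <- 0L
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 0.5, tailsVal) + 1L  # first tail >= x[i]
    prev[i] <- if (pos > 1L) tailsIdx[pos - 1L] else 0L
    tailsVal[pos] <- x[i]
    tailsIdx[pos] <- i
    m <- max(m, pos)
  }
  out <- integer(0); k <- tailsIdx[m]
  while (k > 0L) { out <- c(k, out); k <- prev[k] }
  out
}

alignGapEvents <- function(refGap, altGap, refOffset) {
  # resolve a short non-identical region by global alignment; returns
  # variant rows with positions on the reference
  al <- pairwiseAlignment(refGap, altGap, type = "global",
                          gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  refPos <- cumsum(p != "-")
  diffCol <- p != s
  rows <- list()
  i <- 1L
  while (i <= length(p)) {
    if (!diffCol[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(p) && diffCol[j + 1L]) j <- j + 1L
    refPart <- paste(p[i:j][p[i:j] != "-"], collapse = "")
    altPart <- paste(s[i:j][s[i:j] != "-"], collapse = "")
    if (nchar(refPart) == 1L && nchar(altPart) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "SNV", pos = refOffset + refPos[i], end = refOffset + refPos[i],
        ref = refPart, alt = altPart, length = 1L)
    } else if (nchar(altPart) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "deletion", pos = refOffset + refPos[i],
        end = refOffset + refPos[j],
        ref = refPart, alt = "-", length = nchar(refPart))
    } else if (nchar(refPart) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "insertion", pos = refOffset + if (i > 1L) refPos[i - 1L] else 0L,
        end = refOffset + if (i > 1L) refPos[i - 1L] else 0L,
        ref = "-", alt = altPart, length = nchar(altPart))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "complex", pos = refOffset + refPos[i],
        end = refOffset + refPos[j],
        ref = refPart, alt = altPart, length = nchar(refPart))
    }
    i <- j + 1L
  }
  do.call(rbind, rows)
}

#' Call variants between two collinear near-identical genomes
#'
#' Partitions the two genomes into matched blocks by chaining k-mers that
#' are unique in both sequences (k = 21); out-of-order anchors (a
#' rearrangement signature) are removed by a longest-increasing-
#' subsequence filter and flagged. Inter-block gaps are resolved by
#' global alignment when short, or reported directly as
#' insertion/deletion events when one side is empty. A contiguous
#' multi-base event counts as one site; deletions at or above the
#' structural threshold (default 50 bp) are typed `structural_deletion`
#' with their breakpoints. Indels are left-normalized so equivalent
#' placements compare identically.
#'
#' @param reference,variant DNAStringSet / character genomes.
#' @param config a [RunConfig-class].
#' @param k anchor k-mer size.
#' @return list with `variants` (data.frame `type, pos, end, ref, alt,
#'   length`, 1-based on the reference) and `rearrangement_flag`.
#' @export
diffGenomes <- function(reference, variant, config = runConfig(), k = 21L) {
  toChr <- function(g) {
    if (is(g, "DNAStringSet")) g <- g[[1]]
    toupper(as.character(g))
  }
  refChr <- toChr(reference); altChr <- toChr(variant)
  empty <- data.frame(type = character(0), pos = integer(0), end = integer(0),
                      ref = character(0), alt = character(0), length = integer(0))
  if (identical(refChr, altChr))
    return(list(variants = empty, rearrangement_flag = FALSE))

  kmerMap <- function(chr) {
    n <- nchar(chr) - k + 1L
    km <- substring(chr, seq_len(n), seq_len(n) + k - 1L)
    uniq <- !(duplicated(km) | duplicated(km, fromLast = TRUE))
    list(kmers = km[uniq], pos = which(uniq))
  }
  rm_ <- kmerMap(refChr); am <- kmerMap(altChr)
  m <- match(rm_$kmers, am$kmers)
  keep <- !is.na(m)
  refPos <- rm_$pos[keep]; altPos <- am$pos[m[keep]]
  if (!length(refPos)) {
    warning("no shared unique anchors; genomes too divergent for chaining")
    return(list(variants = empty, rearrangement_flag = TRUE))
  }
  lis <- longestIncreasingIdx(altPos)
  rearr <- length(lis) < length(altPos) * 0.9
  refPos <- refPos[lis]; altPos <- altPos[lis]

  # collapse anchors into identity blocks: constant offset and overlap/adjacency
  off <- altPos - refPos
  newBlock <- c(TRUE, off[-1] != off[-length(off)] |
                  refPos[-1] > refPos[-length(refPos)] + k)
  blockId <- cumsum(newBlock)
  bRefStart <- unname(tapply(refPos, blockId, min))
  bRefEnd <- unname(tapply(refPos, blockId, max)) + k - 1L
  bAltStart <- unname(tapply(altPos, blockId, min))
  bAltEnd <- unname(tapply(altPos, blockId, max)) + k - 1L
  nb <- length(bRefStart)
  # an anchor k-mer that coincidentally spans a variant can extend a block
  # into the next one's territory; trim such overlaps so every inter-block
  # gap is non-negative in both genomes
  if (nb > 1L) for (i in seq_len(nb - 1L)) {
    ovl <- max(bRefEnd[i] - bRefStart[i + 1L] + 1L,
               bAltEnd[i] - bAltStart[i + 1L] + 1L, 0L)
    if (ovl > 0L) {
      bRefEnd[i] <- bRefEnd[i] - ovl
      bAltEnd[i] <- bAltEnd[i] - ovl
    }
  }
  keepB <- bRefEnd >= bRefStart & bAltEnd >= bAltStart
  bRefStart <- bRefStart[keepB]; bRefEnd <- bRefEnd[keepB]
  bAltStart <- bAltStart[keepB]; bAltEnd <- bAltEnd[keepB]
  nb <- length(bRefStart)

  rows <- list()
  gapBounds <- data.frame(
    refFrom = c(1L, bRefEnd + 1L), refTo = c(bRefStart - 1L, nchar(refChr)),
    altFrom = c(1L, bAltEnd + 1L), altTo = c(bAltStart - 1L, nchar(altChr)))
  for (gi in seq_len(nrow(gapBounds))) {
    rf <- gapBounds$refFrom[gi]; rt <- gapBounds$refTo[gi]
    af <- gapBounds$altFrom[gi]; at <- gapBounds$altTo[gi]
    refGap <- if (rt >= rf) substring(refChr, rf, rt) else ""
    altGap <- if (at >= af) substring(altChr, af, at) else ""
    if (!nchar(refGap) && !nchar(altGap)) next
    if (identical(refGap, altGap)) next
    if (!nchar(altGap)) {
      nrm <- leftNormalizeIndel(refChr, rf, rt)
      len <- rt - rf + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        type = if (len >= config@structuralMinLen) "structural_deletion" else "deletion",
        pos = nrm[1], end = nrm[2],
        ref = substring(refChr, nrm[1], nrm[2]), alt = "-", length = len)
    } else if (!nchar(refGap)) {
      nrm <- leftNormalizeIndel(refChr, rf - 1L, NA, inserted = altGap)
      rows[[length(rows) + 1L]] <- data.frame(
        type = if (nchar(altGap) >= config@structuralMinLen)
          "structural_insertion" else "insertion",
        pos = nrm$pos, end = nrm$pos, ref = "-", alt = nrm$alt,
        length = nchar(altGap))
    } else if (nchar(refGap) <= 5000L && nchar(altGap) <= 5000L) {
      ev <- alignGapEvents(refGap, altGap, rf - 1L)
      if (!is.null(ev)) rows[[length(rows) + 1L]] <- ev
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "complex", pos = rf, end = rt, ref = "", alt = "",
        length = rt - rf + 1L)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, rearrangement_flag = rearr)
}

#' Reconstruct a variant genome from reference plus calls
#'
#' Applies SNVs, insertions and deletions (right to left). Used to verify
#' the round-trip property of [diffGenomes()].
#'
#' @param reference reference genome (character / DNAString(Set)).
#' @param variants data.frame of calls in [diffGenomes()] format.
#' @return character genome.
#' @export
applyVariants <- function(reference, variants) {
  if (is(reference, "DNAStringSet")) reference <- reference[[1]]
  chr <- toupper(as.character(reference))
  if (!nrow(variants)) return(chr)
  v <- variants[order(-variants$pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "SNV" || v$type[i] == "complex") {
      chr <- paste0(substring(chr, 1L, v$pos[i] - 1L), v$alt[i],
                    substring(chr, v$end[i] + 1L, nchar(chr)))
    } else if (v$type[i] %in% c("insertion", "structural_insertion")) {
      chr <- paste0(substring(chr, 1L, v$pos[i]), v$alt[i],
                    substring(chr, v$pos[i] + 1L, nchar(chr)))
    } else {
      chr <- paste0(substring(chr, 1L, v$pos[i] - 1L),
                    substring(chr, v$end[i] + 1L, nchar(chr)))
    }
  }
  chr
}

#' Classify escape mutations against protospacer loci
#'
#' For each protospacer (reference coordinates, strand and PAM side), the
#' highest-priority event among the variant calls decides the class:
#' a deletion containing the whole protospacer interval >
#' `deletion_spanning_protospacer`; an SNV in the PAM positions >
#' `pam_mutation`; a substitution at seed positions > `seed_substitution`;
#' an indel touching seed positions > `seed_frameshift`; any other change
#' inside the protospacer > `non_seed_change`; otherwise `none`.
#'
#' @param variants data.frame of calls from [diffGenomes()].
#' @param protospacers data.frame with columns `protospacer, start, end,
#'   strand` (e.g. the truth table of [generatePhage()] or annotated
#'   matches from [scanArray()]).
#' @param config a [RunConfig-class].
#' @return data.frame `protospacer, escape_class`.
#' @export
classifyEscape <- function(variants, protospacers, config = runConfig()) {
  sr <- config@seedRegion
  fivePrime <- config@pamConvention == "five_prime_of_protospacer"
  n <- nrow(protospacers)
  cls <- character(n)
  for (i in seq_len(n)) {
    ps <- protospacers$start[i]; pe <- protospacers$end[i]
    strand <- protospacers$strand[i]
    pamProximalLeft <- (strand == "+") == fivePrime
    if (pamProximalLeft) {
      seedLo <- ps + sr[1] - 1L; seedHi <- ps + sr[2] - 1L
      pamPos <- c(ps - 2L, ps - 1L)
    } else {
      seedLo <- pe - sr[2] + 1L; seedHi <- pe - sr[1] + 1L
      pamPos <- c(pe + 1L, pe + 2L)
    }
    out <- "none"
    if (nrow(variants)) {
      isDel <- variants$type %in% c("deletion", "structural_deletion")
      spanning <- isDel & variants$pos <= ps & variants$end >= pe
      inSeed <- variants$pos <= seedHi & variants$end >= seedLo
      inPs <- variants$pos <= pe & variants$end >= ps
      isIndel <- variants$type %in% c("insertion", "structural_insertion",
                                      "deletion", "structural_deletion")
      pamHit <- variants$type == "SNV" & variants$pos %in% pamPos
      if (any(spanning)) out <- "deletion_spanning_protospacer"
      else if (any(pamHit)) out <- "pam_mutation"
      else if (any(variants$type == "SNV" & inSeed)) out <- "seed_substitution"
      else if (any(isIndel & inSeed)) out <- "seed_frameshift"
      else if (any(inPs)) out <- "non_seed_change"
    }
    cls[i] <- out
  }
  data.frame(protospacer = protospacers$protospacer, escape_class = cls)
}

#' In-silico PCR with exact primer matching
#'
#' Finds amplicons where the forward primer matches the plus strand and
#' the reverse primer's reverse complement matches downstream on the plus
#' strand, plus the symmetric orientation (amplicon on the minus strand,
#' reported in plus coordinates). Product length includes both primers.
#'
#' @param genome template (character / DNAString(Set)).
#' @param fwd,rev primer sequences (>= 15 nt).
#' @param maxProduct maximum product length in bp.
#' @return data.frame `start, end, length` (empty when no product).
#' @export
insilicoPcr <- function(genome, fwd, rev, maxProduct = 5000L) {
  if (is(genome, "DNAStringSet")) genome <- genome[[1]]
  if (is.character(genome)) genome <- DNAString(toupper(genome))
  fwd <- toupper(as.character(fwd)); rev <- toupper(as.character(rev))
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 nt")
  prods <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  pair <- function(p1, p2) {
    s1 <- matchPattern(p1, genome, fixed = TRUE)
    s2 <- matchPattern(revcompChr(p2), genome, fixed = TRUE)
    out <- list()
    for (i in seq_along(s1)) for (j in seq_along(s2)) {
      f <- start(s1)[i]; e <- end(s2)[j]
      if (start(s2)[j] > end(s1)[i] && e - f + 1L <= maxProduct)
        out[[length(out) + 1L]] <- data.frame(start = f, end = e,
                                              length = e - f + 1L)
    }
    do.call(rbind, out)
  }
  prods <- rbind(prods, pair(fwd, rev), pair(rev, fwd))
  prods <- unique(prods)
  prods[order(prods$start), , drop = FALSE]
}

#' Global protein comparison: identity, similarity, C-terminal loss
#'
#' Needleman-Wunsch global alignment with BLOSUM62. Identity is the
#' fraction of alignment columns with identical residues; similarity the
#' fraction with a positive substitution score; C-terminal loss is the
#' number of reference residues past the last reference position aligned
#' to a non-gap in the query (e.g. residues lost to premature
#' termination after a frameshift).
#'
#' @param refProtein,altProtein amino-acid sequences (character /
#'   AAString).
#' @return list `percent_identity, percent_similarity, cterm_loss`.
#' @export
compareProteins <- function(refProtein, altProtein) {
  refChr <- toupper(as.character(refProtein))
  altChr <- toupper(as.character(altProtein))
  if (!nchar(refChr) || !nchar(altChr)) stop("protein sequences must be non-empty")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  al <- pairwiseAlignment(Biostrings::AAString(refChr),
                          Biostrings::AAString(altChr),
                          type = "global", substitutionMatrix = mat,
                          gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  alen <- length(p)
  ident <- sum(p == s & p != "-")
  bothRes <- p != "-" & s != "-"
  simil <- sum(vapply(which(bothRes), function(i)
    mat[p[i], s[i]] > 0, logical(1)))
  refPosAtCol <- cumsum(p != "-")
  lastAligned <- which(bothRes)
  ctermLoss <- if (length(lastAligned))
    nchar(refChr) - refPosAtCol[max(lastAligned)] else nchar(refChr)
  list(percent_identity = 100 * ident / alen,
       percent_similarity = 100 * simil / alen,
       cterm_loss = ctermLoss)
}

#' Translate a DNA ORF to protein (standard code, stops at first stop)
#'
#' @param dna ORF sequence starting at the first codon.
#' @return character amino-acid sequence.
#' @export
translateOrf <- function(dna) {
  dna <- toupper(as.character(dna))
  dna <- substring(dna, 1L, (nchar(dna) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(DNAString(dna),
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}
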