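#' Extract the PAM of a protospacer match
#'
#' Reads the two bases flanking the match on the protospacer-containing
#' strand, on the side named by the configuration (default: the two bases
#' immediately 5' of the protospacer). Matches at the genome edge, where
#' the PAM bases do not exist, return `NA`.
#'
#' @param genomeChr genome sequence (character).
#' @param start,end 1-based inclusive match coordinates.
#' @param strand `"+"` or `"-"` (strand the spacer sequence matches).
#' @param config a [RunConfig-class].
#' @return 2-letter string, or `NA_character_` when unavailable.
#' @export
extractPam <- function(genomeChr, start, end, strand, config = runConfig()) {
  L <- nchar(genomeChr)
  fivePrime <- config@pamConvention == "five_prime_of_protospacer"
  upstream <- (strand == "+") == fivePrime
  if (upstream) {
    if (start - 2L < 1L) return(NA_character_)
    p <- substring(genomeChr, start - 2L, start - 1L)
  } else {
    if (end + 2L > L) return(NA_character_)
    p <- substring(genomeChr, end + 1L, end + 2L)
  }
  if (strand == "-") p <- revcompChr(p)
  p
}

#' Scan a genome for protospacers matching a spacer
#'
#' Reports every placement on either strand with Hamming distance at most
#' `maxMismatches` (no indels: protospacer matches are length-preserving).
#' Each match is annotated with its mismatch positions (1-based from the
#' PAM-proximal end), its PAM and whether it is canonical, and whether any
#' mismatch falls in the seed region. Results are sorted by (mismatches,
#' coordinate).
#'
#' @param spacer a spacer sequence (character or DNAString).
#' @param genome DNAStringSet / character phage or plasmid genome.
#' @param maxMismatches maximum Hamming distance (default from config).
#' @param config a [RunConfig-class].
#' @param spacerId id string recorded in the output.
#' @return data.frame `spacer_id, start, end, strand, mismatches,
#'   mismatch_positions, pam, pam_available, pam_canonical,
#'   seed_mismatch`.
#' @export
scanProtospacers <- function(spacer, genome, maxMismatches = NULL,
                             config = runConfig(), spacerId = "spacer") {
  if (is.null(maxMismatches)) maxMismatches <- config@maxMismatches
  if (is(genome, "DNAStringSet")) genome <- genome[[1]]
  if (is.character(genome)) genome <- DNAString(toupper(genome))
  spacerChr <- toupper(as.character(spacer))
  if (nchar(spacerChr) < config@seedRegion[2])
    stop("spacer shorter than the configured seed region")
  hits <- hammingHits(spacerChr, genome, maxMismatches)
  genomeChr <- as.character(genome)
  n <- nrow(hits)
  mmPos <- character(n); pam <- character(n); seedMm <- logical(n)
  sr <- seq(config@seedRegion[1], config@seedRegion[2])
  spVec <- strsplit(spacerChr, "")[[1]]
  for (i in seq_len(n)) {
    win <- substring(genomeChr, hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") win <- revcompChr(win)
    # window read 5'->3' on the match strand; position 1 is PAM-proximal
    # under the 5'-PAM convention, else counted from the 3' end
    diffs <- which(spVec != strsplit(win, "")[[1]])
    if (config@pamConvention == "three_prime_of_protospacer")
      diffs <- nchar(spacerChr) - diffs + 1L
    diffs <- sort(diffs)
    mmPos[i] <- paste(diffs, collapse = ",")
    seedMm[i] <- any(diffs %in% sr)
    pam[i] <- extractPam(genomeChr, hits$start[i], hits$end[i],
                         hits$strand[i], config)
  }
  out <- data.frame(spacer_id = rep(spacerId, n),
                    start = hits$start, end = hits$end,
                    strand = hits$strand, mismatches = hits$mismatches,
                    mismatch_positions = mmPos,
                    pam = pam, pam_available = !is.na(pam),
                    pam_canonical = !is.na(pam) & pam == config@pamCanonical,
                    seed_mismatch = seedMm)
  out <- out[order(out$mismatches, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orientation of a protospacer relative to the phage transcript
#'
#' A type III effector only engages when the crRNA can base-pair with the
#' nascent mRNA. That happens when the spacer matches the strand opposite
#' the overlapping ORF's coding strand (`antisense_crRNA_complementary`).
#' A spacer matching the coding strand yields a crRNA identical to the
#' mRNA (`sense_crRNA_noncomplementary`); a protospacer outside ORFs has
#' `no_transcript`.
#'
#' @param matches data.frame from [scanProtospacers()].
#' @param orfs GRanges of ORFs (with strand). When `NULL`, ORFs are
#'   called with [callOrfs()] on `genome`.
#' @param genome genome sequence (needed only when `orfs` is NULL).
#' @param config a [RunConfig-class].
#' @return `matches` with an `orientation_vs_transcript` column appended.
#' @export
orientationVsTranscript <- function(matches, orfs = NULL, genome = NULL,
                                    config = runConfig()) {
  if (is.null(orfs)) {
    if (is.null(genome)) stop("supply either orfs or a genome")
    orfs <- callOrfs(genome, minLen = config@orfMinLen)
  }
  n <- nrow(matches)
  orient <- rep("no_transcript", n)
  if (n && length(orfs)) {
    sq <- as.character(seqnames(orfs))[1]
    gr <- GRanges(sq, IRanges(matches$start, matches$end))
    ov <- GenomicRanges::findOverlaps(gr, orfs, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      ovw <- width(IRanges::pintersect(IRanges::ranges(gr)[qh],
                                       IRanges::ranges(orfs)[sh]))
      keep <- ovw >= config@geneOverlapFrac * width(gr)[qh]
      qh <- qh[keep]; sh <- sh[keep]; ovw <- ovw[keep]
      if (length(qh)) {
        o <- order(qh, -ovw)
        first <- !duplicated(qh[o])
        qh <- qh[o][first]; sh <- sh[o][first]
        same <- matches$strand[qh] == as.character(strand(orfs))[sh]
        orient[qh] <- ifelse(same, "sense_crRNA_noncomplementary",
                             "antisense_crRNA_complementary")
      }
    }
  }
  matches$orientation_vs_transcript <- orient
  matches
}

#' Self / non-self flank discrimination for type III targeting
#'
#' The crRNA 5' handle is the last `handleLen` bases of the repeat; in the
#' host's own CRISPR locus the sequence 5' of each protospacer-equivalent
#' (on the match strand) is exactly that repeat tail. Base-pairing between
#' handle and flank marks the target as "self" and suppresses type III
#' interference. A flank with at least `flankIdentityMin` of `handleLen`
#' positions identical to the repeat tail (default: all of them) is
#' classed `self`; flanks truncated by the genome edge are `non_self`
#' with a warning.
#'
#' @param matches data.frame from [scanProtospacers()].
#' @param genome genome (character / DNAString(Set)).
#' @param repeatSeq repeat of the array the spacer came from.
#' @param config a [RunConfig-class].
#' @return `matches` with a `flank_class` column appended.
#' @export
flankSelfCheck <- function(matches, genome, repeatSeq, config = runConfig()) {
  if (is(genome, "DNAStringSet")) genome <- genome[[1]]
  genomeChr <- toupper(as.character(genome))
  L <- nchar(genomeChr)
  hl <- config@handleLen
  repChr <- toupper(as.character(repeatSeq))
  handle <- substring(repChr, nchar(repChr) - hl + 1L, nchar(repChr))
  handleVec <- strsplit(handle, "")[[1]]
  cls <- character(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    if (matches$strand[i] == "+") {
      s <- matches$start[i] - hl
      if (s < 1L) {
        warning("flank truncated by genome edge; classed non_self")
        cls[i] <- "non_self"; next
      }
      fl <- substring(genomeChr, s, matches$start[i] - 1L)
    } else {
      e <- matches$end[i] + hl
      if (e > L) {
        warning("flank truncated by genome edge; classed non_self")
        cls[i] <- "non_self"; next
      }
      fl <- revcompChr(substring(genomeChr, matches$end[i] + 1L, e))
    }
    ident <- sum(strsplit(fl, "")[[1]] == handleVec)
    cls[i] <- if (ident >= config@flankIdentityMin) "self" else "non_self"
  }
  matches$flank_class <- cls
  matches
}

#' Predict per-system interference competence of a protospacer
#'
#' Type I-F interference is transcription-independent but PAM- and
#' seed-dependent: competent iff the PAM is canonical, no mismatch falls
#' in the seed region, and total mismatches stay within the ceiling.
#' Type III-B interference is PAM-irrelevant but transcription-dependent
#' and self-limited: competent iff the crRNA is complementary to the
#' transcript (antisense match), the flank is non-self, and total
#' mismatches stay within the ceiling. Every negative call carries its
#' reasons.
#'
#' @param matches fully annotated data.frame (after
#'   [orientationVsTranscript()] and [flankSelfCheck()]).
#' @param config a [RunConfig-class].
#' @return `matches` with `typeIF_competent`, `typeIIIB_competent` and
#'   `reasons` columns appended.
#' @export
predictInterference <- function(matches, config = runConfig()) {
  n <- nrow(matches)
  ifc <- logical(n); iiibc <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    okMm <- matches$mismatches[i] <= config@maxMismatches
    if (!okMm) r <- c(r, "too_many_mismatches")
    ifOk <- okMm
    if (!isTRUE(matches$pam_canonical[i])) { ifOk <- FALSE; r <- c(r, "pam_noncanonical") }
    if (isTRUE(matches$seed_mismatch[i])) { ifOk <- FALSE; r <- c(r, "seed_mismatch") }
    iiibOk <- okMm
    if (!identical(matches$orientation_vs_transcript[i],
                   "antisense_crRNA_complementary")) {
      iiibOk <- FALSE
      r <- c(r, if (identical(matches$orientation_vs_transcript[i],
                              "sense_crRNA_noncomplementary"))
        "sense_orientation" else "no_transcript")
    }
    if (identical(matches$flank_class[i], "self")) { iiibOk <- FALSE; r <- c(r, "self_flank") }
    ifc[i] <- ifOk; iiibc[i] <- iiibOk
    reasons[i] <- paste(unique(r), collapse = ";")
  }
  matches$typeIF_competent <- ifc
  matches$typeIIIB_competent <- iiibc
  matches$reasons <- reasons
  matches
}

#' Scan and fully annotate protospacers for a set of spacers
#'
#' Convenience wrapper chaining [scanProtospacers()],
#' [orientationVsTranscript()], [flankSelfCheck()] and
#' [predictInterference()] over every spacer of an array.
#'
#' @param array a [CrisprArray-class].
#' @param genome phage/plasmid genome.
#' @param orfs GRanges of ORFs (or NULL for the fallback caller).
#' @param config a [RunConfig-class].
#' @return one data.frame of annotated matches, all spacers combined.
#' @export
scanArray <- function(array, genome, orfs = NULL, config = runConfig()) {
  sp <- spacers(array)
  out <- lapply(seq_along(sp), function(i) {
    m <- scanProtospacers(sp[[i]], genome, config = config,
                          spacerId = names(sp)[i])
    if (!nrow(m)) return(m)
    m <- orientationVsTranscript(m, orfs = orfs, genome = genome, config = config)
    m <- flankSelfCheck(m, genome, repeatSeq(array), config)
    predictInterference(m, config)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimal 6-frame ORF caller
#'
#' Fallback transcript model when no annotation is available: reports
#' every ATG-to-stop open reading frame of at least `minLen` nt on both
#' strands.
#'
#' @param genome genome (character / DNAString(Set)).
#' @param minLen minimum ORF length in nt (including the stop codon).
#' @return GRanges of ORFs with strand and `gene_id`.
#' @export
callOrfs <- function(genome, minLen = 150L) {
  if (is(genome, "DNAStringSet")) { nm <- names(genome)[1]; genome <- genome[[1]] }
  else nm <- "genome"
  if (is.character(genome)) genome <- DNAString(toupper(genome))
  genomeChr <- as.character(genome)
  L <- nchar(genomeChr)
  stops <- c("TAA", "TAG", "TGA")
  findIn <- function(chr) {
    res <- data.frame(start = integer(0), end = integer(0))
    for (frame in 0:2) {
      starts <- seq(1L + frame, nchar(chr) - 2L, by = 3L)
      codons <- substring(chr, starts, starts + 2L)
      open <- NA_integer_
      for (j in seq_along(codons)) {
        if (is.na(open) && codons[j] == "ATG") open <- starts[j]
        else if (!is.na(open) && codons[j] %in% stops) {
          if (starts[j] + 2L - open + 1L >= minLen)
            res <- rbind(res, data.frame(start = open, end = starts[j] + 2L))
          open <- NA_integer_
        }
      }
    }
    res
  }
  fwd <- findIn(genomeChr)
  rev <- findIn(revcompChr(genomeChr))
  if (nrow(rev)) {
    tmp <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L)
    rev <- tmp
  }
  gr <- GRanges(nm, IRanges(c(fwd$start, rev$start), c(fwd$end, rev$end)),
                strand = rep(c("+", "-"), c(nrow(fwd), nrow(rev))))
  if (length(gr)) mcols(gr)$gene_id <- sprintf("orf%04d", seq_along(gr))
  gr
}
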