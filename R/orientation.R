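#' @importFrom Biostrings matchPattern
NULL

hammingHits <- function(patternChr, subject, maxMismatch) {
  # all fixed-length matches of pattern on both strands of `subject`
  # (a DNAString); minus-strand matches are located by matching the
  # reverse complement on the plus strand. N never matches (fixed = TRUE).
  fwd <- matchPattern(patternChr, subject, max.mismatch = maxMismatch,
                      fixed = TRUE)
  rev <- matchPattern(revcompChr(patternChr), subject,
                      max.mismatch = maxMismatch, fixed = TRUE)
  subjChr <- as.character(subject)
  mism <- function(v, s, e, rc) {
    win <- substring(subjChr, s, e)
    if (rc) win <- revcompChr(win)
    a <- strsplit(v, "")[[1]]
    vapply(strsplit(win, ""), function(b) sum(a != b), integer(1))
  }
  df <- data.frame(start = integer(0), end = integer(0),
                   strand = character(0), mismatches = integer(0))
  if (length(fwd))
    df <- rbind(df, data.frame(start = start(fwd), end = end(fwd),
                               strand = "+",
                               mismatches = mism(patternChr, start(fwd), end(fwd), FALSE)))
  if (length(rev))
    df <- rbind(df, data.frame(start = start(rev), end = end(rev),
                               strand = "-",
                               mismatches = mism(patternChr, start(rev), end(rev), TRUE)))
  df[df$mismatches <= maxMismatch, , drop = FALSE]
}

#' Map acquired spacers to a genome (best hit per spacer)
#'
#' Finds, for every spacer, the genomic placement with the fewest Hamming
#' mismatches on either strand. Ties are broken toward the leftmost hit on
#' the plus strand, then the leftmost on the minus strand (each acquired
#' spacer has a single true source, so one best hit is reported).
#' Spacers with no hit within `maxMismatches` are dropped and counted in
#' a message. The search escalates the allowed mismatch count from 0, so
#' exact spacers are found at exact-match speed.
#'
#' @param spacerSet named DNAStringSet (or character vector) of spacers.
#' @param genome DNAStringSet, [AnnotatedGenome-class], or character.
#' @param maxMismatches maximum Hamming distance.
#' @return data.frame `spacer_id, start, end, strand, mismatches`
#'   (1-based inclusive coordinates).
#' @export
mapSpacers <- function(spacerSet, genome, maxMismatches = 5L) {
  if (is(genome, "AnnotatedGenome")) genome <- genomeSeq(genome)
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(toupper(genome))
  subject <- genome[[1]]
  if (!is(spacerSet, "DNAStringSet")) spacerSet <- DNAStringSet(toupper(spacerSet))
  ids <- names(spacerSet)
  if (is.null(ids)) ids <- sprintf("sp%05d", seq_along(spacerSet))
  n <- length(spacerSet)
  rows <- vector("list", n)
  nDropped <- 0L

  # vectorized exact stage: all spacers of one width at once
  widths <- Biostrings::width(spacerSet)
  done <- logical(n)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(spacerSet[idx])
    fwd <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
    pdr <- Biostrings::PDict(reverseComplement(spacerSet[idx]))
    rev <- Biostrings::startIndex(Biostrings::matchPDict(pdr, subject))
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (length(fwd[[j]])) {
        s <- min(fwd[[j]])
        rows[[i]] <- data.frame(spacer_id = ids[i], start = s,
                                end = s + w - 1L, strand = "+", mismatches = 0L)
        done[i] <- TRUE
      } else if (length(rev[[j]])) {
        s <- min(rev[[j]])
        rows[[i]] <- data.frame(spacer_id = ids[i], start = s,
                                end = s + w - 1L, strand = "-", mismatches = 0L)
        done[i] <- TRUE
      }
    }
  }

  # escalating mismatch search for the rest
  for (i in which(!done)) {
    pat <- as.character(spacerSet[[i]])
    best <- NULL
    for (mm in seq_len(maxMismatches)) {
      h <- hammingHits(pat, subject, mm)
      if (nrow(h)) {
        h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
        h <- h[order(h$strand, h$start), , drop = FALSE]  # "+" < "-"
        best <- h[1, , drop = FALSE]
        break
      }
    }
    if (is.null(best)) { nDropped <- nDropped + 1L; next }
    rows[[i]] <- cbind(spacer_id = ids[i], best)
  }
  if (nDropped)
    message(nDropped, " spacer(s) had no hit within ", maxMismatches,
            " mismatches and were dropped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(spacer_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0))
  rownames(out) <- NULL
  out
}

#' Classify spacer hits as sense / antisense / unassigned
#'
#' A hit is assigned to a gene when at least `overlapFrac` of the spacer
#' lies inside it (the gene with the largest overlap wins). `sense` means
#' the spacer matches the gene's coding strand (its crRNA could not pair
#' with the mRNA); `antisense` means it matches the template strand (the
#' crRNA is complementary to the mRNA). Hits outside genes give no basis
#' for strand assignment and are `unassigned`.
#'
#' @param hits data.frame from [mapSpacers()].
#' @param genes GRanges of genes (or an [AnnotatedGenome-class]).
#' @param overlapFrac minimum in-gene fraction of the spacer.
#' @return `hits` with `gene_id` and `orientation` columns appended.
#' @export
classifyOrientation <- function(hits, genes, overlapFrac = 0.5) {
  if (is(genes, "AnnotatedGenome")) genes <- geneRanges(genes)
  n <- nrow(hits)
  geneId <- rep(NA_character_, n)
  orient <- rep("unassigned", n)
  if (n && length(genes)) {
    sq <- as.character(seqnames(genes))[1]
    hitGr <- GRanges(sq, IRanges(hits$start, hits$end))
    ov <- GenomicRanges::findOverlaps(hitGr, genes, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      ovw <- width(IRanges::pintersect(IRanges::ranges(hitGr)[qh],
                                       IRanges::ranges(genes)[sh]))
      keep <- ovw >= overlapFrac * width(hitGr)[qh]
      qh <- qh[keep]; sh <- sh[keep]; ovw <- ovw[keep]
      if (length(qh)) {
        o <- order(qh, -ovw)
        first <- !duplicated(qh[o])
        qh <- qh[o][first]; sh <- sh[o][first]
        geneId[qh] <- genes$gene_id[sh]
        sameStrand <- hits$strand[qh] == as.character(strand(genes))[sh]
        orient[qh] <- ifelse(sameStrand, "sense", "antisense")
      }
    }
  }
  hits$gene_id <- geneId
  hits$orientation <- orient
  hits
}

#' Strand-bias statistic for acquired spacers
#'
#' Computes, per sample and pooled, the fraction of spacers mapping to the
#' sense strand of host genes. The denominator is ALL mapped spacers,
#' including those outside genes: with ~11.4% of the genome outside
#' annotated genes, an unbiased process therefore yields ~44.3% sense
#' (not 50%), and the null expectation reported here is
#' (annotated fraction)/2. SEM across samples is reported when there are
#' at least two samples.
#'
#' @param hitsBySample a list of classified hit data.frames (one per
#'   sample, from [classifyOrientation()]), or a single data.frame.
#' @param host an [AnnotatedGenome-class] (for the annotation-derived
#'   null), or a numeric annotated-base fraction in `[0,1]`.
#' @return list with counts (`n_sense`, `n_antisense`, `n_unassigned`),
#'   `sense_fraction` (pooled), `per_sample` fractions, `sem`, and
#'   `null_expectation`.
#' @export
strandBias <- function(hitsBySample, host) {
  if (is.data.frame(hitsBySample)) hitsBySample <- list(hitsBySample)
  total <- sum(vapply(hitsBySample, nrow, integer(1)))
  if (total == 0L) stop("strand bias undefined: zero spacers")
  annFrac <- if (is(host, "AnnotatedGenome")) annotatedFraction(host) else host
  stopifnot(annFrac >= 0, annFrac <= 1)
  perSample <- vapply(hitsBySample, function(h) {
    if (!nrow(h)) return(NA_real_)
    sum(h$orientation == "sense") / nrow(h)
  }, numeric(1))
  pooled <- do.call(rbind, hitsBySample)
  ns <- sum(pooled$orientation == "sense")
  na_ <- sum(pooled$orientation == "antisense")
  nu <- sum(pooled$orientation == "unassigned")
  sem <- if (length(perSample) >= 2)
    stats::sd(perSample) / sqrt(length(perSample)) else NA_real_
  list(n_sense = ns, n_antisense = na_, n_unassigned = nu,
       sense_fraction = ns / total,
       per_sample = perSample, sem = sem,
       null_expectation = annFrac / 2)
}

#' Compare strand bias between two groups of samples
#'
#' Two-sided Welch (unequal-variance) t-test on per-sample sense
#' fractions.
#'
#' @param groupA,groupB numeric vectors of per-sample sense fractions (or
#'   lists of classified hit data.frames).
#' @return list with `p_value`, `t`, and group means.
#' @export
compareBias <- function(groupA, groupB) {
  toFrac <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(h) sum(h$orientation == "sense") / nrow(h), numeric(1))
  }
  a <- toFrac(groupA); b <- toFrac(groupB)
  if (length(a) < 2 || length(b) < 2)
    stop("compareBias needs at least 2 samples per group")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       mean_a = mean(a), mean_b = mean(b))
}
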