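#' Synthetic data generation with known truth
#'
#' The generator builds a host genome with a controlled intergenic
#' fraction, stranded genes with log-normal expression, and embedded
#' CRISPR arrays; simulates acquired spacers, mature-crRNA small-RNA
#' reads, phage genomes with planted protospacers, and phage variants.
#' Every output carries a truth table so downstream stages can be scored
#' for exact recovery.
#'
#' @name synthetic-data
NULL

pctIdentity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  sum(av[seq_len(n)] == bv[seq_len(n)]) / n
}

#' Generate a synthetic host genome with genes and CRISPR arrays
#'
#' Places `nGenes` non-overlapping genes on random strands so that the
#' realized fraction of bases outside annotated genes equals
#' `intergenicFraction` (the study host has ~11.4% of its genome outside
#' genes, which is what makes the no-bias expectation for spacer strand
#' assignment ~44.3% rather than 50%). Per-gene expression is log-normal.
#' Two CRISPR arrays — a type I-F-like and a type III-B-like one, with
#' repeats constrained to share < 60% identity — are embedded in
#' intergenic space as repeat-spacer-...-repeat runs.
#'
#' @param genomeLength genome size in bp.
#' @param intergenicFraction target fraction of bases outside genes.
#' @param nGenes number of genes (default scales to ~900 bp genes).
#' @param expressionMeanlog,expressionSdlog log-normal expression model.
#' @param arraySpecs list of per-array specs, each a list with `name`,
#'   `nSpacers`, `spacerLength` and optionally `repeatSeq` (random 28-mer
#'   when absent).
#' @param seed integer seed.
#' @return A list with elements `host` ([AnnotatedGenome-class]), `arrays`
#'   (list of [CrisprArray-class]), `arrayRanges` (GRanges of array
#'   placements) and `truth` (list of data.frames `genes`, `arrays`).
#' @export
generateHost <- function(genomeLength = 100000L,
                         intergenicFraction = 0.114,
                         nGenes = NULL,
                         expressionMeanlog = 3,
                         expressionSdlog = 1,
                         arraySpecs = list(
                           list(name = "CRISPR04", nSpacers = 8L, spacerLength = 32L),
                           list(name = "CRISPR03", nSpacers = 8L, spacerLength = 32L)),
                         seed = 1L) {
  set.seed(stageSeed(seed, "generate_host"))
  L <- as.integer(genomeLength)
  geneBases <- round((1 - intergenicFraction) * L)
  if (is.null(nGenes)) nGenes <- max(1L, round(geneBases / 900))
  nGenes <- as.integer(nGenes)

  if (nGenes > 0L) {
    raw <- stats::rlnorm(nGenes, meanlog = 0, sdlog = 0.3)
    lens <- pmax(100L, as.integer(round(raw / sum(raw) * geneBases)))
    lens[nGenes] <- lens[nGenes] + (geneBases - sum(lens))
    if (lens[nGenes] < 100L) stop("genome too small to place ", nGenes, " genes")
  } else lens <- integer(0)

  arrays <- lapply(arraySpecs, function(sp) {
    rep1 <- if (!is.null(sp$repeatSeq)) toupper(sp$repeatSeq) else randomDna(28L)
    spl <- if (!is.null(sp$spacerLength)) sp$spacerLength else 32L
    # a mature crRNA read is handle + spacer + repeat-prefix stub; keep the
    # 5-nt repeat prefix (the trimming anchor) out of handle and spacers so
    # that noiseless reads trim at the genuine repeat junction
    repeat {
      anchor <- substring(rep1, 1L, 5L)
      handle <- substring(rep1, nchar(rep1) - 7L, nchar(rep1))
      if (!grepl(anchor, handle, fixed = TRUE) || !is.null(sp$repeatSeq)) break
      rep1 <- randomDna(nchar(rep1))
    }
    cleanSpacer <- function() {
      repeat {
        s <- randomDna(spl)
        probe <- paste0(handle, s, substring(rep1, 1L, 4L))
        if (regexpr(anchor, probe, fixed = TRUE) < 1L) return(s)
      }
    }
    spc <- replicate(sp$nSpacers, cleanSpacer())
    while (anyDuplicated(spc)) spc <- replicate(sp$nSpacers, cleanSpacer())
    crisprArray(sp$name, rep1, spc)
  })
  # repeats of distinct arrays share < 60% identity (the two systems'
  # repeats are only sparsely similar)
  if (length(arrays) >= 2) {
    for (i in seq_along(arrays)[-1]) {
      while (pctIdentity(as.character(repeatSeq(arrays[[i]])),
                         as.character(repeatSeq(arrays[[1]]))) >= 0.6) {
        arrays[[i]]@repeatSeq <- DNAString(randomDna(length(repeatSeq(arrays[[i]]))))
      }
    }
  }
  arraySeqs <- vapply(arrays, function(a) {
    r <- as.character(repeatSeq(a))
    paste0(r, paste0(as.character(spacers(a)), r, collapse = ""))
  }, character(1))
  arrayLens <- nchar(arraySeqs)

  interBases <- L - sum(lens)
  freeBases <- interBases - sum(arrayLens)
  nGaps <- nGenes + 1L
  if (freeBases < nGaps)
    stop("genome too small for the requested genes and arrays")
  gapSizes <- as.vector(stats::rmultinom(1, freeBases - nGaps, rep(1, nGaps))) + 1L
  arrayGap <- sort(sample.int(nGaps, length(arrays),
                              replace = nGaps < length(arrays)))

  # lay out: gap1 [arrays?] gene1 gap2 [arrays?] gene2 ... gapN
  seqChunks <- character(0)
  geneStart <- integer(nGenes); geneEnd <- integer(nGenes)
  arrStart <- integer(length(arrays)); arrEnd <- integer(length(arrays))
  pos <- 0L
  for (g in seq_len(nGaps)) {
    ais <- which(arrayGap == g)
    gfree <- gapSizes[g]
    if (length(ais)) {
      segs <- as.vector(stats::rmultinom(1, gfree, rep(1, length(ais) + 1L)))
      for (j in seq_along(ais)) {
        seqChunks <- c(seqChunks, randomDna(segs[j]), arraySeqs[ais[j]])
        arrStart[ais[j]] <- pos + segs[j] + 1L
        arrEnd[ais[j]] <- arrStart[ais[j]] + arrayLens[ais[j]] - 1L
        pos <- pos + segs[j] + arrayLens[ais[j]]
      }
      seqChunks <- c(seqChunks, randomDna(segs[length(segs)]))
      pos <- pos + segs[length(segs)]
    } else {
      seqChunks <- c(seqChunks, randomDna(gfree))
      pos <- pos + gfree
    }
    if (g <= nGenes) {
      seqChunks <- c(seqChunks, randomDna(lens[g]))
      geneStart[g] <- pos + 1L
      geneEnd[g] <- pos + lens[g]
      pos <- pos + lens[g]
    }
  }
  genomeChr <- paste(seqChunks, collapse = "")
  stopifnot(nchar(genomeChr) == L)

  geneIds <- sprintf("g%04d", seq_len(nGenes))
  strands <- sample(c("+", "-"), nGenes, replace = TRUE)
  expr <- stats::rlnorm(nGenes, expressionMeanlog, expressionSdlog)
  genes <- if (nGenes > 0L)
    GRanges("host", IRanges(geneStart, geneEnd), strand = strands,
            gene_id = geneIds, expr = expr)
  else {
    g <- GRanges()
    mcols(g)$gene_id <- character(0)
    mcols(g)$expr <- numeric(0)
    g
  }
  genome <- DNAStringSet(genomeChr)
  names(genome) <- "host"
  host <- annotatedGenome(genome, genes)

  arrayRanges <- if (length(arrays))
    GRanges("host", IRanges(arrStart, arrEnd), strand = "+",
            gene_id = vapply(arrays, arrayName, character(1)))
  else GRanges()
  truth <- list(
    genes = data.frame(gene_id = geneIds, start = geneStart, end = geneEnd,
                       strand = strands, expr = expr),
    arrays = data.frame(array = vapply(arrays, arrayName, character(1)),
                        start = arrStart, end = arrEnd,
                        repeat_seq = vapply(arrays, function(a)
                          as.character(repeatSeq(a)), character(1)),
                        n_spacers = vapply(arrays, function(a)
                          length(spacers(a)), integer(1))))
  list(host = host, arrays = arrays, arrayRanges = arrayRanges, truth = truth)
}

#' Simulate newly acquired spacers with a tunable strand bias
#'
#' Source loci are drawn from the genome: with probability equal to the
#' realized intergenic base fraction a spacer comes from intergenic
#' sequence (uniform over gaps that can hold it, random strand, labeled
#' unassignable); otherwise a gene is chosen with weight length x
#' expression (`source = "RNA"`) or length alone (`source = "DNA"`), the
#' spacer is placed fully inside it, and it is oriented antisense to the
#' gene with probability `antisenseBias` (RNA) or exactly 0.5 (DNA —
#' double-stranded substrate has no strand memory, which is why the bias
#' disappears in RT-deficient strains).
#'
#' @param hostObj result of [generateHost()] (or an AnnotatedGenome).
#' @param n number of spacers.
#' @param source `"RNA"` or `"DNA"` substrate.
#' @param antisenseBias probability a gene-derived RNA spacer is antisense.
#' @param spacerLength spacer length in bp.
#' @param seed integer seed.
#' @param expressionExponent exponent applied to expression in the RNA
#'   weighting (1 = proportional).
#' @return list with `spacers` (DNAStringSet) and `truth` (data.frame:
#'   `spacer_id, start, end, strand, gene_id, orientation`).
#' @export
simulateAcquiredSpacers <- function(hostObj, n, source = c("RNA", "DNA"),
                                    antisenseBias = 0.5, spacerLength = 32L,
                                    seed = 1L, expressionExponent = 1) {
  source <- match.arg(source)
  host <- if (is(hostObj, "AnnotatedGenome")) hostObj else hostObj$host
  set.seed(stageSeed(seed, paste0("simulate_spacers_", source)))
  n <- as.integer(n)
  if (n == 0L)
    return(list(spacers = DNAStringSet(), truth = data.frame(
      spacer_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0), orientation = character(0))))
  stopifnot(antisenseBias >= 0, antisenseBias <= 1)
  genomeChr <- as.character(genomeSeq(host)[[1]])
  L <- nchar(genomeChr)
  genes <- geneRanges(host)
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(genes, ignore.strand = TRUE))
  gaps <- gaps[as.character(strand(gaps)) == "*" & width(gaps) >= spacerLength]
  pInter <- 1 - annotatedFraction(host)

  w <- if (source == "RNA") width(genes) * (genes$expr ^ expressionExponent)
       else as.numeric(width(genes))
  pAnti <- if (source == "RNA") antisenseBias else 0.5

  ids <- sprintf("sp%05d", seq_len(n))
  start <- integer(n); strandOut <- character(n)
  geneId <- rep(NA_character_, n); orient <- character(n)
  fromInter <- stats::runif(n) < pInter & length(gaps) > 0
  for (i in seq_len(n)) {
    if (fromInter[i]) {
      gp <- sample.int(length(gaps), 1L,
                       prob = width(gaps) - spacerLength + 1)
      start[i] <- start(gaps)[gp] + sample.int(width(gaps)[gp] - spacerLength + 1L, 1L) - 1L
      strandOut[i] <- sample(c("+", "-"), 1L)
      orient[i] <- "unassigned"
    } else {
      gi <- sample.int(length(genes), 1L, prob = w)
      start[i] <- start(genes)[gi] + sample.int(width(genes)[gi] - spacerLength + 1L, 1L) - 1L
      anti <- stats::runif(1) < pAnti
      gs <- as.character(strand(genes))[gi]
      strandOut[i] <- if (anti) setdiff(c("+", "-"), gs) else gs
      geneId[i] <- genes$gene_id[gi]
      orient[i] <- if (anti) "antisense" else "sense"
    }
  }
  end <- start + spacerLength - 1L
  seqs <- substring(genomeChr, start, end)
  neg <- strandOut == "-"
  seqs[neg] <- revcompChr(seqs[neg])
  sp <- DNAStringSet(seqs); names(sp) <- ids
  list(spacers = sp,
       truth = data.frame(spacer_id = ids, start = start, end = end,
                          strand = strandOut, gene_id = geneId,
                          orientation = orient))
}

#' Simulate small-RNA sequencing reads containing mature crRNAs
#'
#' A mature crRNA read is the last `handleLen` nt of the repeat (the 5'
#' handle), the full spacer, and a 3' stub of the first few nt of the next
#' repeat (3' ends of mature crRNAs are heterogeneous; stub lengths are
#' uniform over `stubRange`, kept at or above the 5-nt anchor so that
#' every mature read is anchorable). Background reads are full-length tRNA
#' copies — with one designated tRNA most abundant, emulating the
#' isoleucine tRNA used as the normalizer — plus random fragments.
#'
#' @param arrays list of [CrisprArray-class] (reads drawn uniformly).
#' @param nMature,nBackground read counts.
#' @param trnaSet optional DNAStringSet of tRNA references; 5 random
#'   76-nt species are generated when absent, the first ("tRNA-Ile")
#'   designated most abundant.
#' @param config a [RunConfig-class] (handle/anchor lengths).
#' @param stubRange integer length-2 range of 3'-stub lengths.
#' @param seed integer seed.
#' @return list with `reads` (DNAStringSet), `trna` (DNAStringSet) and
#'   `truth` (data.frame: `read_id, class, array, spacer_index, trna`).
#' @export
simulateCrrnaReads <- function(arrays, nMature, nBackground = 0L,
                               trnaSet = NULL, config = runConfig(),
                               stubRange = c(5L, 8L), seed = 1L) {
  stopifnot(length(arrays) >= 1)
  set.seed(stageSeed(seed, "simulate_crrna_reads"))
  if (is.null(trnaSet)) {
    trnaSet <- DNAStringSet(replicate(5, randomDna(76L)))
    names(trnaSet) <- c("tRNA-Ile", paste0("tRNA-", c("Ala", "Gly", "Ser", "Arg")))
  }
  hl <- config@handleLen
  reads <- character(0); cls <- character(0)
  arr <- character(0); spIdx <- integer(0); trnaOf <- character(0)
  if (nMature > 0) {
    ai <- sample.int(length(arrays), nMature, replace = TRUE)
    for (i in seq_len(nMature)) {
      a <- arrays[[ai[i]]]
      r <- as.character(repeatSeq(a))
      si <- sample.int(length(spacers(a)), 1L)
      stub <- sample(seq(stubRange[1], stubRange[2]), 1L)
      reads <- c(reads, paste0(substring(r, nchar(r) - hl + 1L, nchar(r)),
                               as.character(spacers(a)[[si]]),
                               substring(r, 1L, stub)))
      cls <- c(cls, "mature"); arr <- c(arr, arrayName(a))
      spIdx <- c(spIdx, si); trnaOf <- c(trnaOf, NA_character_)
    }
  }
  if (nBackground > 0) {
    nTrna <- round(0.7 * nBackground)
    nRand <- nBackground - nTrna
    if (nTrna > 0) {
      wts <- c(0.6, rep(0.4 / (length(trnaSet) - 1), length(trnaSet) - 1))
      ti <- sample.int(length(trnaSet), nTrna, replace = TRUE, prob = wts)
      reads <- c(reads, as.character(trnaSet)[ti])
      cls <- c(cls, rep("trna", nTrna)); arr <- c(arr, rep(NA, nTrna))
      spIdx <- c(spIdx, rep(NA_integer_, nTrna))
      trnaOf <- c(trnaOf, names(trnaSet)[ti])
    }
    if (nRand > 0) {
      reads <- c(reads, vapply(sample(20:60, nRand, replace = TRUE),
                               randomDna, character(1)))
      cls <- c(cls, rep("random", nRand)); arr <- c(arr, rep(NA, nRand))
      spIdx <- c(spIdx, rep(NA_integer_, nRand))
      trnaOf <- c(trnaOf, rep(NA_character_, nRand))
    }
  }
  ids <- sprintf("read%06d", seq_along(reads))
  rs <- DNAStringSet(reads); names(rs) <- ids
  list(reads = rs, trna = trnaSet,
       truth = data.frame(read_id = ids, class = cls, array = arr,
                          spacer_index = spIdx, trna = trnaOf))
}

applyMismatches <- function(spacer, positions) {
  v <- strsplit(spacer, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

writeInto <- function(genomeChr, at, what) {
  paste0(substring(genomeChr, 1L, at - 1L), what,
         substring(genomeChr, at + nchar(what), nchar(genomeChr)))
}

#' Generate a phage genome with planted protospacers
#'
#' Each protospacer spec references a host spacer and controls its planted
#' orientation relative to the phage transcript, its PAM, its mismatch
#' count (with or without a seed-region mismatch) and its flank mode
#' (`"random"`, or `"repeat"` to reproduce the self-flank configuration in
#' which repeat-derived flanks suppress type III targeting).
#'
#' A spec is a list with fields `array` (index into `arrays`), `spacer`
#' (index within the array), `orientation` (`"antisense"` = the crRNA is
#' complementary to the phage mRNA, `"sense"`), `pam` (2-letter string),
#' `nMismatches`, `seedMismatch` (logical) and `flank`
#' (`"random"`/`"repeat"`).
#'
#' @param arrays list of [CrisprArray-class] host arrays.
#' @param specs list of protospacer specs (see Details).
#' @param genomeLength phage genome size in bp.
#' @param config a [RunConfig-class].
#' @param seed integer seed.
#' @return list with `genome` (DNAStringSet named "phage"), `orfs`
#'   (GRanges of the synthetic ORFs hosting the protospacers) and `truth`
#'   (data.frame with coordinates, strand, pam, mismatch positions, flags
#'   and the per-system competence implied by the planted design).
#' @export
generatePhage <- function(arrays, specs, genomeLength = 20000L,
                          config = runConfig(), seed = 1L) {
  set.seed(stageSeed(seed, "generate_phage"))
  L <- as.integer(genomeLength)
  genomeChr <- randomDna(L)
  nPs <- length(specs)
  orfLen <- 900L
  slot <- L %/% (nPs + 1L)
  if (slot < orfLen + 100L) stop("phage genome too small for ", nPs, " planted ORFs")
  orfStart <- slot * seq_len(nPs) - orfLen %/% 2L
  orfStrand <- sample(c("+", "-"), nPs, replace = TRUE)

  hl <- config@handleLen
  sr <- config@seedRegion
  tr <- data.frame()
  for (i in seq_len(nPs)) {
    sp <- specs[[i]]
    S <- as.character(spacers(arrays[[sp$array]])[[sp$spacer]])
    spl <- nchar(S)
    nmm <- if (is.null(sp$nMismatches)) 0L else as.integer(sp$nMismatches)
    seedMm <- isTRUE(sp$seedMismatch)
    if (seedMm && nmm < 1L) stop("seedMismatch requires nMismatches >= 1")
    seedPos <- seq(sr[1], min(sr[2], spl))
    nonSeed <- setdiff(seq_len(spl), seedPos)
    mmPos <- integer(0)
    if (nmm > 0) {
      if (seedMm) {
        mmPos <- c(sample(seedPos, 1L),
                   if (nmm > 1L) sample(nonSeed, nmm - 1L))
      } else mmPos <- sample(nonSeed, nmm)
      mmPos <- sort(mmPos)
    }
    Smut <- applyMismatches(S, mmPos)

    # protospacer match strand: antisense = opposite the ORF coding strand
    psStrand <- if (identical(sp$orientation, "antisense"))
      setdiff(c("+", "-"), orfStrand[i]) else orfStrand[i]
    psStart <- orfStart[i] + orfLen %/% 2L - spl %/% 2L
    psEnd <- psStart + spl - 1L

    flankMode <- if (is.null(sp$flank)) "random" else sp$flank
    pam <- if (is.null(sp$pam)) config@pamCanonical else toupper(sp$pam)
    repTail <- {
      r <- as.character(repeatSeq(arrays[[sp$array]]))
      substring(r, nchar(r) - hl + 1L, nchar(r))
    }
    if (psStrand == "+") {
      genomeChr <- writeInto(genomeChr, psStart, Smut)
      if (flankMode == "repeat") {
        genomeChr <- writeInto(genomeChr, psStart - hl, repTail)
        pam <- substring(repTail, hl - 1L, hl)
      } else {
        genomeChr <- writeInto(genomeChr, psStart - 2L, pam)
      }
    } else {
      genomeChr <- writeInto(genomeChr, psStart, revcompChr(Smut))
      if (flankMode == "repeat") {
        genomeChr <- writeInto(genomeChr, psEnd + 1L, revcompChr(repTail))
        pam <- substring(repTail, hl - 1L, hl)
      } else {
        genomeChr <- writeInto(genomeChr, psEnd + 1L, revcompChr(pam))
      }
    }
    tr <- rbind(tr, data.frame(
      protospacer = sprintf("ps%02d", i),
      array = arrayName(arrays[[sp$array]]), spacer_index = sp$spacer,
      start = psStart, end = psEnd, strand = psStrand,
      orf_strand = orfStrand[i],
      orientation = sp$orientation,
      pam = pam, n_mismatches = nmm,
      mismatch_positions = paste(mmPos, collapse = ","),
      seed_mismatch = seedMm, flank = flankMode,
      typeIF_competent = identical(pam, config@pamCanonical) && !seedMm &&
        nmm <= config@maxMismatches,
      typeIIIB_competent = identical(sp$orientation, "antisense") &&
        flankMode != "repeat" && nmm <= config@maxMismatches))
  }
  genome <- DNAStringSet(genomeChr); names(genome) <- "phage"
  orfs <- GRanges("phage", IRanges(orfStart, orfStart + orfLen - 1L),
                  strand = orfStrand,
                  gene_id = sprintf("orf%02d", seq_len(nPs)))
  list(genome = genome, orfs = orfs, truth = tr)
}

leftNormalizeIndel <- function(refChr, start, end, inserted = NULL) {
  # shift a deletion [start,end] (or an insertion after position start)
  # to its leftmost equivalent representation
  if (is.null(inserted)) {
    while (start > 1L &&
           substring(refChr, start - 1L, start - 1L) ==
           substring(refChr, end, end)) {
      start <- start - 1L; end <- end - 1L
    }
    c(start, end)
  } else {
    while (start > 0L &&
           substring(refChr, start, start) ==
           substring(inserted, nchar(inserted), nchar(inserted))) {
      inserted <- paste0(substring(refChr, start, start),
                         substring(inserted, 1L, nchar(inserted) - 1L))
      start <- start - 1L
    }
    list(pos = start, alt = inserted)
  }
}

#' Apply mutation events to a phage genome
#'
#' Supported event types: `"SNV"` (fields `pos`), `"insertion"` (`pos` =
#' reference base after which `len` random bases are inserted),
#' `"deletion"` (`pos`, `len`). Deletions of `len >=` the structural
#' threshold are recorded as structural deletions with their breakpoints.
#' Events are rejected when they overlap. Indels are recorded in leftmost
#' (normalized) form so they compare exactly with caller output.
#'
#' @param phageObj result of [generatePhage()] (or a DNAStringSet).
#' @param events list of event lists (see Details).
#' @param config a [RunConfig-class].
#' @param seed integer seed (alternative alleles are random).
#' @return list with `genome` (mutated DNAStringSet) and `truth`
#'   (data.frame: `type, pos, end, ref, alt, length`; 1-based on the
#'   reference).
#' @export
mutatePhage <- function(phageObj, events, config = runConfig(), seed = 1L) {
  set.seed(stageSeed(seed, "mutate_phage"))
  genome <- if (is(phageObj, "DNAStringSet")) phageObj else phageObj$genome
  refChr <- as.character(genome[[1]])
  L <- nchar(refChr)
  if (!length(events))
    return(list(genome = genome, truth = data.frame(
      type = character(0), pos = integer(0), end = integer(0),
      ref = character(0), alt = character(0), length = integer(0))))
  spans <- t(vapply(events, function(e) {
    len <- if (is.null(e$len)) 1L else as.integer(e$len)
    switch(e$type,
           SNV = c(e$pos, e$pos),
           insertion = c(e$pos, e$pos),
           deletion = c(e$pos, e$pos + len - 1L),
           stop("unknown event type: ", e$type))
  }, numeric(2)))
  if (any(spans < 1L) || any(spans > L)) stop("event outside genome bounds")
  o <- order(spans[, 1])
  if (any(spans[o, 1][-1] <= spans[o, 2][-length(events)]))
    stop("overlapping events rejected")

  tr <- data.frame()
  varChr <- refChr
  for (i in rev(o)) {  # right to left keeps earlier coordinates valid
    e <- events[[i]]
    len <- if (is.null(e$len)) 1L else as.integer(e$len)
    if (e$type == "SNV") {
      ref <- substring(refChr, e$pos, e$pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      varChr <- paste0(substring(varChr, 1L, e$pos - 1L), alt,
                       substring(varChr, e$pos + 1L, nchar(varChr)))
      tr <- rbind(tr, data.frame(type = "SNV", pos = e$pos, end = e$pos,
                                 ref = ref, alt = alt, length = 1L))
    } else if (e$type == "insertion") {
      ins <- randomDna(len)
      norm <- leftNormalizeIndel(refChr, e$pos, NA, inserted = ins)
      varChr <- paste0(substring(varChr, 1L, e$pos), ins,
                       substring(varChr, e$pos + 1L, nchar(varChr)))
      tr <- rbind(tr, data.frame(type = "insertion", pos = norm$pos,
                                 end = norm$pos, ref = "-", alt = norm$alt,
                                 length = len))
    } else {
      nrm <- leftNormalizeIndel(refChr, e$pos, e$pos + len - 1L)
      type <- if (len >= config@structuralMinLen) "structural_deletion" else "deletion"
      varChr <- paste0(substring(varChr, 1L, e$pos - 1L),
                       substring(varChr, e$pos + len, nchar(varChr)))
      tr <- rbind(tr, data.frame(type = type, pos = nrm[1], end = nrm[2],
                                 ref = substring(refChr, nrm[1], nrm[2]),
                                 alt = "-", length = len))
    }
  }
  tr <- tr[order(tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  out <- DNAStringSet(varChr); names(out) <- names(genome)[1]
  list(genome = out, truth = tr)
}
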