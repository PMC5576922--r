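# Independent brute-force oracles used to cross-check the package's
# optimized implementations, plus small fixture builders.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

rcChr <- function(x) as.character(reverseComplement(DNAStringSet(x)))

rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

# every window on both strands with Hamming distance <= maxMm, by direct
# per-position comparison (no shared code with the scanner)
bruteForceScan <- function(spacer, genomeChr, maxMm) {
  L <- nchar(spacer)
  n <- nchar(genomeChr)
  gv <- strsplit(genomeChr, "")[[1]]
  sv <- strsplit(spacer, "")[[1]]
  rv <- strsplit(rcChr(spacer), "")[[1]]
  scanStrand <- function(pat) {
    mm <- integer(n - L + 1)
    for (j in seq_len(L))
      mm <- mm + (gv[seq(j, n - L + j)] != pat[j])
    mm
  }
  fw <- scanStrand(sv)
  rc <- scanStrand(rv)
  out <- rbind(
    data.frame(start = which(fw <= maxMm),
               strand = rep("+", sum(fw <= maxMm)),
               mismatches = fw[fw <= maxMm]),
    data.frame(start = which(rc <= maxMm),
               strand = rep("-", sum(rc <= maxMm)),
               mismatches = rc[rc <= maxMm]))
  out$end <- out$start + L - 1L
  out[order(out$mismatches, out$start), c("start", "end", "strand", "mismatches")]
}

# reference multinomial draw for comparison with stochastic universal sampling
multinomialCounts <- function(weights, n) {
  as.vector(stats::rmultinom(1, n, weights / sum(weights)))
}

# grid-search likelihood oracle for the MPN estimator
mpnGridOracle <- function(positives, tubes, volumes,
                          grid = 10^seq(-6, 6, by = 1e-4)) {
  ll <- vapply(grid, function(cc) {
    p <- 1 - exp(-cc * volumes)
    p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
    sum(positives * log(p) - (tubes - positives) * cc * volumes)
  }, numeric(1))
  grid[which.max(ll)]
}

smallHost <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(424242)
      cache <<- generateHost(genomeLength = 30000L, seed = 99L)
    }
    cache
  }
})

defaultSpecsThree <- function() list(
  list(array = 1L, spacer = 1L, orientation = "antisense", pam = "AG",
       nMismatches = 1L, seedMismatch = FALSE, flank = "random"),
  list(array = 1L, spacer = 2L, orientation = "antisense", pam = "GG",
       nMismatches = 0L, flank = "random"),
  list(array = 1L, spacer = 3L, orientation = "sense", pam = "TG",
       nMismatches = 5L, seedMismatch = TRUE, flank = "random"))
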