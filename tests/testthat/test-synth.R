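test_that("realized intergenic fraction matches the request within 0.01", {
  for (s in c(1L, 2L)) {
    h <- generateHost(genomeLength = 100000L, intergenicFraction = 0.114,
                      seed = s)
    expect_lt(abs((1 - annotatedFraction(h$host)) - 0.114), 0.01)
  }
})

test_that("a gene-free host is fully intergenic with empty annotation", {
  h <- generateHost(genomeLength = 20000L, nGenes = 0L, seed = 1L)
  expect_equal(length(geneRanges(h$host)), 0L)
  expect_equal(annotatedFraction(h$host), 0)
})

test_that("an embedded array occupies exactly its repeat-spacer arithmetic", {
  h <- generateHost(genomeLength = 50000L, seed = 3L,
                    arraySpecs = list(list(name = "A", nSpacers = 8L,
                                           spacerLength = 32L)))
  tr <- h$truth$arrays
  expect_equal(tr$end - tr$start + 1L, 8L * 32L + 9L * 28L)
  # the embedded sequence is literally repeat-spacer-...-repeat
  arr <- h$arrays[[1]]
  emb <- substring(as.character(genomeSeq(h$host)[[1]]), tr$start, tr$end)
  expected <- paste0(tr$repeat_seq,
                     paste0(as.character(spacers(arr)), tr$repeat_seq,
                            collapse = ""))
  expect_identical(emb, expected)
})

test_that("spacers are unique within arrays and repeats dissimilar between them", {
  h <- smallHost()
  for (a in h$arrays)
    expect_false(anyDuplicated(as.character(spacers(a))) > 0)
  r1 <- as.character(repeatSeq(h$arrays[[1]]))
  r2 <- as.character(repeatSeq(h$arrays[[2]]))
  ident <- mean(strsplit(r1, "")[[1]] == strsplit(r2, "")[[1]])
  expect_lt(ident, 0.6)
})

test_that("DNA-derived spacers lose the strand bias regardless of the bias knob", {
  h <- smallHost()
  sim <- simulateAcquiredSpacers(h, 4000, "DNA", antisenseBias = 0.95, seed = 2L)
  gm <- sim$truth[sim$truth$orientation != "unassigned", ]
  expect_lt(abs(mean(gm$orientation == "antisense") - 0.5), 0.03)
})

test_that("full antisense bias with no intergenic space gives 100% antisense", {
  h <- generateHost(genomeLength = 30000L, intergenicFraction = 0.002,
                    nGenes = 20L, seed = 4L, arraySpecs = list())
  sim <- simulateAcquiredSpacers(h, 500, "RNA", antisenseBias = 1, seed = 5L)
  gm <- sim$truth[sim$truth$orientation != "unassigned", ]
  expect_equal(mean(gm$orientation == "antisense"), 1)
})

test_that("RNA spacer counts track length x expression (multinomial oracle)", {
  h <- smallHost()
  genes <- geneRanges(h$host)
  w <- width(genes) * genes$expr
  sim <- simulateAcquiredSpacers(h, 5000, "RNA", 0.5, seed = 6L)
  counts <- table(factor(sim$truth$gene_id, levels = genes$gene_id))
  expect_gt(cor(as.integer(counts), w, method = "spearman"), 0.8)
  # oracle: a direct multinomial draw with the same weights shows the same
  # correlation structure
  set.seed(99)
  oracle <- multinomialCounts(w, sum(!is.na(sim$truth$gene_id)))
  expect_gt(cor(oracle, w, method = "spearman"), 0.8)
})

test_that("mature crRNA reads have handle+spacer+stub structure", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  rr <- simulateCrrnaReads(h$arrays[1], 50, 0, config = cfg, seed = 7L)
  a <- h$arrays[[1]]
  r <- as.character(repeatSeq(a))
  handle <- substring(r, nchar(r) - 7L, nchar(r))
  for (i in seq_len(5)) {
    rd <- as.character(rr$reads[[i]])
    expect_identical(substring(rd, 1, 8), handle)
    sidx <- rr$truth$spacer_index[i]
    expect_identical(substring(rd, 9, 40), as.character(spacers(a)[[sidx]]))
  }
})

test_that("the designated tRNA is the modal background species", {
  h <- smallHost()
  rr <- simulateCrrnaReads(h$arrays, 0, 2000, config = runConfig(), seed = 8L)
  tb <- table(rr$truth$trna)
  expect_equal(names(tb)[which.max(tb)], "tRNA-Ile")
})

test_that("an empty mutation list returns the genome unchanged", {
  h <- smallHost()
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, runConfig(), seed = 9L)
  mut <- mutatePhage(ph, list(), runConfig(), seed = 1L)
  expect_identical(as.character(mut$genome[[1]]), as.character(ph$genome[[1]]))
  expect_equal(nrow(mut$truth), 0L)
})

test_that("overlapping and out-of-bounds mutation events are rejected", {
  h <- smallHost()
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, runConfig(), seed = 9L)
  expect_error(mutatePhage(ph, list(list(type = "deletion", pos = 100, len = 50),
                                    list(type = "SNV", pos = 120)),
                           runConfig(), seed = 1L), "overlap")
  expect_error(mutatePhage(ph, list(list(type = "SNV", pos = 10^6)),
                           runConfig(), seed = 1L), "bounds")
})

test_that("planted protospacers carry the requested PAM and mismatch design", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 10L)
  tr <- ph$truth
  genomeChr <- as.character(ph$genome[[1]])
  for (i in seq_len(nrow(tr))) {
    pam <- extractPam(genomeChr, tr$start[i], tr$end[i], tr$strand[i], cfg)
    expect_identical(pam, tr$pam[i])
  }
  expect_equal(tr$pam, c("AG", "GG", "TG"))
  expect_equal(tr$n_mismatches, c(1L, 0L, 5L))
  expect_equal(tr$seed_mismatch, c(FALSE, FALSE, TRUE))
})

test_that("repeat-derived flanks are planted verbatim next to the protospacer", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  specs <- list(list(array = 1L, spacer = 1L, orientation = "antisense",
                     nMismatches = 0L, flank = "repeat"))
  ph <- generatePhage(h$arrays, specs, 10000L, cfg, seed = 11L)
  m <- scanArray(h$arrays[[1]], ph$genome, orfs = ph$orfs, config = cfg)
  m <- m[m$spacer_id == names(spacers(h$arrays[[1]]))[1], ]
  expect_equal(m$flank_class[which.min(m$mismatches)], "self")
})
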