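test_that("protospacer scan equals the brute-force Hamming oracle", {
  set.seed(41)
  cfg <- runConfig(seed = 1)
  for (rep in 1:5) {
    genomeChr <- rndDna(5000)
    spacer <- substring(genomeChr, 2001, 2032)  # guarantees >= 1 hit
    m <- scanProtospacers(spacer, genomeChr, maxMismatches = 3, config = cfg)
    bf <- bruteForceScan(spacer, genomeChr, 3)
    expect_equal(nrow(m), nrow(bf))
    expect_equal(m$start, bf$start)
    expect_equal(m$strand, bf$strand)
    expect_equal(m$mismatches, bf$mismatches)
  }
})

test_that("planted protospacers are recovered at truth coordinates", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 42)
  tr <- ph$truth
  for (i in seq_len(nrow(tr))) {
    sp <- as.character(spacers(h$arrays[[1]])[[tr$spacer_index[i]]])
    m <- scanProtospacers(sp, ph$genome, config = cfg)
    best <- m[which.min(m$mismatches), ]
    expect_equal(best$start, tr$start[i])
    expect_equal(best$strand, tr$strand[i])
    expect_equal(best$mismatches, tr$n_mismatches[i])
    expect_equal(best$seed_mismatch, tr$seed_mismatch[i])
    expect_equal(best$pam, tr$pam[i])
  }
})

test_that("stored PAM and seed flags agree with recomputation from sequence", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 43)
  m <- scanArray(h$arrays[[1]], ph$genome, orfs = ph$orfs, config = cfg)
  genomeChr <- as.character(ph$genome[[1]])
  for (i in seq_len(nrow(m))) {
    expect_identical(m$pam[i],
                     extractPam(genomeChr, m$start[i], m$end[i], m$strand[i], cfg))
    mm <- as.integer(strsplit(m$mismatch_positions[i], ",")[[1]])
    expect_identical(m$seed_mismatch[i], any(mm %in% 1:8))
    expect_identical(m$pam_canonical[i], identical(m$pam[i], "GG"))
  }
})

test_that("a match at the genome edge keeps its row with PAM unavailable", {
  cfg <- runConfig(seed = 1)
  set.seed(44)
  sp <- rndDna(32)
  genomeChr <- paste0(sp, rndDna(200))
  m <- scanProtospacers(sp, genomeChr, maxMismatches = 0, config = cfg)
  expect_equal(m$start[1], 1L)
  expect_false(m$pam_available[1])
  expect_true(is.na(m$pam[1]))
})

test_that("transcript orientation follows ORF strand", {
  cfg <- runConfig(seed = 1)
  orfs <- GRanges("phage", IRanges(c(101, 1001), c(700, 1600)),
                  strand = c("+", "-"), gene_id = c("o1", "o2"))
  m <- data.frame(spacer_id = c("a", "b", "c", "d"),
                  start = c(300, 300, 1200, 3000),
                  end = c(331, 331, 1231, 3031),
                  strand = c("-", "+", "-", "+"), mismatches = 0)
  out <- orientationVsTranscript(m, orfs = orfs, config = cfg)
  expect_equal(out$orientation_vs_transcript,
               c("antisense_crRNA_complementary", "sense_crRNA_noncomplementary",
                 "sense_crRNA_noncomplementary", "no_transcript"))
})

test_that("flank self-call requires full handle identity by default", {
  cfg <- runConfig(seed = 1)
  set.seed(45)
  repeatChr <- rndDna(28)
  handle <- substring(repeatChr, 21, 28)
  sp <- rndDna(32)
  mkGenome <- function(flank) paste0(rndDna(300), flank, sp, rndDna(300))
  m <- data.frame(spacer_id = "s", start = 309, end = 340, strand = "+",
                  mismatches = 0)
  self <- flankSelfCheck(m, mkGenome(handle), repeatChr, cfg)
  expect_equal(self$flank_class, "self")
  # one mismatched position (7 of 8 identical) must NOT be self
  h7 <- handle
  substring(h7, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substring(handle, 3, 3))[1]
  near <- flankSelfCheck(m, mkGenome(h7), repeatChr, cfg)
  expect_equal(near$flank_class, "non_self")
  rand <- flankSelfCheck(m, mkGenome(rndDna(8)), repeatChr, cfg)
  expect_equal(rand$flank_class, "non_self")
})

test_that("interference competence reproduces the per-system logic table", {
  cfg <- runConfig(seed = 1)
  row <- function(pam, seedMm, orient, flank, mm = 0L)
    data.frame(spacer_id = "s", start = 1, end = 32, strand = "+",
               mismatches = mm, mismatch_positions = "", pam = pam,
               pam_available = TRUE, pam_canonical = pam == "GG",
               seed_mismatch = seedMm, orientation_vs_transcript = orient,
               flank_class = flank)
  # AG PAM, antisense, non-self: escapes I-F but III-B compensates
  r1 <- predictInterference(row("AG", FALSE, "antisense_crRNA_complementary",
                                "non_self", 1L), cfg)
  expect_false(r1$typeIF_competent); expect_true(r1$typeIIIB_competent)
  expect_match(r1$reasons, "pam_noncanonical")
  # GG PAM, antisense, clean: both systems competent
  r2 <- predictInterference(row("GG", FALSE, "antisense_crRNA_complementary",
                                "non_self"), cfg)
  expect_true(r2$typeIF_competent); expect_true(r2$typeIIIB_competent)
  # sense orientation with seed mismatch: neither system
  r3 <- predictInterference(row("GG", TRUE, "sense_crRNA_noncomplementary",
                                "non_self", 5L), cfg)
  expect_false(r3$typeIF_competent); expect_false(r3$typeIIIB_competent)
  expect_match(r3$reasons, "seed_mismatch")
  expect_match(r3$reasons, "sense_orientation")
  # self flank suppresses III-B even for a perfect antisense target
  r4 <- predictInterference(row("GG", FALSE, "antisense_crRNA_complementary",
                                "self"), cfg)
  expect_false(r4$typeIIIB_competent)
  expect_match(r4$reasons, "self_flank")
  # mismatch ceiling disables both
  r5 <- predictInterference(row("GG", FALSE, "antisense_crRNA_complementary",
                                "non_self", 6L), cfg)
  expect_false(r5$typeIF_competent); expect_false(r5$typeIIIB_competent)
})

test_that("reversing orientation kills III-B-only targets but not I-F targets", {
  cfg <- runConfig(seed = 1)
  base <- data.frame(spacer_id = "s", start = 1, end = 32, strand = "+",
                     mismatches = 0L, mismatch_positions = "", pam = "AG",
                     pam_available = TRUE, pam_canonical = FALSE,
                     seed_mismatch = FALSE,
                     orientation_vs_transcript = "antisense_crRNA_complementary",
                     flank_class = "non_self")
  fwd <- predictInterference(base, cfg)
  expect_true(fwd$typeIIIB_competent && !fwd$typeIF_competent)
  flipped <- base
  flipped$orientation_vs_transcript <- "sense_crRNA_noncomplementary"
  revd <- predictInterference(flipped, cfg)
  expect_false(revd$typeIIIB_competent || revd$typeIF_competent)
  # a canonical-PAM target is orientation-invariant for type I-F
  ifTarget <- base; ifTarget$pam <- "GG"; ifTarget$pam_canonical <- TRUE
  ifFlipped <- flipped; ifFlipped$pam <- "GG"; ifFlipped$pam_canonical <- TRUE
  expect_true(predictInterference(ifTarget, cfg)$typeIF_competent)
  expect_true(predictInterference(ifFlipped, cfg)$typeIF_competent)
})

test_that("competence predictions match the planted design exactly", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 46)
  m <- scanArray(h$arrays[[1]], ph$genome, orfs = ph$orfs, config = cfg)
  m <- do.call(rbind, lapply(split(m, m$spacer_id), function(x)
    x[which.min(x$mismatches), ]))
  m <- m[order(m$start), ]
  tr <- ph$truth[order(ph$truth$start), ]
  expect_equal(m$typeIF_competent, tr$typeIF_competent)
  expect_equal(m$typeIIIB_competent, tr$typeIIIB_competent)
})

test_that("the fallback ORF caller finds planted reading frames", {
  set.seed(47)
  orf <- paste0("ATG", paste(replicate(80, sample(setdiff(
    c(outer(c(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)),
            c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), 1)), collapse = ""), "TAA")
  genomeChr <- paste0(rndDna(500), orf, rndDna(500))
  found <- callOrfs(genomeChr, minLen = 150)
  expect_true(any(start(found) == 501 & end(found) == 500 + nchar(orf) &
                    as.character(strand(found)) == "+"))
})
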