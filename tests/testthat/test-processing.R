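# a fixed miniature array for hand-traceable classification tests
procFixture <- function() {
  rep28 <- "GTTCACTGCCGTATAGGCAGCTAAGAAA"
  spacers <- c(s1 = "ATCGGATCCATGCTAGCTAGGATCCTAGCTAA",
               s2 = "TTGACCGGTAACCGGTTAACCGGTAGGCCTAA")
  list(array = crisprArray("mini", rep28, spacers),
       repeatChr = rep28, spacers = spacers)
}

test_that("a mature crRNA read trims to handle + spacer length", {
  fx <- procFixture()
  cfg <- runConfig(seed = 1)
  r <- fx$repeatChr
  read <- paste0(substring(r, 21, 28), fx$spacers[["s1"]], substring(r, 1, 6))
  cl <- classifyReads(read, r, fx$spacers, cfg)
  expect_equal(cl$class, "crRNA_trimmed")
  expect_equal(cl$trimmed_len, 40L)
  expect_equal(cl$anchor_pos, 41L)
})

test_that("pure-repeat and anchorless reads classify as designed", {
  fx <- procFixture()
  cfg <- runConfig(seed = 1)
  cl <- classifyReads(c(full = fx$repeatChr,
                        none = "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"),
                      fx$repeatChr, fx$spacers, cfg)
  expect_equal(cl$class, c("repeat_substring", "no_anchor"))
  # a read that is a mid-repeat fragment continuing into the repeat start
  frag <- paste0(substring(fx$repeatChr, 10, 28), substring(fx$repeatChr, 1, 8))
  expect_equal(classifyReads(frag, fx$repeatChr, fx$spacers, cfg)$class,
               "repeat_substring")
})

test_that("short trimmed reads are resolved by the 5-base spacer junction", {
  fx <- procFixture()
  cfg <- runConfig(seed = 1)
  r <- fx$repeatChr
  # last 8 bases of spacer s2 followed by repeat: an authentic junction
  conf <- paste0(substring(fx$spacers[["s2"]], 25, 32), substring(r, 1, 12))
  # 8 random-looking bases that end unlike any spacer
  rej <- paste0("ACACACAC", substring(r, 1, 12))
  cl <- classifyReads(c(a = conf, b = rej), r, fx$spacers, cfg)
  expect_equal(cl$class, c("junction_confirmed", "junction_rejected"))
  expect_equal(cl$trimmed_len, c(8L, 8L))
})

test_that("every read gets exactly one class and counts partition the total", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  rr <- simulateCrrnaReads(h$arrays, 300, 500, config = cfg, seed = 21)
  cl <- classifyReads(rr$reads, repeatSeq(h$arrays[[1]]),
                      spacers(h$arrays[[1]]), cfg)
  expect_equal(nrow(cl), length(rr$reads))
  expect_equal(sum(table(cl$class)), length(rr$reads))
  expect_true(all(cl$class %in% c("crRNA_trimmed", "repeat_substring",
                                  "junction_confirmed", "junction_rejected",
                                  "no_anchor")))
  expect_true(all(is.na(cl$trimmed_len[cl$class == "no_anchor"])))
})

test_that("anchor finding equals a brute-force substring search", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  rr <- simulateCrrnaReads(h$arrays, 100, 200, config = cfg, seed = 22)
  repeatChr <- as.character(repeatSeq(h$arrays[[1]]))
  anchor <- substring(repeatChr, 1, 5)
  cl <- classifyReads(rr$reads, repeatChr, spacers(h$arrays[[1]]), cfg)
  for (i in sample(length(rr$reads), 40)) {
    rd <- as.character(rr$reads[[i]])
    # oracle: scan every offset
    found <- NA_integer_
    for (p in seq_len(max(nchar(rd) - 4, 0)))
      if (substring(rd, p, p + 4) == anchor) { found <- p; break }
    expect_identical(cl$anchor_pos[i], found)
  }
})

test_that("noiseless mature reads classify perfectly with modal offset = handle", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  rr <- simulateCrrnaReads(h$arrays[1], 400, 0, config = cfg, seed = 23)
  prof <- suppressWarnings(processingProfile(rr$reads, h$arrays[[1]],
                                             DNAStringSet(c(dummy = "ACGTACGT")),
                                             cfg))
  expect_equal(mean(prof$classes$class == "crRNA_trimmed"), 1)
  expect_equal(prof$dominant_offset, 8L)
  expect_equal(prof$histogram$trimmed_len[which.max(prof$histogram$count)], 40L)
})

test_that("normalization is linear in the tRNA background", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  rr <- simulateCrrnaReads(h$arrays[1], 200, 400, config = cfg, seed = 24)
  p1 <- processingProfile(rr$reads, h$arrays[[1]], rr$trna, cfg)
  doubled <- c(rr$reads, rr$reads[rr$truth$class == "trna"])
  p2 <- processingProfile(doubled, h$arrays[[1]], rr$trna, cfg)
  expect_equal(p2$normalizer, 2L * p1$normalizer)
  common <- intersect(p1$histogram$trimmed_len, p2$histogram$trimmed_len)
  n1 <- p1$histogram$normalized[match(common, p1$histogram$trimmed_len)]
  n2 <- p2$histogram$normalized[match(common, p2$histogram$trimmed_len)]
  expect_equal(n2, n1 / 2)
})

test_that("zero tRNA reads still emits the raw histogram with a warning", {
  fx <- procFixture()
  cfg <- runConfig(seed = 1)
  r <- fx$repeatChr
  read <- paste0(substring(r, 21, 28), fx$spacers[["s1"]], substring(r, 1, 6))
  expect_warning(
    prof <- processingProfile(DNAStringSet(c(x = read)), fx$array,
                              DNAStringSet(c(t = "ACGTACGTACGT")), cfg),
    "tRNA")
  expect_equal(nrow(prof$histogram), 1L)
  expect_true(is.na(prof$histogram$normalized))
})

test_that("processing detection needs test-specific enrichment", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  withProc <- simulateCrrnaReads(h$arrays[1], 300, 600, config = cfg, seed = 25)
  noProc <- simulateCrrnaReads(h$arrays[1], 0, 600, config = cfg, seed = 26)
  pTest <- processingProfile(withProc$reads, h$arrays[[1]], withProc$trna, cfg)
  pCtrl <- processingProfile(noProc$reads, h$arrays[[1]], noProc$trna, cfg)
  expect_true(processingDetected(pTest, pCtrl, cfg))
  expect_false(processingDetected(pTest, pTest, cfg))
  expect_false(processingDetected(pCtrl, pCtrl, cfg))
})
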