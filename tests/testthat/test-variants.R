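test_that("identical genomes yield zero variant calls", {
  set.seed(51)
  g <- rndDna(10000)
  d <- diffGenomes(g, g)
  expect_equal(nrow(d$variants), 0L)
  expect_false(d$rearrangement_flag)
})

test_that("planted 6 SNVs + 1 insertion are called as exactly 7 sites", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 52)
  ev <- c(lapply(c(1000, 3000, 5500, 8000, 12000, 16000),
                 function(p) list(type = "SNV", pos = p)),
          list(list(type = "insertion", pos = 1809, len = 1)))
  mut <- mutatePhage(ph, ev, cfg, seed = 53)
  d <- diffGenomes(ph$genome, mut$genome, cfg)
  expect_equal(nrow(d$variants), 7L)
  expect_equal(d$variants[, c("type", "pos", "ref", "alt")],
               mut$truth[, c("type", "pos", "ref", "alt")])
})

test_that("a structural deletion is called with exact breakpoints", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 54)
  mut <- mutatePhage(ph, list(list(type = "deletion", pos = 5000, len = 1201)),
                     cfg, seed = 55)
  d <- diffGenomes(ph$genome, mut$genome, cfg)
  expect_equal(nrow(d$variants), 1L)
  expect_equal(d$variants$type, "structural_deletion")
  expect_equal(d$variants$pos, mut$truth$pos)
  expect_equal(d$variants$end, mut$truth$end)
  expect_gte(d$variants$length, 50L)
})

test_that("applying called variants reconstructs the variant genome", {
  h <- smallHost()
  cfg <- runConfig(seed = 1)
  ph <- generatePhage(h$arrays, defaultSpecsThree(), 20000L, cfg, seed = 56)
  for (s in 1:4) {
    ev <- list(list(type = "SNV", pos = 700 + 997 * s),
               list(type = "insertion", pos = 9000 + 13 * s, len = s),
               list(type = "deletion", pos = 14000 + 31 * s, len = 2 * s),
               list(type = "deletion", pos = 17000, len = 120))
    mut <- mutatePhage(ph, ev, cfg, seed = 60 + s)
    d <- diffGenomes(ph$genome, mut$genome, cfg)
    expect_identical(applyVariants(ph$genome, d$variants),
                     as.character(mut$genome[[1]]))
    expect_equal(nrow(d$variants), 4L)
  }
})

test_that("escape classes are assigned by locus and event type", {
  cfg <- runConfig(seed = 1)
  ps <- data.frame(protospacer = c("ps1", "ps2"),
                   start = c(1000, 5000), end = c(1031, 5031),
                   strand = c("+", "-"))
  # ps1: plus strand, 5' PAM at 998-999, seed at 1000-1007
  # ps2: minus strand, PAM at 5032-5033, seed at 5024-5031
  classify1 <- function(v) classifyEscape(v, ps, cfg)$escape_class
  del <- data.frame(type = "structural_deletion", pos = 900, end = 1100,
                    ref = "", alt = "-", length = 201)
  expect_equal(classify1(del), c("deletion_spanning_protospacer", "none"))
  pamSnv <- data.frame(type = "SNV", pos = 998, end = 998, ref = "G",
                       alt = "T", length = 1)
  expect_equal(classify1(pamSnv)[1], "pam_mutation")
  pamSnv2 <- data.frame(type = "SNV", pos = 5033, end = 5033, ref = "G",
                        alt = "T", length = 1)
  expect_equal(classify1(pamSnv2)[2], "pam_mutation")
  seedSub <- data.frame(type = "SNV", pos = 1003, end = 1003, ref = "A",
                        alt = "C", length = 1)
  expect_equal(classify1(seedSub), c("seed_substitution", "none"))
  seedSub2 <- data.frame(type = "SNV", pos = 5026, end = 5026, ref = "A",
                         alt = "C", length = 1)
  expect_equal(classify1(seedSub2)[2], "seed_substitution")
  fs <- data.frame(type = "deletion", pos = 1005, end = 1005, ref = "A",
                   alt = "-", length = 1)
  expect_equal(classify1(fs)[1], "seed_frameshift")
  nonSeed <- data.frame(type = "SNV", pos = 1020, end = 1020, ref = "A",
                        alt = "C", length = 1)
  expect_equal(classify1(nonSeed)[1], "non_seed_change")
  outside <- data.frame(type = "SNV", pos = 3000, end = 3000, ref = "A",
                        alt = "C", length = 1)
  expect_equal(classify1(outside), c("none", "none"))
})

test_that("in-silico PCR product arithmetic and orientation are correct", {
  set.seed(57)
  fwd <- rndDna(20); rev <- rndDna(20)
  mid <- rndDna(150)
  template <- paste0(rndDna(300), fwd, mid, rcChr(rev), rndDna(300))
  p <- insilicoPcr(template, fwd, rev)
  expect_equal(nrow(p), 1L)
  expect_equal(p$length, 190L)
  expect_equal(p$start, 301L)
  # the same amplicon is found when the template is reverse-complemented
  p2 <- insilicoPcr(rcChr(template), fwd, rev)
  expect_equal(p2$length, 190L)
  # absent primer: no product
  expect_equal(nrow(insilicoPcr(template, rndDna(20), rev)), 0L)
  # product cap discards over-long amplicons
  expect_equal(nrow(insilicoPcr(template, fwd, rev, maxProduct = 100)), 0L)
  expect_error(insilicoPcr(template, "ACGTACGTAC", rev), ">= 15")
})

test_that("protein comparison reports identity, similarity and C-terminal loss", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKRQTLGQHDFSAGEGLYTHMKALRPDEDRLSPLHSVYVDQWDWE"
  r <- compareProteins(p, p)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$percent_similarity, 100)
  expect_equal(r$cterm_loss, 0)
  r2 <- compareProteins(p, substring(p, 1, 100))
  expect_equal(r2$cterm_loss, 20)
  expect_error(compareProteins("", p), "non-empty")
})

test_that("a premature termination's C-terminal loss matches the ground truth", {
  # a frameshift near the C-terminus modifies a short run of residues and
  # terminates early; the residues lost to termination are the reference
  # tail beyond the variant's end
  set.seed(58)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  refAa <- paste(c("M", sample(aas, 119, replace = TRUE)), collapse = "")
  # premature termination alone: loss is exactly the missing tail
  r <- compareProteins(refAa, substring(refAa, 1, 100))
  expect_equal(r$cterm_loss, 20)
  # modified run before the termination: the conserved prefix dominates
  # identity, and the loss cannot shrink below zero nor exceed the
  # affected span
  modified <- vapply(94:100, function(i)
    sample(setdiff(aas, substring(refAa, i, i)), 1), character(1))
  altAa <- paste0(substring(refAa, 1, 93), paste(modified, collapse = ""))
  r2 <- compareProteins(refAa, altAa)
  expect_gte(r2$cterm_loss, 0)
  expect_lte(r2$cterm_loss, 27)
  expect_lt(r2$percent_identity, 100)
  expect_gte(r2$percent_identity, 100 * 93 / 120)
})
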