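reportDigests <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  md5 <- tools::md5sum(files)
  data.frame(file = basename(files), md5 = unname(md5))
}

#' End-to-end synthetic spacer-acquisition strand-bias experiment
#'
#' Builds a synthetic host (defaults: 100 kb, 11.4% intergenic), then
#' simulates newly acquired RNA-derived spacers for two genotypes:
#' interference-off (no type III-B activity; no strand selection) and
#' interference-on, where antisense host-gene spacers are purged
#' post-acquisition with a small survival probability — the autoimmune
#' selection that biases surviving spacers toward sense. Each genotype
#' yields `nSamples` samples which are mapped, orientation-classified,
#' summarized by [strandBias()], compared by Welch t-test, and checked
#' against the SUS null envelope.
#'
#' @param config a [RunConfig-class].
#' @param nSamples samples per genotype.
#' @param spacersPerSample spacers drawn per sample.
#' @param genomeLength host genome size (bp).
#' @param purgeSurvival survival probability of an antisense gene-derived
#'   spacer under active interference (a selection model, not a measured
#'   rate).
#' @param outDir directory for result TSVs (a temp dir by default).
#' @return list (`PipelineReport`): `bias_on`, `bias_off`
#'   ([strandBias()] results), `p_value`, `envelope_call`, `null_expectation`,
#'   `config`, `files` (with content digests).
#' @export
runBiasExperiment <- function(config = runConfig(), nSamples = 8L,
                              spacersPerSample = 500L,
                              genomeLength = 100000L,
                              purgeSurvival = 0.05,
                              outDir = NULL) {
  if (is.null(outDir)) outDir <- tempfile("bias_experiment_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hostObj <- generateHost(genomeLength = genomeLength, seed = config@seed)
  host <- hostObj$host
  genes <- geneRanges(host)

  set.seed(stageSeed(config@seed, "bias_experiment_purge"))
  simulateSample <- function(sampleSeed, purge) {
    sim <- simulateAcquiredSpacers(hostObj, spacersPerSample, source = "RNA",
                                   antisenseBias = 0.5, seed = sampleSeed)
    keep <- rep(TRUE, nrow(sim$truth))
    if (purge) {
      anti <- sim$truth$orientation == "antisense"
      keep[anti] <- stats::runif(sum(anti)) < purgeSurvival
    }
    sp <- sim$spacers[keep]
    hits <- mapSpacers(sp, host, config@maxMismatches)
    classifyOrientation(hits, genes, config@geneOverlapFrac)
  }
  offSamples <- lapply(seq_len(nSamples), function(i)
    simulateSample(stageSeed(config@seed, paste0("off_sample_", i)), FALSE))
  onSamples <- lapply(seq_len(nSamples), function(i)
    simulateSample(stageSeed(config@seed, paste0("on_sample_", i)), TRUE))

  biasOff <- strandBias(offSamples, host)
  biasOn <- strandBias(onSamples, host)
  cmp <- compareBias(biasOn$per_sample, biasOff$per_sample)

  env <- nullEnvelope(width(genes), genes$expr, genes$gene_id,
                      sampleSize = config@susSampleSize,
                      trials = config@susTrials, config = config,
                      seed = config@seed)
  pooled <- do.call(rbind, offSamples)
  counts <- table(pooled$gene_id[!is.na(pooled$gene_id)])
  obs <- stats::setNames(as.integer(counts), names(counts))
  envCall <- envelopeTest(obs, env)

  summary <- data.frame(
    genotype = c("interference_on", "interference_off"),
    n_sense = c(biasOn$n_sense, biasOff$n_sense),
    n_antisense = c(biasOn$n_antisense, biasOff$n_antisense),
    n_unassigned = c(biasOn$n_unassigned, biasOff$n_unassigned),
    sense_fraction = c(biasOn$sense_fraction, biasOff$sense_fraction),
    sem = c(biasOn$sem, biasOff$sem),
    null_expectation = biasOff$null_expectation)
  writeResultTsv(summary, file.path(outDir, "strand_bias_summary.tsv"))
  writeResultTsv(data.frame(rank = seq_along(env$order), gene = env$order,
                            lower = env$lower, upper = env$upper,
                            observed = envCall$observed,
                            position = envCall$position),
                 file.path(outDir, "null_envelope.tsv"))
  list(bias_on = biasOn, bias_off = biasOff, p_value = cmp$p_value,
       envelope_call = envCall, null_expectation = biasOff$null_expectation,
       summary = summary, config = config,
       files = reportDigests(outDir))
}

escapeEventsFor <- function(psRow, type, config, refChr, seedOffset = 3L) {
  sr <- config@seedRegion
  fivePrime <- config@pamConvention == "five_prime_of_protospacer"
  pamProximalLeft <- (psRow$strand == "+") == fivePrime
  seedGenomic <- if (pamProximalLeft)
    seq(psRow$start + sr[1] - 1L, psRow$start + sr[2] - 1L)
  else seq(psRow$end - sr[2] + 1L, psRow$end - sr[1] + 1L)
  pos <- seedGenomic[seedOffset]
  if (type == "seed_frameshift") {
    # pick a left-stable seed position so the normalized 1-nt deletion
    # stays inside the seed window
    stable <- seedGenomic[substring(refChr, seedGenomic - 1L, seedGenomic - 1L) !=
                            substring(refChr, seedGenomic, seedGenomic)]
    if (length(stable)) pos <- stable[min(seedOffset, length(stable))]
  }
  switch(type,
         deletion = {
           lpad <- sample(60:200, 1L); rpad <- sample(60:200, 1L)
           list(list(type = "deletion", pos = psRow$start - lpad,
                     len = (psRow$end - psRow$start + 1L) + lpad + rpad))
         },
         seed_substitution = list(list(type = "SNV", pos = pos)),
         seed_frameshift = list(list(type = "deletion", pos = pos, len = 1L)))
}

#' End-to-end synthetic phage-escape experiment
#'
#' Reconstructs the escape scenario on synthetic data: a host whose type
#' I-F-like array holds three spacers matching a phage at planted
#' protospacers — one antisense with a mutated (AG) PAM, one antisense
#' with the canonical GG PAM, one sense with mismatches including a seed
#' mismatch. The phage is scanned and per-system competence predicted
#' (only the GG-PAM protospacer supports type I-F interference; both
#' antisense protospacers support type III-B; the sense one supports
#' neither). An escape cohort is then generated by mutating the
#' I-F-targeted protospacer (large spanning deletions, a seed
#' substitution, a seed frameshift), each variant genome is diffed
#' against the parent and its escape mutations classified, and
#' plaquing efficiencies across host genotypes are simulated from the
#' competence calls (each active interference route multiplies phage
#' survival by `perRouteEscape`).
#'
#' @param config a [RunConfig-class].
#' @param nVariants escape cohort size.
#' @param phageLength phage genome size (bp).
#' @param perRouteEscape phage survival factor per active interference
#'   route.
#' @param outDir directory for result TSVs.
#' @return list (`PipelineReport`): `matches` (annotated competence
#'   table), `phage_truth`, `cohort` (per-variant escape classes),
#'   `eop_table`, `mpn_demo`, `config`, `files`.
#' @export
runEscapeExperiment <- function(config = runConfig(), nVariants = 11L,
                                phageLength = 20000L,
                                perRouteEscape = 0.02,
                                outDir = NULL) {
  if (is.null(outDir)) outDir <- tempfile("escape_experiment_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hostObj <- generateHost(genomeLength = 30000L, seed = config@seed,
                          arraySpecs = list(
                            list(name = "CRISPR04", nSpacers = 3L, spacerLength = 32L),
                            list(name = "CRISPR03", nSpacers = 8L, spacerLength = 32L)))
  ifArray <- hostObj$arrays[[1]]
  specs <- list(
    list(array = 1L, spacer = 1L, orientation = "antisense", pam = "AG",
         nMismatches = 1L, seedMismatch = FALSE, flank = "random"),
    list(array = 1L, spacer = 2L, orientation = "antisense", pam = "GG",
         nMismatches = 0L, flank = "random"),
    list(array = 1L, spacer = 3L, orientation = "sense", pam = "TG",
         nMismatches = 5L, seedMismatch = TRUE, flank = "random"))
  phage <- generatePhage(hostObj$arrays, specs, genomeLength = phageLength,
                         config = config, seed = config@seed)
  matches <- scanArray(ifArray, phage$genome, orfs = phage$orfs, config = config)
  # keep the best placement per spacer (the planted protospacer)
  matches <- do.call(rbind, lapply(split(matches, matches$spacer_id), function(m)
    m[which.min(m$mismatches), , drop = FALSE]))
  matches <- matches[order(matches$start), , drop = FALSE]

  # escape cohort: every variant mutates the I-F-susceptible protospacer
  # (the one with a canonical PAM); 8 distinct mutations, reused beyond 8
  psIF <- phage$truth[phage$truth$typeIF_competent, , drop = FALSE][1, ]
  set.seed(stageSeed(config@seed, "escape_cohort"))
  baseTypes <- c(rep("deletion", 6L), "seed_substitution", "seed_frameshift")
  types <- baseTypes[(seq_len(nVariants) - 1L) %% length(baseTypes) + 1L]
  seedOffsets <- sample(seq(config@seedRegion[1], config@seedRegion[2]),
                        nVariants, replace = TRUE)
  cohort <- data.frame()
  for (v in seq_len(nVariants)) {
    ev <- escapeEventsFor(psIF, types[v], config,
                          as.character(phage$genome[[1]]), seedOffsets[v])
    mut <- mutatePhage(phage, ev, config,
                       seed = stageSeed(config@seed, paste0("variant_", v)))
    calls <- diffGenomes(phage$genome, mut$genome, config)
    esc <- classifyEscape(calls$variants, phage$truth, config)
    cohort <- rbind(cohort, cbind(variant = sprintf("esc%02d", v),
                                  planted = types[v], esc))
  }

  # susceptibility across host genotypes from the competence calls
  nIF <- sum(matches$typeIF_competent)
  nIIIB <- sum(matches$typeIIIB_competent)
  routes <- c(WT = nIF + nIIIB, dIFcas123 = nIIIB, dIIIB = nIF, dIFdIIIB = 0L)
  inoculum <- 1e8
  set.seed(stageSeed(config@seed, "plaque_counts"))
  titers <- vapply(routes, function(r) {
    mu <- inoculum * perRouteEscape^r
    stats::rpois(1L, mu * 0.1) / 0.1  # 0.1 mL plated
  }, numeric(1))
  eopTable <- data.frame(genotype = names(routes),
                         active_routes = as.integer(routes),
                         pfu = titers,
                         eop = titers / titers["WT"])

  # MPN demonstration on the extreme genotypes
  mpnDemo <- lapply(c("WT", "dIFdIIIB"), function(g) {
    vols <- rep(10^-(0:2), each = 3) * 1
    tubes <- rep(1L, 9L)
    pos <- as.integer(stats::runif(9) < 1 - exp(-titers[g] * vols))
    est <- mpn(tapply(pos, rep(1:3, each = 3), sum),
               rep(3L, 3L), 10^-(0:2))
    data.frame(genotype = g, true_titer = titers[g], mpn_titer = est$titer,
               censored = est$censored)
  })
  mpnDemo <- do.call(rbind, mpnDemo)

  writeResultTsv(matches, file.path(outDir, "protospacer_matches.tsv"))
  writeResultTsv(cohort, file.path(outDir, "escape_cohort.tsv"))
  writeResultTsv(eopTable, file.path(outDir, "eop_simulation.tsv"))
  list(matches = matches, phage_truth = phage$truth, cohort = cohort,
       eop_table = eopTable, mpn_demo = mpnDemo, config = config,
       files = reportDigests(outDir))
}
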