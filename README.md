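# crisprCrossTalk

Some bacteria carry more than one CRISPR-Cas system, and the systems can
share guides: a type III-B effector complex can load crRNAs transcribed
from a type I-F array. Because type III targeting is
transcription-dependent and PAM-independent, while type I-F targeting
requires a canonical GG protospacer-adjacent motif and an intact seed
region, a host with both systems can keep suppressing phage mutants that
escape type I-F interference through PAM or seed mutations.
`crisprCrossTalk` implements the computational arm of this biology as a
tested, reusable R package:

* **Spacer orientation and strand bias** — map newly acquired spacers to
  the host genome, call sense/antisense orientation against annotated
  genes, and compare the sense fraction with its annotation-derived null.
  With a fraction *a* of genome bases inside genes, no bias yields a
  sense fraction of *a*/2 — e.g. 0.886/2 = **44.3%**, not 50%, because
  intergenic spacers give no basis for strand assignment.
* **Acquisition null envelope** — Monte Carlo null for spacer acquisition
  versus gene expression, built from trials of 500 spacers drawn by
  length-weighted **stochastic universal sampling** (SUS), 1000 trials,
  with the envelope as the pointwise range of cumulative acquisition
  curves along the expression ranking.
* **Pre-crRNA processing detection** — classify small-RNA reads by the
  5-base repeat-prefix anchor, trim, resolve sub-12-nt prefixes through
  the 5-base spacer junction rule, and build tRNA-normalized
  trimmed-length histograms. Site-specific processing appears as a modal
  3' end 8 nt upstream of the repeat 3' end (the crRNA handle length).
* **Protospacer scanning and interference prediction** — Hamming scan of
  phage genomes for 32-bp spacer matches; annotate PAM (GG canonical;
  AG/TG are typical escape PAMs), seed mismatches (positions 1–8 from
  the PAM-proximal end), orientation versus the phage transcript, and
  repeat-derived ("self") flanks; predict per-system interference
  competence:
  * type I-F: canonical PAM ∧ no seed mismatch ∧ mismatches ≤ 5
  * type III-B: crRNA complementary to mRNA ∧ non-self flank ∧ mismatches ≤ 5
* **Phage variant calling and escape classification** — unique-21-mer
  anchor chaining between collinear genomes; SNVs, indels and structural
  deletions (≥ 50 bp) with exact Δstart–end breakpoints; escape classes
  per protospacer (spanning deletion, PAM mutation, seed substitution,
  seed frameshift); in-silico PCR; global protein comparison with
  identity/similarity and C-terminal loss.
* **Assay quantification** — log10 cfu/mL with detection-limit censoring,
  efficiency of plaquing (EOP), Most Probable Number titers by maximum
  likelihood under the Poisson single-hit model, and relative protospacer
  transcript levels (log10 RNA reads / log10 DNA reads).
* **Synthetic-data generators** — hosts with a controlled intergenic
  fraction (default 11.4%), log-normal expression, embedded CRISPR
  arrays; acquired-spacer reads with tunable strand bias; mature crRNA
  reads with tRNA background; phages with planted protospacers; variant
  phages with planted mutations. Every generator emits a truth table, so
  every analysis stage is testable end to end without downloads.

## Worked example

```r
library(crisprCrossTalk)

cfg  <- runConfig(seed = 1)
host <- generateHost(genomeLength = 100000, intergenicFraction = 0.114,
                     seed = 1)
annotatedFraction(host$host)
#> [1] 0.886

sim  <- simulateAcquiredSpacers(host, 500, source = "RNA",
                                antisenseBias = 0.5, seed = 2)
hits <- mapSpacers(sim$spacers, host$host, cfg@maxMismatches)
cl   <- classifyOrientation(hits, geneRanges(host$host))
sb   <- strandBias(cl, host$host)
c(sense = sb$sense_fraction, null = sb$null_expectation)
#>  sense   null 
#> 0.4340 0.4430
```

An unbiased sample lands at the 44.3% null within sampling noise. The
escape experiment chains the phage modules:

```r
esc <- runEscapeExperiment(cfg, nVariants = 11)
esc$matches[, c("spacer_id", "pam", "typeIF_competent", "typeIIIB_competent")]
#>       spacer_id pam typeIF_competent typeIIIB_competent
#> 1 CRISPR04_sp01  AG            FALSE               TRUE
#> 2 CRISPR04_sp02  GG             TRUE               TRUE
#> 3 CRISPR04_sp03  TG            FALSE              FALSE
table(esc$cohort$escape_class[esc$cohort$protospacer == "ps02"])
#> deletion_spanning_protospacer  seed_frameshift  seed_substitution
#>                             9                1                  1
```

Only the GG-PAM protospacer supports type I-F interference; both
antisense protospacers support type III-B; the sense, seed-mismatched one
supports neither. Every escape variant mutates the I-F-targeted
protospacer and is classified exactly.

## Tests

```sh
Rscript -e 'devtools::test()'
```

The suite cross-checks every optimized routine against an independent
brute-force oracle (Hamming scans, anchor search, MPN grid likelihood,
multinomial sampling) and validates all stages against generator truth
tables.
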