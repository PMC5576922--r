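---
title: "Models and methods behind crisprCrossTalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprCrossTalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprCrossTalk)
```

# The biological setting

A marine bacterium carrying two CRISPR-Cas systems — a type I-F system
with a GG-PAM-dependent DNA-targeting effector, and a type III-B system
whose Cmr effector performs transcription-dependent interference — can
share guides between them: type I-F crRNAs are loaded by the type III-B
machinery. The consequence is a two-layer defense. A phage that mutates a
protospacer-adjacent motif (PAM) or a seed position escapes type I-F
interference, but as long as the protospacer is transcribed and the
crRNA is complementary to the mRNA, the type III-B layer still fires.
This package implements the analyses that establish and quantify that
picture: strand-bias statistics for newly acquired spacers, a Monte
Carlo acquisition null, small-RNA evidence of pre-crRNA processing,
protospacer annotation with per-system interference prediction, phage
escape-mutation classification, and the plate/dilution arithmetic of the
associated assays — all exercised end to end on synthetic data with
known truth.

# Strand bias of acquired spacers

Newly acquired spacers are mapped to the host genome (best Hamming hit,
ties resolved to the leftmost hit on the plus strand, then the minus
strand; one best hit per spacer, because each acquired spacer has one
true source). A hit is *sense* when it matches the coding strand of an
overlapping gene, *antisense* when it matches the template strand, and
*unassigned* when no gene overlaps. We require at least 50% of the
spacer inside the gene — the boundary is not addressed by the underlying
protocol, and the 50% rule makes the expected assignment probability per
uniformly placed spacer equal to the gene's base fraction.

The central arithmetic: the sense fraction is computed over **all**
mapped spacers, unassigned ones included. If a fraction $a$ of genome
bases lies in annotated genes, an orientation-blind acquisition process
gives a sense fraction of $a/2$. With the study host's $a = 0.886$
(11.4% intergenic), the no-bias expectation is 44.3%, not 50% — which is
why `strandBias()` derives its null from the annotation rather than
assuming one half. Group comparisons use a two-sided Welch test on
per-sample sense fractions (the source protocol says only "t-test"; the
unequal-variance form is the safer default and agrees with a permutation
oracle within a factor of two in our tests).

When interference is active, antisense spacers matching host genes are
an autoimmunity risk: cells that acquire them are selected against. The
end-to-end simulation (`runBiasExperiment()`) models this as post-hoc
purging of antisense gene-derived spacers with a survival probability
(default 0.05). That is a selection model, not a measured rate; it is
the simplest mechanism that reproduces the observed sense enrichment in
the interference-proficient genotype.

# The acquisition null envelope

The null hypothesis — acquisition from genomic DNA with no dependence on
expression — is simulated by drawing 500 spacers per trial from all
genes with probability proportional to gene length using **stochastic
universal sampling** (SUS): a single random offset and 500 equally
spaced pointers over the cumulative length line, so each gene receives
the floor or ceiling of its expected count. 1000 such trials give a
family of cumulative acquisition curves along the genes ranked by
descending expression (ties broken by gene id for determinism); the
envelope is their pointwise min/max — an exact range, matching the
method's description — with a quantile band available as an option.
Curves above the envelope at early (high-expression) ranks indicate
preferential acquisition from highly expressed genes.

Two numerical facts matter for interpretation. First, SUS is strongly
under-dispersed relative to independent (multinomial) sampling — that is
its purpose, and the tests verify the variance ordering directly.
Second, as a consequence, the exact-range envelope is *narrower* than
the sampling noise of any finite independently drawn sample: a curve
built from $n$ iid length-weighted draws has cumulative standard errors
around $\sqrt{0.25/n}$ (≈ 0.022 at $n = 500$), while the envelope's
half-width at the same design is roughly 0.005. An expression-blind iid
sample therefore oscillates *around* the envelope rather than sitting
inside it at every rank. The package's tests treat the envelope the way
it is used scientifically — directionally: expression-weighted (RNA
source) acquisition rises above it decisively at early ranks, a
length-only (DNA source) sample does not — and additionally verify exact
coverage for observations drawn by the null procedure itself.

# Pre-crRNA processing from small-RNA reads

Reads are classified against a CRISPR repeat by an exact, leftmost match
of the repeat's first 5 bases (the anchor). The prefix before the anchor
is the trimmed read. Classes, in order: no anchor; trimmed prefix an
exact substring of the repeat (an empty prefix counts — pure-repeat
reads carry no spacer evidence); for trimmed prefixes shorter than 12 nt,
a junction test comparing the last 5 trimmed bases with the last 5 bases
of each genomic spacer (confirmed/rejected); otherwise an accepted
crRNA-derived read. Matching is exact and strand-specific — the
sequencing protocol this emulates preserves strand — and a mismatch
allowance is deliberately not enabled by default.

Histograms of trimmed lengths are normalized to the read count of the
most abundant tRNA reference (isoleucine tRNA in the study system; the
generator reproduces a designated dominant species). Site-specific
processing shows up as a modal trimmed length of handle + spacer: with
the 8-nt repeat-derived 5' handle and 32-nt spacers, trimmed length 40,
i.e. a cleavage site 8 nt upstream of the repeat 3' end. The modal
(trimmed length − spacer length) over spacer-attributable reads is
reported as the dominant 3' offset. Detection against a control profile
requires a 5-fold enrichment of the modal bin (the underlying work never
quantifies "processed efficiently"; 5× is a package default, exposed in
the configuration).

# Protospacer annotation and interference prediction

Protospacers are located by exhaustive Hamming scanning on both strands
(no indels — all matches of interest are length-preserving 32-mers), with
"N" never matching. The PAM is read as the two bases immediately 5' of
the protospacer on its matching strand; the 5' convention is explicit
and switchable, since the source figures identify PAM positions only
graphically. The seed region is positions 1–8 from the PAM-proximal
end, following the type I-F seed literature; its width is configurable.

Self/non-self discrimination for type III targeting compares the
`handleLen` (8) bases immediately 5' of the protospacer on the match
strand with the repeat's 3'-terminal 8 bases — in the host's own array
that flank *is* the repeat tail, and base-pairing between it and the
crRNA handle suppresses targeting. Full identity is required by default
(the repeat-flanked constructs this models used complete repeats);
partial-complementarity tolerance is untested biology and left
configurable.

Competence rules:

* **type I-F** — canonical PAM, no seed mismatch, total mismatches
  within the ceiling (default 5). Transcription-independent, so
  orientation never enters.
* **type III-B** — crRNA complementary to the transcript (spacer matches
  the strand opposite the overlapping ORF), non-self flank, mismatches
  within the ceiling. PAM-irrelevant.

Every negative call carries machine-readable reasons. When no ORF
annotation is supplied, a minimal 6-frame ATG-to-stop caller (≥ 150 nt)
provides the transcript model.

# Phage genome comparison and escape classes

Near-identical collinear genomes are compared by chaining 21-mers unique
in both sequences; out-of-order anchors (rearrangements) are filtered by
a longest-increasing-subsequence pass and flagged. A k-mer that
coincidentally spans a variant can extend a block past it, so block
overlaps are trimmed before gap resolution. Gaps with one empty side are
direct insertions/deletions (structural at ≥ 50 bp, reported with
Δstart–end breakpoints); short non-identical gaps are resolved by global
alignment. A contiguous multi-base event counts as one site — an
insertion plus six SNVs is seven sites — and indels are left-normalized
so equivalent placements (a deletion inside a repeat can be written at
several offsets) compare identically between caller and truth.

Escape classification per protospacer, by priority: a deletion spanning
the whole protospacer; an SNV at a PAM position (PAM escape is the
central mechanism, so PAM positions are included even though the
underlying tabulation lists protospacer-region mutations); a seed
substitution; a seed indel (frameshift); any other in-protospacer
change; none.

Protein comparison uses Needleman–Wunsch with BLOSUM62; identity and
similarity are fractions of alignment columns. The C-terminal loss —
residues beyond the last reference position aligned to a non-gap — is
exact for premature-termination variants (a truncated protein anchors
the alignment), but when a variant carries a run of *modified* residues
before its end, global alignment may legitimately place the gap run
internally, making the tail-loss readout construction-dependent; the
tests therefore pin exact values only on pure truncations.

# Assay quantification

Plate counts become log10 cfu/mL; zero counts are reported at the assay
detection limit with a lower-censoring flag, and the "too many to count"
sentinel upper-censors without a numeric value. Censoring flags travel
with values and are never silently dropped. EOP is the fold change in
pfu against the reference host (EOP = 1 by definition). MPN titers are
maximum-likelihood under the Poisson single-hit model
$P(\text{positive}) = 1 - e^{-cv}$, maximized numerically over
log-concentration rather than read from historical lookup tables; the
single-level closed form ($c = -\ln(1 - p/n)/v$) and a grid-search
likelihood oracle verify the optimizer. All-negative series are censored
at zero, all-positive series yield only a lower bound. The relative
transcript level is $\log_{10}(\text{RNA reads}) / \log_{10}(\text{DNA
reads})$ with a count floor of 10 (the source defines no floor; 10
guards the logarithm of small counts) — deliberately not scale-invariant,
as it is a relative incidence across constructs, not a per-cell ratio.

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Host** — default 100 kb; genes placed without overlap so the realized
  intergenic fraction equals the requested 11.4% (within ±0.01);
  per-gene log-normal expression (meanlog 3, sdlog 1 — a generic
  heavy-tailed transcriptome); two CRISPR arrays with random 28-bp
  repeats constrained below 60% mutual identity, mirroring the sparse
  similarity of the two systems' repeats, embedded in intergenic space
  as repeat–spacer–…–repeat runs of 32-bp spacers.
* **Acquired spacers** — a spacer comes from intergenic sequence with
  probability equal to the intergenic base fraction (uniform over gaps
  that can hold it, strandless, unassignable); otherwise from a gene
  weighted by length × expression (RNA source, with a tunable exponent)
  or length alone (DNA source), placed fully inside the gene, antisense
  with probability *b* (RNA) or exactly 0.5 (DNA — double-stranded
  substrate has no strand memory). This is the simplest model that
  makes the 44.3% null emerge from the annotation arithmetic and
  reproduces the expression (transcriptional) bias of RNA-derived
  acquisition.
* **crRNA reads** — handle (8 nt) + spacer + a 3' stub of the next
  repeat's first bases. Mature crRNA 3' ends are heterogeneous and
  their distribution is not quantified in the source; stubs are uniform
  over 5–8 nt, the lower end chosen so every mature read contains the
  5-nt anchor (a read with a shorter stub is physically unanchorable and
  would be unclassifiable by any anchor-based rule). Arrays are
  additionally generated anchor-clean — the repeat's 5-base prefix does
  not occur inside handles or spacers — so noiseless reads trim at the
  genuine repeat junction. Background reads are full-length tRNA copies
  (one designated species most abundant, emulating the isoleucine tRNA
  normalizer) plus random fragments.
* **Phage** — planted protospacers inside synthetic ORFs with requested
  orientation, PAM, mismatch count (optionally including one seed
  mismatch), and flank mode (random, or repeat-derived to reproduce the
  self-flank configuration). Escape variants carry planted SNVs, short
  indels and large deletions, recorded in left-normalized form.

What the generator does **not** model — sequencing errors, quality
scores, paired ends, realistic phage gene content, partial processing
intermediates — bounds what passing tests show: they demonstrate the
correctness of the algorithms and decision rules on clean data, not
robustness to noisy libraries.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout (GRanges/IRanges and
  GFF3 share the convention), with range arithmetic delegated to
  IRanges.
* One master seed; each stochastic stage forks a deterministic stream
  from (seed, stage name), so stage order never changes results, and
  identical configurations reproduce outputs byte-for-byte.
* Problem sizes in the tests and the acceptance script — 100-kb hosts,
  20-kb phages, 100 samples of 500 spacers, 500–1000 envelope trials,
  500 MPN series — were chosen as the smallest sizes at which every
  statistical check is decisively powered.
* The mapping fast path finds exact placements for all spacers of one
  width in a single dictionary pass and escalates the allowed mismatch
  count only for the remainder; tests assert equality with a windowed
  brute-force Hamming oracle.
* The end-to-end susceptibility simulation models each competent
  (system, protospacer) pair as an independent interference route
  multiplying phage survival by 0.02; this reproduces the qualitative
  genotype ordering (WT least susceptible; then the I-F targeting
  deletion, which keeps both III-B routes; then the III-B deletion,
  which keeps one I-F route; then the double deletion) without claiming
  the wet-lab magnitudes, which depend on plaque physiology outside this
  package's scope.

# Known limitations

* Hamming-only protospacer matching: an indel inside a protospacer is
  found by the variant caller, not the scanner.
* The exact-range envelope's under-coverage of iid noise (above) means
  per-rank "within" calls should be read directionally for real data.
* The anchor-based read classifier accepts only literal repeat
  substrings; repeat rotations spanning the spacer-repeat junction are
  not counted as repeat-derived.
* MPN assumes perfect Poisson single-hit behavior; aggregation or
  inhibition in real dilution series biases titers in ways the model
  cannot see.
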