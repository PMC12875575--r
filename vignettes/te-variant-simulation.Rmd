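---
title: "Simulating and benchmarking transposable element variants with TEforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking transposable element variants with TEforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Transposable elements (TEs) — LINE-1, Alu, SVA, endogenous retroviruses —
are mobile sequence classes whose presence or absence at a locus varies
between haplotypes, individuals and populations. Dozens of tools detect and
genotype such TE variants from short- or long-read data, but their relative
accuracies are hard to establish without ground truth. TEforge generates
that ground truth: it plants TE insertions and deletions into a reference,
produces the variant-containing genomes, the sequencing reads, and the truth
VCF, and then scores a detector's calls against that truth.

```{r}
library(TEforge)
```

## The variant model

A TE variant is either an **insertion** (a TE sequence present in a sample
but absent from the reference) or a **deletion** (a TE interval of the
reference absent from a sample). Internally the catalog is a `GRanges`:
deletions span their reference interval, insertions are zero-width ranges
marking the insertion point — an insertion at 0-based point $p$ is placed
between reference bases $p-1$ and $p$. On disk the catalog is a 7-column
BED (0-based half-open; insertions have start = end) plus a FASTA of
insertion sequences keyed by variant id. Real-insertion FASTA identifiers
(`chr1-683234-AluSp#SINE/Alu`) carry 1-based positions, which are
decremented on load; this convention is stated here because identifier
conventions in public TE datasets are rarely explicit.

Three generators produce catalogs:

* **random** — consensus sequences are drawn from a library, individually
  mutated (below), and dropped at uniform random positions, rejecting
  points inside long N runs, inside user-excluded regions, or colliding
  with already placed variants; deletions are sampled *without replacement*
  from a BED of known TE intervals, never invented, so deletion
  breakpoints always correspond to annotated elements.
* **real** — insertions are taken verbatim from a FASTA of observed
  insertions with RepeatMasker-style identifiers.
* **pangenome** — simple bubbles of a GFA 1.x graph (two internally
  vertex-disjoint walks between two reference-path anchors) are detected
  natively; a bubble whose off-reference side classifies to a TE family
  becomes an insertion, one whose reference-only side classifies becomes a
  deletion. Classification is by k-mer containment (fraction of the query's
  k-mers present in a library entry, strand-aware), with defaults k = 15
  and threshold 0.5: a 15-mer match is ~1 in 10^9 by chance, so random
  sequence scores near 0 while even half-length truncated TE copies score
  far above 0.5. Only simple two-path bubbles are extracted; nested or
  cyclic regions are skipped with a warning.

Conflicting variants at merge time (overlapping deletions, an insertion
strictly inside a deletion, duplicate insertion points) are resolved by
dropping the later-sorted variant with a warning rather than failing: a
simulator should always deliver a usable catalog, and the warning tells the
user what was thinned.

## The consensus mutation model

Real TE copies differ from their consensus. `mutateSequence()` applies, in
a fixed order, 5' truncation → SNPs → INDELs → 3' polyA tail:

* each non-N base mutates to one of the other three bases with probability
  `snpRate` (default 0.02 per base);
* each position seeds an INDEL with probability `indelRate` (default
  0.005), insertion or deletion with equal probability, with length drawn
  from a geometric distribution on {1, 2, ...} with success parameter
  `indelGeomP` (default 0.7, mean length 1/0.7 ≈ 1.43 bp);
* a sequence is 5'-truncated with probability `truncateSeqFraction`
  (default 0.3), removing a uniform prefix of at most
  `maxTruncateLenFraction` (default 0.5) of its length — 5'-truncation
  is the canonical incomplete-retrotransposition signature of LINE-1;
* a polyA tail of uniform length in `[polyaMinLen, polyaMaxLen]` bp
  (defaults 5–50) is appended with probability `polyaFraction` (default 1).

The polyA bounds and fraction are this package's own defaults, chosen as
simple bounded values spanning the short tails typical of genomic TE
copies, and are user-overridable. Two readings of the truncation
parameters are possible (per-sequence probability versus per-length
fraction); both are exposed as separate fields —
`truncateSeqFraction` is the fraction of *sequences* truncated,
`maxTruncateLenFraction` the maximum fraction of *length* removed.

The fixed edit order gives every recorded edit a single well-defined
coordinate frame, which is what makes the edit list replayable: truncation
length refers to the source, SNP positions to the truncated sequence,
INDEL positions to the post-SNP sequence (applied right-to-left), polyA
last. Each output carries a `VAR=` annotation string (e.g.
`VAR=T5:120,S:17:CT,I:30:AC,PA:25`) that round-trips losslessly and is
embedded in FASTA identifiers, so any simulated sequence can be audited
back to its consensus.

```{r}
m <- mutateSequence(strrep("ACGT", 100), VariationProfile(polyaMaxLen = 10))
m@annotation
identical(replayEdits(strrep("ACGT", 100), m@edits), m@sequence)
```

## Genotypes and chunk-merge genome assembly

Each variant draws an allele frequency f ~ Uniform(`freqLow`, `freqHigh`)
(defaults 0.1–0.9, spanning common and rare polymorphisms without fixing
or losing variants), and each haplotype carries the alternate allele
independently with probability f — a site-frequency model without linkage,
which is adequate for detector benchmarking though not for LD-aware
analyses.

Assembling m genomes by cutting and splicing the reference once per
variant costs O(m·n·c) for n variants and genome length c. TEforge instead
partitions each chromosome **once** at all variant breakpoints into at
most 2n+1 blocks — invariable blocks, deletion blocks, and zero-width
insertion points — and builds every haplotype by block concatenation,
reducing the cost to O(m·(n+c)). The naive right-to-left applier is kept
in the package (`naiveApply()`) purely as a correctness oracle: the test
suite asserts byte-identical output and identical 21-mer multisets between
the two routes on randomized instances. One boundary convention matters
and is fixed by those oracle tests: when an insertion point coincides with
a deletion start, the insertion lands in front of the deleted interval.

The truth VCF (4.2) uses explicit REF/ALT sequences anchored on the base
preceding the event (events at a chromosome start anchor on the following
base), never symbolic `<INS>`/`<DEL>` alleles — precisely so that applying
the VCF back onto the reference is an exact, testable round trip
(`applyVcfToReference()`). INFO records SVTYPE, signed SVLEN, family,
superfamily and the simulated allele frequency; genotypes are unphased by
default with phased emission behind a flag. Within-cohort TE sequence
diversity (`perGenomeProfile`) mutates each spliced insertion per
haplotype under its own RNG sub-stream, with truncation and polyA disabled
in that pass so the locus structure is preserved; the VCF intentionally
records only presence/absence, not these per-genome micro-edits, because
the truth set describes TE variants, not private SNVs inside them.
Diploid samples are written as two haplotype FASTAs (`_h1`/`_h2`); the
haplotype order carries no meaning.

## Read simulation

The read simulators are native so the package is self-contained and its
outputs fully deterministic per seed; `emitReadsimCommands()` prints
equivalent Mason2/PBSIM3 invocations for users who prefer those engines.

Short reads: N = round(depth × L / (2 × readLength)) fragment positions
are drawn uniformly (chromosomes proportional to length), fragment lengths
from Normal(mean, sd) truncated to [readLength, chromosome length]; R1 is
the 5' end, R2 the reverse complement of the 3' end; substitution errors
are i.i.d.; base qualities are a constant Phred value (no quality model is
claimed). Long reads: reads are drawn until the emitted bases reach
depth × L, lengths from a truncated Normal — chosen over a lognormal
because its two parameters are exactly the user-facing mean and sd —
with base-wise errors split into substitution/insertion/deletion
fractions. Depth is defined per individual and split evenly across the
haplotypes passed in (`nHaplotypes`). Neither simulator models
platform-specific error profiles or homopolymer artifacts; tests
therefore validate coverage identities, fragment-length recovery and
error rates, not realism of error spectra.

## Comparison and metrics

Truth and predicted calls (VCF or BED) are normalized to representative
positions: a VCF POS is read as the left anchor, so the event point equals
POS in the internal 0-based frame; a BED row contributes its start. Pairs
on the same chromosome within `--tolerance` bp (default 50) are matched
greedily by ascending distance, ties broken by ascending truth then
predicted position, each variant used once; `--type-aware` restricts
INS to INS and DEL to DEL. Greedy matching with deterministic tie-breaks
was chosen for reproducibility; on crossing configurations it can fall one
match short of the maximum-cardinality assignment (truth {0, 6},
predictions {5, 11}, tolerance 5 is the canonical counterexample, frozen
in the test suite with a brute-force matcher as the oracle). Then

* sensitivity = tp/(tp+fn), precision = tp/(tp+fp), F1 their harmonic
  mean, each `NA` when its denominator is zero;
* genotype accuracy = the fraction of positionally matched pairs with
  exactly identical genotypes, compared as unordered allele multisets
  (0/1 ≡ 1/0; `./.` counts as absent), over the pairs genotyped on both
  sides — so presence-only detectors are scored on detection without
  being penalized on genotyping.

## Synthetic fixtures and what passing tests mean

Everything the test suite consumes is generated in code: i.i.d. reference
sequences at a requested GC with planted N runs, random consensus
"families" at realistic length scales (Alu-like 300 bp, L1-like 6 kb,
SVA-like 1.5 kb, ERV-like 8 kb — synthetic sequences, no real consensus is
shipped), toy GFA graphs built bubble-by-bubble with a manifest of the
variants they encode, and `degradePredictions()`, which turns a truth VCF
into an imperfect "detector" with known jitter, miss rate, spurious-call
rate and genotype-flip rate. The end-to-end check recovers those rates
through the comparison module within binomial sampling error.

These fixtures deliberately lack the things that make real TE detection
hard: repeat-rich flanks, nested and truncated pre-existing elements,
GC-biased coverage, platform error spectra. Passing tests therefore
demonstrate that the simulator's bookkeeping (coordinates, genotypes,
round trips, metric arithmetic) is exact, not that any detector will
perform comparably on real genomes.

## Numerical and design choices

* **RNG**: one master seed; per-sequence and per-haplotype work derives
  sub-seeds by stable string hashing (`substreamSeed()`), so per-item
  output is independent of processing order and cohorts are reproducible
  end to end.
* **Problem sizes in tests**: toy references of 2.5–150 kb, cohorts of a
  few samples, one 1 Mb / 500-variant end-to-end run, 10^5-draw
  distributional checks — sizes at which every distributional assertion
  has power (3-SE bands) while the whole suite runs in minutes on one CPU.
* **Degenerate inputs**: empty catalogs simulate to the unchanged
  reference; an empty edit list encodes as `VAR=none`; zero-denominator
  metrics are `NA`, never 0 or 1; placement failure after bounded retries
  reports the achieved count.
* **Known limitations**: no target-site duplications or insertion-strand
  inversions; uniform parameters across TE families (no family-specific
  insertion preferences or mutation spectra); no background genome-wide
  SNP model; ploidy ≤ 2; simple bubbles only in pangenome extraction.
  Region-biased insertion (enriching or excluding specific intervals) is
  achieved by editing the catalog BED between generation and simulation,
  which the BED/FASTA round trip supports directly.
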