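---
title: "Methods: structural discovery and annotation of retrozymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural discovery and annotation of retrozymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrozyme)
```

## The biological object

Retrozymes are small non-autonomous LTR retroelements of plants.  A
full genomic copy consists of two direct-repeat LTRs of roughly
300–400 bp flanking a non-coding internal region of roughly
300–600 bp, with a 4-bp target-site duplication (TSD, consensus WWRR)
on either side.  Each LTR carries one hammerhead ribozyme (HHR);
transcription followed by self-cleavage at the two ribozymes releases
a monomeric RNA of about 600–1000 nt whose length is exactly the
cleavage-to-cleavage distance, and which circularizes in vivo.  Two
~25-nt domains are shared with Ty3-gypsy retrotransposons: a 3' box
spanning the LTR 3' end plus the tRNA-Met primer binding site (PBS),
and a 5' box spanning the polypurine tract (PPT) plus the LTR 5' end.
This package implements the in-silico discovery pipeline for these
elements and a synthetic-genome benchmark for it.

## The hammerhead descriptor and scanner

The HHR is modelled as a cycle: helix I, the core segment CUGANGA,
helix II closed by loop 2, the core segment GAAA, helix III closed by
loop 3, the cleavage context NUH immediately 5' of the scissile bond,
and back into helix I.  A genomic motif linearizes the cycle by
opening exactly one helix; the open helix names the topology (type I,
II or III).  The constrained catalytic core comprises the two core
segments (7 + 4 nt), the cleavage context (3 nt) and one invariant
residue immediately 3' of the cut — the first base of helix I, fixed
to C so that helix I closes with a C:G pair — for a total of
`r core_positions(hhr_descriptor())` positions.  The residue-level
identity of the core lives entirely in the configuration
(`hhr_descriptor()`), so a user who prefers a different transcription
of the catalytic core can change it without touching code; the
reported core-position count always tracks the configured strings.

Tunable parameters, with defaults:

* helix length ranges — helix I 3–7 bp, helix II 3–6 bp, helix III
  2–5 bp; loops of closed helices 3–20 nt.  These span the motif sizes
  of typical plant hammerheads; the full motif never exceeds 150 nt.
* pairing — Watson–Crick plus at most one G·U wobble per helix.
  Natural hammerhead helices tolerate occasional wobbles; more than
  one per short helix is rare.
* topologies — types I and III by default (the forms described in
  plants); type II scanning is implemented but off by default, and a
  type II hit is never flagged bona fide because the loop 1–loop 2
  interaction it would need has no loop 2 to interact with.
* bona-fide filter — a hit is bona fide when the longest contiguous
  antiparallel Watson–Crick run between loop 1 and loop 2 (for type I,
  between the terminal 6 nt of the distal helix-I arm and loop 2) is
  at least 2.  This is a stand-in for the manual inspection of
  loop–loop tertiary contacts used in the field; it is deliberately
  permissive and should not be read as reproducing any curator's
  judgement exactly.

The search seeds on exact occurrences of the least-degenerate core
word (CTGA under the defaults) and attempts junction assembly around
each seed within the length ranges, on both strands.  Overlapping
candidates are resolved greedily by descending helix-stability score
(GC = 3, AT = 2, GT = 1 summed over all pairs), then leftmost.  A
consequence of seeding is that motifs mutated inside the seed word are
invisible to the scanner by design; degenerate relatives are recovered
separately by `find_degenerate_copies()` (90% identity over a 90-nt
window by default), mirroring the usual motif-search-then-BLAST
two-step.

Coordinates are 0-based half-open on the plus strand throughout, and
cleavage positions are between-base indices, so monomer extraction is
a pure slice and the monomer length is exactly `cleavage2 − cleavage1`
with no off-by-one ambiguity.  Ambiguity codes other than N are read
as N, and N never matches a descriptor position.

## Element assembly

Bona fide hits on the same contig, strand and topology whose
cleavage-to-cleavage spacings fall in 400–1100 nt are chained into
runs; a run of k hits spans k−1 monomer units.  For a pair, the two
motif regions are anchored at their cleavage sites and flanking
windows (±600 nt) are aligned with a banded global alignment (band
±10; match +1, mismatch −1, gap −2).  The LTR pair is reported as the
maximum-scoring aligned block containing the anchor, with two guards:
block ends must locally satisfy a rolling 20-nt identity of at least
0.6, and a score slack of 2 trims chance net-positive extensions a few
nucleotides past the repeat boundary (without the slack, a run of
random matches beyond the boundary occasionally drags the end out by
5–10 nt).  Delimitation fails — absence is a value — if the block is
shorter than 200 nt or below 70% identity, which is what rejects two
stray hammerheads in unrelated flanking sequence.

TSDs are sought as exact duplications whose left copy ends at the
element start and right copy begins at the element end, sliding the
boundaries by up to 12 nt.  The search prefers the smallest boundary
adjustment first, then the longest duplication (6 > 5 > 4), then the
leftmost position.  Preferring length over adjustment, the other
plausible order, turns out to be noisy: with a ±12 slide there are
625 boundary combinations, and a spurious 6-mer duplication somewhere
in that window would outrank the true 4-bp TSD at the unslid boundary
roughly 15% of the time.  A 4-bp TSD is additionally checked against
the WWRR consensus on the element's strand.

The junction boxes are matched with at most 6 mismatches in ±40-nt
windows around the expected junctions: the 3' box against the 3'
boundary of the element's 5' LTR, the 5' box against the 5' boundary
of the 3' LTR.  A standalone PPT detector also reports the longest
purine run (≥8 nt, at most one pyrimidine, starting and ending on a
purine) within 40 nt upstream of the 3' LTR.  The box consensus
strings themselves are configuration, not code: the defaults are
working placeholders (a canonical tRNA-Met PBS complement, TG…CA LTR
termini, a purine-rich PPT), and the synthetic generator embeds
whatever is configured, so every test is self-consistent regardless of
how faithfully a user transcribes the motifs of a particular plant
family.

Classification is a partition of the bona fide hits: `full_retrozyme`
(a pair with a delimited LTR block and a monomer inside 500–1200 nt —
deliberately wider than the natural 600–1000 nt so boundary noise
cannot flip a class), `multimeric_retrozyme(n)` for runs of three or
more hits, `solo_LTR` for an unpaired hit whose flanks carry the 5'
box upstream and the 3' box downstream across a 250–450 nt span (the
circular-template cDNA layout PPT–LTR–PBS), and `orphan_HHR`
otherwise.

## The fold module

The self-complementarity statistic (fraction of nucleotides paired) is
computed from a nested structure that maximizes the weighted number of
base pairs (GC = 3, AU = 2, GU = 1; hairpin loops of at least 3 nt),
via an interval dynamic program with a deterministic traceback, not
from a thermodynamic model.  This choice makes the optimum exactly
testable: an independent memoized recursion over the other end of each
interval reproduces the DP score on every random sequence tried, so
the implementation is verified against exhaustive enumeration rather
than against itself.  A thermodynamic engine can be substituted
externally by the user; no test requires one.  Two subtleties of this
model class are worth recording: only the optimal *score* is invariant
under reverse complementation (co-optimal structures can differ in
pair count when pair weights differ, and a G·U pair maps onto an
unpairable A·C), and the fraction-paired statistic of a weighted
maximization is sensitive to base composition.  At the generator's
40% GC, planted ~750-nt monomers fold to a fraction paired of about
0.75 (0.73–0.76 across seeds), which sits inside the ±7-percentage-
point band around the ~70% figure reported for natural retrozyme RNAs
from minimum-free-energy structures — a cross-model agreement worth
having, but not a thermodynamic validation.

`hhr_blocked()` quantifies the observation that in monomer structures
most of the hammerhead is sequestered by pairing with a complementary
region elsewhere in the RNA: it reports the fraction of motif
nucleotides whose partner lies outside the motif span.

## The consensus renderer

Per column, with gaps excluded from the denominator: a single base at
full conservation is uppercase; an all-purine (all-pyrimidine) column
is R (Y); a base at or above the partial threshold (default 0.70) is
lowercase; a purine (pyrimidine) class at or above the threshold is r
(y); anything else is a dot.  The precedence places the class-R/Y rule
before the lowercase-base rule, so a 7G+3A column renders R (it is
fully purine), while 7G+3U renders g.  Gap exclusion is a choice made
for robustness to ragged alignment ends; alignments themselves are an
input (a deliberately small center-star aligner is included only to
build test fixtures).

## The synthetic benchmark

`build_genome()` plants elements in an i.i.d. background (40% GC, a
typical plant-genome composition) at uniform non-overlapping
positions, on either strand with equal probability, all randomness
flowing from one seed.  The reference conditions are a 5-Mb genome
with 20 full elements, 5 solo LTRs, 2 three-ribozyme multimers and 10
decoys; 330-bp LTRs; internal regions of 300–600 bp (hence monomers of
~650–950 nt); 1% LTR–LTR divergence; 4-bp WWRR TSDs; type III motifs.
Decoys probe each filter independently: full-shaped elements whose
motifs carry one core substitution (scanner specificity), shuffled
monomers (sequence-composition specificity), bare motifs without LTR
context (classification), and LTR pairs without ribozymes (pairing).

Two generator policies deserve explanation.  First, LTR divergence is
applied outside the ribozyme footprint: a benchmark that demands
perfect recall of full elements is only coherent if the second
ribozyme stays functional, and biologically this mimics the purifying
selection that keeps both hammerheads active in elements that still
transpose.  Second, planted loci are verified to be unambiguous: in
about 0.5% of random draws the planted motif plus its chance context
admits a second, higher-scoring valid hammerhead reading (for
example, a type III core re-read as type I using accidental flanking
pairs) whose cleavage index differs; since ground truth must be
unambiguous, such loci are resampled.  The same phenomenon bounds what
specificity can mean: a motif carrying a single core substitution is
never called at its own cleavage site, but once in a few hundred
random contexts the mutated sequence plus its flanks happens to spell
a different, fully valid hammerhead at a shifted register — a chance
background motif, which the benchmark's decoy builders also screen
out so that planted decoys are genuinely motif-free.  Loop ends inside a motif are
likewise pinned to non-pairable bases so a planted helix cannot be
extended by one chance pair into its own loop.  What the benchmark
demonstrates, therefore, is that the pipeline recovers every planted,
unambiguously-defined element with exact boundaries — not that real
genomes are this clean.  Real plant genomes bring repeat families,
nested insertions, truncated and degenerate copies, and assembly
artifacts that i.i.d. background deliberately does not emulate; census
numbers from draft assemblies also depend on assembly version and
manual curation, which is why published per-genome counts are treated
as indicative context rather than machine-checkable targets.

## Problem sizes and numerical choices

The test suite and the acceptance script use the reference 5-Mb
benchmark (two contigs), 200 planted motifs per topology for the
detection-rate property, 100 random sequences of up to 25 nt for the
fold oracle, and 50 seeded genomes for strand-symmetry — sizes chosen
so the whole suite completes in a few minutes on one CPU while leaving
each property with enough replicates to be meaningful.  Determinism is
absolute: the same seed yields byte-identical genomes, hit tables and
structures; co-optimal folds are resolved by a fixed traceback order
(5'-most base first, partners tried 3'-most first), and overlapping
scanner candidates by score, then leftmost position, then strand.

## Known limitations

* The bona-fide filter is a contiguous-complementarity heuristic; it
  does not model the geometry of natural loop–loop interactions.
* The scanner's census counts strand-collapsed unique loci; a motif
  mutated in the CTGA seed word is found only via the degenerate-copy
  search, as in the original motif-search-plus-homology strategy.
* Base-pair maximization is not a free-energy model; fraction-paired
  values are comparable between sequences folded the same way, not
  with published MFE structures, beyond the level documented above.
* The simulator does not model nested insertions, element truncation,
  or transposition dynamics; evaluation on it bounds pipeline
  correctness, not real-genome performance.
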