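---
title: "Validating circular RNAs in silico: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating circular RNAs in silico: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circvalid)
```

## The problem

A circular RNA (circRNA) differs from its linear parent transcript in a
single sequence feature: the back-splice junction (BSJ), the covalent joint
between the 3' end of a downstream ("donor") exon and the 5' start of an
upstream ("acceptor") exon. Everything else about the circle is shared with
the linear splice variants of the same locus, which is why claimed circRNAs
need a battery of converging in-silico and molecular checks before they can
be believed: divergent-primer PCR, clone sequencing with careful exon-path
reading, exclusion of genomic tandem repeats, BSJ-guided RNase H cleavage,
and RNase R resistance. `circvalid` implements the computational half of
each of those checks over an explicit locus model, and ships a synthetic
TRAM1-like fixture locus (11 exons, reverse strand, five linear variants,
four predicted circles) on which the whole chain can be exercised offline.

## The locus model

A `gene_locus` holds the genomic segment on the chromosome forward strand,
the gene strand, linear transcripts as ordered exon intervals, and circRNAs
as exon index ranges `[acceptor, donor]` on a parent transcript. Two
conventions are fixed throughout:

* Coordinates are 1-based inclusive. Exons are numbered in *transcript
  order*, so on the minus strand exon 1 carries the highest genomic
  coordinates. Circles are defined by exon indices, never by absolute
  coordinates, which keeps the model free of genome-assembly mismatches
  between annotation sources.
* The linearized circle sequence starts at the acceptor exon's first base
  and ends at the donor exon's last base; all occurrence counts on circles
  are taken on the doubled sequence. The BSJ `2k`-mer is the last `k` bases
  of the donor exon joined to the first `k` bases of the acceptor exon.

Degenerate inputs: zero-exon transcripts are rejected, single-exon circles
are allowed, and a circle whose annotated mature length disagrees with the
computed exon sum yields a warning rather than an error (annotation
disagreements are data, not bugs).

## In-silico PCR

Priming is abstracted by a seed model: a primer binds where its 3'-terminal
seed (default 10 nt) matches exactly and at most 2 mismatches fall 5' of
the seed. This is a deliberate simplification of polymerase extension
chemistry -- the 3' end governs whether Taq extends -- and it doubles as the
specificity criterion for primer design. Orientation of a pair is purely
geometric: convergent when a sense site lies 5' of an antisense site (the
amplifiable configuration), divergent when every configuration points
apart. Amplicons are enumerated per facing site pair up to a 3000 nt cap;
circular templates are scanned on the doubled sequence with monomer
products reported once.

Rolling-circle reverse transcription is modeled as a rotation of the
circle tiled `r` times. On such a concatemer the divergent pair yields the
characteristic ladder `L, L + c, L + 2c, ...` (`c` = circle length), which
is one of the two hypotheses for multi-band divergent PCR patterns; the
simulator can produce both that ladder and the several-distinct-circles
alternative, and asserts neither. Repeat counts in the library generator
follow a geometric distribution (`p = 0.5`) because no empirical
distribution is available.

## Primer and asON design

Design constraints default to the printed wet-lab window: Tm 57-63 degC
(optimum 60, pair difference at most 3), spliced products of 70-150 nt.
Melting temperatures use unified nearest-neighbor thermodynamics
(SantaLucia 1998; 50 mM Na+, 500 nM oligo, entropy salt correction
`0.368 (N-1) ln[Na+]`), which is deterministic and reproducible offline; it
replaces the interactive design service used at the bench, so absolute Tm
values differ slightly from values computed under other salt models, while
rankings are stable. Oligos with a hairpin (stem >= 4 bp closing a loop of
at most 3 nt) or a self-dimer (>= 8 bp) are discarded.

BSJ-spanning forward primers place at least `overhang_min = 4` 3'-terminal
bases inside the acceptor exon: too few 3' bases in the acceptor exon and
the primer extends on any template carrying the donor exon; a primer lying
entirely within the donor exon is rejected by the same screen. Candidates
are ranked by closeness to the Tm optimum, then by overhang, with a
lexicographic tie-break for reproducibility.

Antisense oligonucleotides (asONs) for RNase H work are reverse
complements of target windows. Linear targets must offer an unpaired
stretch of >= 10 nt in the user-supplied pairing map (secondary-structure
prediction itself is out of scope; the map is an input). For circular
targets only the BSJ is target-specific, so every candidate spans the
junction; candidates are ordered centre-out and screened so that no
12 nt sub-window (the assumed minimal RNase H heteroduplex) occurs in any
other transcript or circle of the locus. The default asON length is 20 nt,
configurable, as no published length was available to adopt.

## Clone classification

Reads are decomposed into maximal exact exon matches (15 nt seeds; point
substitutions are bridged when flanking matches are collinear, keeping the
effective segment identity at or above `min_identity = 0.95`), chained by
weighted interval scheduling to maximize matched bases, and junction-typed:
`canonical` (next exon at exact boundaries), `back_splice` (equal or lower
index at exact boundaries), `skip`, or `non_splice`. Because TA cloning is
non-directional, the orientation with more matched bases is chosen and
paths are reported with ascending canonical junctions; the mirror notation
of reverse-complement clones (e.g. `4,3/6,5,4` for `4,5,6/3,4`) is
recoverable via `path_string(..., "as_read")`.

Calls apply fixed-order rules -- foreign, primer duplication, missing
internal exon, inconsistent BSJ, circRNA-consistent, linear -- a precedence
that the original criteria list left open; the order puts cheaper, more
damning evidence first. The primer-duplication rule needs care: any
circularly wrapped read legitimately contains each primer twice, spaced by
the implied circle length, so only tandem-range repeats (spacing below
twice the primer length) are flagged as duplication artifacts.

## Flanking-intron complementarity

Inverse-complementary stretches in the introns flanking a circle's exon
block are scored by Smith-Waterman alignment of the upstream intron
against the reverse complement of the downstream one, with affine gaps and
Waterman-Eggert masking for non-intersecting top-k reporting. Scoring is
+5/-4 with gaps -12 to open and -4 per further base. A cheaper gap
extension (e.g. -2) puts local alignment of random DNA into the linear
regime, where alignments between unrelated kilobase introns grow without
bound and swamp genuine repeats; -4 keeps the statistic in the local
(logarithmic) regime. Percent identity is counted over all alignment
columns including gap columns (the uncounted-gaps alternative would only
raise the values).

Alignments are listed when they reach 50 nt and 55% identity *and* beat a
seeded permutation null (best score across 20 shuffles of the downstream
intron, about a 5% false-positive rate for the top hit); the floor alone
does not separate noise, because optimal local alignments of unrelated
introns routinely exceed 55% identity over more than 50 columns. A circle
lacking a flank (first or last exon involved) reports "no flanking pair".
No claim of biogenesis causality is attached to any of this.

## Nuclease models

RNase R digestion scales copies by topology-specific survival (defaults:
0.003 for linear RNA -- a bit more than two orders of magnitude of
degradation -- and 1.0 for circles) under optional multiplicative lognormal
noise. The lg10(B/A) copy ratio is rounded half away from zero to two
decimals and thresholded: at or below -1.0 is linear-consistent, at or
above -0.3 circular-consistent, otherwise indeterminate. The thresholds
are package defaults chosen so that ratios around -2.5 (observed for
linear transcripts) and ratios slightly above 0 (observed for circles;
positive values occur because no cross-sample normalization is possible
after digesting the linear standard away) classify as their topology
suggests; both are configurable. Simulated qPCR noise in the tests uses
`sdlog = 0.15`, the scatter implied by the duplicate copy columns of the
packaged table.

RNase H cleaves a member when it contains the perfect complement of at
least 12 consecutive asON bases. A cleaved circle becomes a linear
molecule opened at the cut site -- which is why a BSJ-guided asON
selectively abolishes the divergent-primer signal of its target circle
while leaving convergent signals (dominated by linear transcripts) intact.
Readout classes compare amplifiable copies after/before: below 0.1 is
lost, below 0.67 reduced, else unchanged.

## Marker arithmetic

The marker statistic is `lg10(fc) = log10(case/control)`, rounded half
away from zero to two decimals -- the convention that reproduces every
printed two-decimal ratio in the packaged urine, RNase R and cell-line
tables exactly. Pools (the transcripts co-amplified by one primer pair)
are summarized by unweighted arithmetic means per group before the ratio;
no transcript-length reweighting is applied. Only species with negative
lg10(fc) enter the pooled down-regulated candidate set; transcripts at
support level TSL 5 are annotated as low-confidence. Zero or negative
abundances are rejected rather than imputed. Cell-line values are treated
as already 18S-normalized inputs; `normalize_18s()` is provided for raw
copies.

## The synthetic-data generator

`make_locus()` emulates the study material: 11 exons (80-300 nt), introns
of 200-1200 nt, GC 0.5, minus strand, and four circles spanning exons 4-5,
3-6, 2-6 and 1-5 -- the architecture of the fixture. An inverted repeat of
chosen length and identity can be planted into the flanking-intron pair of
one circle. `make_clone_library()` mixes linear fragments (runs of one to
three consecutive exons), authentic circle amplicons (rolling-circle cDNA
followed by divergent amplicon prediction, shortest product kept), and
three artifact mechanisms taken from the cDNA-artifact literature:
template switching (two read halves joined), tandem primer duplication,
and internal exon skipping, at equal weights within a default 15% artifact
share. Expression tables draw per-sample abundances lognormally around
configured group means, seven samples per pooled group by default
(mirroring the pooled-urine design). Everything is bit-reproducible under
the config seed.

The fixture's sequences are synthetic (annotated genome sequence is out of
scope), so all sequence-level results on the fixture -- primer sequences,
alignment coordinates, planted-repeat identities -- are emulations; what
carries over from the real locus is the exon-count/length arithmetic
(spliced lengths 542/3394/3056/872/535, circle lengths 176/383/447/422),
the circle architectures, the flanking-intron indices, and every printed
abundance and ratio in the packaged tables. The exon memberships of the
4-5 and 1-5 circles are themselves inferences from their annotated
flanking introns, and are flagged as such in the fixture documentation.

What passing tests on this generator do *not* show: performance on real
Sanger chromatograms (no base-calling or vector trimming is modeled), on
loci with repetitive exons (seed matches would become ambiguous), or under
structured RNase R escape (G-quadruplex ends etc., not modeled).

## Problem sizes and numerical choices

The test suite runs the property checks at sizes a laptop handles in
minutes: 50 seeded loci for divergent-primer specificity, 100 reads of at
most 600 nt against an exhaustive fragment-placement oracle, 400-clone
composition recovery, textbook-DP alignment oracles on inputs of a few
hundred bases, and 1000 seeded RNase R draws. Alignment DP is exact
integer scoring (no floating point); ties in primer ranking are broken
lexicographically; rounding of reported ratios is half away from zero,
implemented without accumulating float error for the exact halves that
occur in printed tables.

## Known limitations

* The binding model ignores thermodynamic mismatch stability and primer
  concentration; presence/absence of a product is modeled, band intensity
  is not.
* Percent-identity conventions for local alignments differ between tools;
  published alignment lengths and identities obtained with other programs
  on real intron sequences are therefore qualitative anchors for the
  fixture, not bit-exact targets.
* Clone classification assumes insert-only reads from a known locus;
  foreign sequence is detected but not identified.
* The RNase models are endpoint models: no kinetics, no partial digestion
  gradients.
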