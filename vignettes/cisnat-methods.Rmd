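---
title: "Methods: antisense pair discovery, nat-siRNA quantification and the count-contrast test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antisense pair discovery, nat-siRNA quantification and the count-contrast test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisnat)
```

## The biological problem

Cis-natural antisense transcripts (cis-NATs) are pairs of genes transcribed
from opposite strands of the same locus whose transcripts overlap. The
double-stranded RNA formed in the overlap can be diced into small interfering
RNAs (nat-siRNAs), which in plants participate in stress responses — the
motivating case being heat stress in *Brassica* leaf vegetables, whose
mesohexaploid genome multiplies both cis-NAT loci and their cross-species
relationships with *Arabidopsis*. This package implements the full desk side
of such a study: pair discovery from a genome annotation, quantification of
small-RNA tags inside overlap regions, strand-bias and condition-response
calling, and conservation mapping through a homolog table. It deliberately
does **not** align reads or assemble transcripts; it consumes the coordinate
and count tables such tools produce.

## Coordinates and annotation handling

All internal coordinates are 0-based half-open, so `length = end - start`
and overlap arithmetic needs no `±1` bookkeeping; GFF3/GTF are converted at
the file boundary (1-based inclusive). Unstranded (`.`) records are rejected
— strand is the entire point of antisense analysis.

Many plant annotations are CDS-only. `extend_with_assembly()` links each CDS
model to same-strand assembled transcripts overlapping its span, selects the
longest candidate, and replaces the model's structure with it
(`provenance = "utr_extended"`). Two choices here were genuinely open:

* **Linkage and ties.** An assembled transcript overlapping two CDS models is
  assigned to the one with the larger overlap (ties to the smaller gene id);
  upstream assemblers leave this unspecified.
* **Containment guarantee.** The replacement span is the *union* of the CDS
  span and the assembled span, stretching terminal exons if needed. A raw
  replacement could shorten a model when the assembly starts inside the CDS,
  which would silently delete annotated coding sequence; extension is
  therefore monotone by construction (`extended span ⊇ CDS span`), which is
  also what "adding UTRs" means biologically.

`place_mirna()` classifies miRNA precursor loci against host transcripts as
intronic (fully inside one intron of a same-strand host), exon-overlapping
(≥ 1 nt on either strand) or intergenic, with intron ordinals counted in
transcription order — reverse coordinate order on the minus strand, matching
how biologists say "the 11th intron".

## Pair detection and orientation

`find_pairs()` reports every unordered opposite-strand pair whose span
overlap length L satisfies `min_overlap ≤ L ≤ max_overlap`, defaulting to
26–1999 nt: *more than 25 nt* read strictly, and *shorter than 2000 nt* read
as a cap on the overlap, since the clause modifies the overlap criterion.
Both bounds are plain parameters, so the alternative gene-length reading is
runnable by the caller. Overlap is computed on transcript spans (UTR-extended
where available), not exon unions, because the consumed gene models are
span-level. Interval queries go through `GenomicRanges::findOverlaps`; the
test suite checks the result against an independent all-pairs classifier on
random annotations.

Orientation is decided on the plus member `[a1, a2)` and minus member
`[b1, b2)`:

* **enclosed** — one span contains the other, tested first, boundary ties
  inclusive (equal starts or ends always mean containment on one side, so
  the three classes are exhaustive);
* **convergent** — `a1 < b1` and `a2 < b2` (3′ ends overlap);
* **divergent** — `b1 < a1` and `b2 < a2` (5′ ends overlap).

A useful sanity property: mirroring the axis while keeping strand labels
swaps convergent and divergent and fixes enclosed, whereas mirroring *and*
flipping strands is a rigid motion of the stranded genome and preserves all
three classes. Both are property-tested.

Pairs in which either member's span overlaps a miRNA precursor locus by at
least 1 nt (either strand) are excluded from the pair database and reported
separately — small RNAs there may derive from the hairpin, not the duplex.

## nat-siRNA quantification

Tags are unique small-RNA sequences with per-library raw counts and genomic
placements. At load time the 17–36 nt parsing window applies; a
(pair, tag, alignment) triple is then retained iff

1. the alignment is a perfect match (`mismatches == 0`);
2. tag length is 20–28 nt;
3. the alignment lies **fully inside** the pair's overlap interval; and
4. the tag reaches ≥ 5 RP10M (`count × 10⁷ / library total`) in at least one
   library.

Full containment (rather than mere touching) is required because only a tag
entirely within the duplex region is unambiguously antisense-paired; it is
exposed as a flag (`contained = FALSE`) for sensitivity analyses. The
abundance threshold is applied to the *normalized* count with `≥` — the
normalized reading keeps the filter comparable across libraries of unequal
depth. A tag mapping into several overlaps contributes its full count to
each; no fractional allocation is attempted, and the abundance threshold is
applied to the tag's library count, not per-locus sums.

`FR` and `RR` are the per-pair read totals on the genome forward and reverse
strands of the overlap. Length and first-nucleotide histograms are computed
both over unique tags and read-weighted.

## The count-contrast test

The statistical core is the Audic–Claverie conditional probability of
observing `y` reads in a library of `N2` total reads given `x` reads in a
library of `N1`:

$$p(y\,|\,x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!}\,
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}$$

which is the negative-binomial mass with size `x + 1` and success probability
`N1/(N1+N2)` — that identity is used as an independent cross-check in the
tests, never as the implementation. Evaluation is in log space (log-gamma),
so counts in the thousands are exact to near machine precision; the unit
tests compare against an exact rational-arithmetic oracle on a
51 × 51 × 3 grid at 10⁻¹² relative tolerance.

Tail construction, which the source methods leave unprinted, is a documented
decision: `lower = Σ_{k ≤ y} p(k|x)`, `upper = Σ_{k ≥ y} p(k|x)` (the
observed point mass counted in both, a conservative convention), and the
two-sided p doubles the smaller tail, capped at 1. The smaller tail is always
computed by direct summation and the larger via `1 − other + point`, so tiny
p-values never suffer cancellation. Under a Poisson null the two-sided test
at α = 0.01 is conservative (empirical type-I error ≈ 0.009 at 10⁵
contrasts), as discreteness predicts. p-values are never reported as exactly
zero: values below double range are floored at the smallest positive double.

**Strand bias.** A pair is strand-biased when FR/RR > 2 or < 0.5 (ratio
conventions: `Inf` when RR = 0 < FR, `0` when FR = 0 < RR, `NA` when both
are zero, serialized as the literal `INF`) *and* p < 0.01. Both strands come
from the same library, so equal library totals are used. One subtlety: the
conditional tail is not symmetric in (x, y) even at N1 = N2, while the FR/RR
labeling is arbitrary — so the call conditions on the **larger** strand
total, making it provably invariant under relabeling the strands.

**Condition response.** Per-pair totals in NT/HT (control/treatment)
replicates 1 and 2 are compared: ratios on RP10M-normalized totals (so
unequal depths do not masquerade as fold changes), the test on raw counts
with true library sizes, as the formula requires. A pair is called
responsive only when both replicate ratios clear the 2-fold threshold in the
same direction *and* both p-values are below 0.01 — a ratio of exactly 2
does not pass (the thresholds are strict). No multiple-testing correction is
applied anywhere: the procedure reproduced here uses raw p < 0.01
throughout, and that choice is preserved and documented rather than
silently "improved".

## Conservation mapping

A species-1 pair (g, h) is conserved iff some species-2 pair (g′, h′) has
g′ ∈ homologs(g) and h′ ∈ homologs(h), member order normalized. Many-to-many
homology is expected (triplicated genomes) and every qualifying combination
is emitted, with `copy_count` per species-2 pair. Gene-level homology alone
decides conservation; no overlap-region sequence similarity is required,
since the homolog table is an input, not an inference.

## The synthetic-data generator

`simulate_annotation()` plants pairs of each orientation class along two
synthetic chromosomes with enough spacing that no unplanned overlaps arise,
plus singleton genes and, optionally, pairs carrying a pre-miRNA locus
inside one member (which the pipeline must then exclude).
`simulate_srna_libraries()` draws tag species once per overlap strand —
lengths biased to 21 nt, first nucleotides biased to adenine, the
composition biases reported for real nat-siRNA populations — and then
per-library Poisson counts around per-strand means, split FR:RR by each
pair's planted bias ratio and scaled by the planted fold in HT libraries.
Counts use a named random substream per library derived from the one global
seed, so dropping a library never perturbs the others, and identical
configurations yield byte-identical output files.

Default study conditions: four libraries (NT1, HT1, NT2, HT2) of 10⁷ total
reads — at that depth the 5 RP10M filter equals 5 raw reads — with ~50
reads per overlap strand at baseline, an 8:1 planted strand-bias ratio, a
4-fold planted heat response, 20 effect-eligible pairs per run plus two
precursor-excluded ones, and overlap lengths of 60–400 nt. Noise is pure
Poisson by default because that is the sampling model the count-contrast
test assumes; a gamma-Poisson `overdispersion` parameter exists but is off
unless requested. Simulations in the test suite use 20 independent seeds of
this configuration (120 planted effects of each kind, 400 null tests).

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: sequencing error and adaptor artifacts, multi-mapping
ambiguity across repeat families, overdispersion beyond Poisson,
transcription units whose spans are mis-annotated, and any correlation
between neighboring loci. Recovery rates on synthetic data are upper bounds
for field performance.

## Numerical and formatting conventions

* Percentages in summary tables use round-half-up to two decimals (this, and
  not banker's rounding, reproduces the published percentage column from its
  integer counts).
* Pair identity is `"geneA|geneB"` with the lexicographically smaller id
  first, making set algebra across varieties order-independent.
* Degenerate inputs: both-zero contrasts give an undefined ratio and are
  never called biased; empty assignment sets yield empty (not NA)
  histograms; an annotation with a single gene yields an empty pair table.

## Known limitations

* Overlap is span-based; a pair whose overlap falls entirely within introns
  of both members is still reported (real duplex formation requires mature
  transcripts to overlap).
* Strand-bias pooling sums FR/RR over all supplied libraries; per-condition
  bias calling is possible by subsetting the library table.
* The conservation step trusts the homolog table; paralog misassignment
  propagates.

## A worked micro-example

```{r}
ann <- annotation_set(data.frame(
  transcript_id = c("t1", "t2"), gene_id = c("gHSP", "gANT"),
  chrom = "chr1", start = c(100, 400), end = c(500, 800),
  strand = c("+", "-")))
find_pairs(ann)
```

```{r}
# forward/reverse totals 300 vs 20: extreme ratio, tiny p, biased
call_strand_bias(FR = 300, RR = 20)
```
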