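# cisnat

Discovery of cis-natural antisense transcripts (cis-NATs) and analysis of
the small interfering RNAs they spawn.

## What this is for

A cis-NAT is a pair of genes transcribed from opposite strands of the same
locus whose transcripts overlap. The double-stranded RNA formed in the
overlap is processed into nat-siRNAs, which in plants mediate responses to
salt, pathogens and heat. This package is for transcriptomics researchers
who have a genome annotation (optionally UTR-extended with assembled
transcripts), small-RNA tag tables with genomic placements, and library
metadata, and who want the complete downstream analysis:

* **pair discovery** — every opposite-strand gene pair whose spans overlap
  by more than 25 nt and less than 2000 nt, classified as convergent
  (3′-end overlap), divergent (5′-end overlap) or enclosed (one transcript
  inside the other), with pairs overlapping miRNA precursor loci excluded;
* **nat-siRNA quantification** — tags retained when perfectly matched,
  20–28 nt, fully inside the overlap, and ≥ 5 RP10M
  (reads per 10 million, `count × 10⁷ / library total`) in at least one
  library;
* **strand bias and condition response** — calls built on the
  Audic–Claverie count-contrast test

  $$p(y\,|\,x) = \left(\tfrac{N_2}{N_1}\right)^{y}
  \tfrac{(x+y)!}{x!\,y!}
  \left(1+\tfrac{N_2}{N_1}\right)^{-(x+y+1)}$$

  where `x`, `y` are a tag population's read counts in two libraries of
  `N1`, `N2` total reads. Strand bias: FR/RR > 2 or < 0.5 with two-sided
  p < 0.01. Condition response: both replicate HT/NT ratios
  (RP10M-normalized) above 2 or below 0.5 in the same direction, both
  p < 0.01;
* **conservation mapping** — pairs whose two members have homologs that
  themselves form a pair in a second species' annotation, with multi-copy
  counting for polyploid-derived genomes;
* **a synthetic-data generator** — planted pairs, pre-miRNA loci and
  Poisson tag counts with a truth manifest, so the whole pipeline runs and
  is testable with no external downloads.

## A worked example

Simulate a small study (20 effect-eligible pairs, two of them carrying a
pre-miRNA locus; four libraries NT1/HT1/NT2/HT2 of 10⁷ reads) and run the
pipeline:

```r
library(cisnat)
cfg  <- simulation_config(seed = 11)
sim  <- simulate_annotation(cfg)
srna <- simulate_srna_libraries(sim, cfg)
res  <- run_pipeline(sim$genes, sim$premirnas, srna$tags, srna$alignments,
                     srna$libraries, verbose = TRUE)
#> [cisnat] find_pairs: 54 models -> 22 pairs
#> [cisnat] exclude_mirna_overlaps: 2 pair(s) dropped, 20 retained
#> [cisnat] assign_tags: 165 tags, 165 alignments -> 123 assignments in 20 pair(s)
#> [cisnat] strand bias: 6 of 20 producing pair(s)
#> [cisnat] heat response: 6 significant pair(s)
```

54 gene models yield 22 antisense pairs; 2 are dropped for overlapping a
planted miRNA precursor. Of 165 tags, 123 (pair, tag, alignment) triples
survive the nat-siRNA filters. The calls recover exactly the planted
effects:

```r
head(res$strand_bias[res$strand_bias$biased, ], 2)
#>             pair_id  FR  RR       ratio      p_value biased
#> 1 SYNG0001|SYNG0002   6 244  0.02459016 1.852437e-64   TRUE
#> 2 SYNG0003|SYNG0004 355  10 35.50000000 1.437264e-91   TRUE
```

`FR`/`RR` are read totals on the overlap's forward/reverse genome strands;
pair `SYNG0003|SYNG0004` produces 35.5-fold more forward-strand reads than
reverse — a strand-biased nat-siRNA source.

```r
head(res$heat_response[res$heat_response$significant, ], 2)
#>             pair_id ratio_rep1       p_rep1 ratio_rep2       p_rep2 direction significant
#> 1 SYNG0001|SYNG0002  0.2110092 8.363230e-15  0.2040816 9.202544e-14      down        TRUE
#> 3 SYNG0005|SYNG0006  4.9456522 1.021238e-58  4.5909091 2.116063e-49        up        TRUE
```

The first pair's nat-siRNAs drop to ~21% of control abundance in both heat
replicates; the second rises ~4.6–4.9-fold — replicate-concordant heat
responses.

The individual stages are plain functions (`find_pairs`,
`exclude_mirna_overlaps`, `assign_tags`, `call_strand_bias`,
`call_heat_response`, `find_conserved_pairs`, `build_summary`), and a thin
command-line front end exposes each stage as a subcommand:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cisnat.R", package = "cisnat"))')" \
  simulate --seed 11 --out-dir demo/
```

## Scope

Read alignment, transcript assembly, BLAST homology and wet-lab validation
are out of scope: the package consumes the coordinate and count tables
those tools produce. See `vignettes/cisnat-methods.Rmd` for the model,
parameter and design discussion.
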