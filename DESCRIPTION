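Package: cisnat
Title: Discovery of Cis-Natural Antisense Transcripts and Their Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cis-natural antisense transcript (cis-NAT) gene pairs from
    genome annotations, classifies their overlap orientation (convergent,
    divergent, enclosed), quantifies small-RNA tags falling in the overlap
    regions under standard nat-siRNA filters (perfect match, 20-28 nt, RP10M
    abundance threshold), calls strand bias and condition-responsive
    differential accumulation with the Audic-Claverie count-contrast test,
    and maps pair conservation between two species via a homolog table.
    Includes a fully self-contained synthetic-data generator with a truth
    manifest so every pipeline stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
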