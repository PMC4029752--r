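# In-code fixture builders shared across test files.

# Compact annotation builder: genes as list(id = c(start, end, "strand")).
make_ann <- function(genes, chrom = "chr1", biotype = "coding") {
  ids <- names(genes)
  df <- data.frame(
    transcript_id = paste0(ids, ".1"), gene_id = ids, chrom = chrom,
    start = vapply(genes, function(g) as.numeric(g[1]), 0),
    end = vapply(genes, function(g) as.numeric(g[2]), 0),
    strand = vapply(genes, function(g) g[3], ""),
    biotype = biotype, stringsAsFactors = FALSE)
  annotation_set(df)
}

# Random single-exon annotation for geometry oracles.
rand_ann <- function(n_genes, genome_len = 20000, n_chrom = 2) {
  start <- sample.int(genome_len, n_genes, replace = TRUE)
  len <- sample(50:3000, n_genes, replace = TRUE)
  annotation_set(data.frame(
    transcript_id = sprintf("t%03d", seq_len(n_genes)),
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = paste0("chr", sample.int(n_chrom, n_genes, replace = TRUE)),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Minimal single-pair quantification fixture: one convergent pair with
# overlap [400, 500) on chr1 and a library table.
one_pair_fixture <- function(total_reads = 1e7) {
  ann <- make_ann(list(gA = c(100, 500, "+"), gB = c(400, 800, "-")))
  pairs <- find_pairs(ann)
  libs <- srna_libraries(c("L1", "L2"), c("NT", "HT"), c(1L, 1L),
                         rep(total_reads, 2))
  list(ann = ann, pairs = pairs, libs = libs)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                collapse = "")
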