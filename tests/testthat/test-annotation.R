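test_that("GFF3 1-based inclusive coordinates convert to 0-based half-open", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1"), f)
  ann <- read_annotation(f, "gff3")
  tr <- ann$transcripts
  expect_equal(tr$start, 100)
  expect_equal(tr$end, 200)
  expect_equal(tr$end - tr$start, 100)
})

test_that("exon lines sharing a transcript id group into one model", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
               "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"), f)
  ann <- read_annotation(f, "gff3")
  expect_equal(nrow(ann$transcripts), 1)
  expect_equal(nrow(ann$exons), 2)
  expect_equal(ann$transcripts$start, 100)
  expect_equal(ann$transcripts$end, 400)
})

test_that("unstranded and malformed records are rejected with line numbers", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t101\t200\t.\t.\t.\tID=t1"), f)
  expect_error(read_annotation(f, "gff3"), "line 2.*unstranded|unstranded.*line 2")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t300\t200\t.\t+\t.\tID=t1"), f)
  expect_error(read_annotation(f, "gff3"), "line 2")
  expect_error(read_annotation(f, "gff3"), "end < start")

  writeLines(c("##gff-version 3", "chr1\tonly-three-fields\t1"), f)
  expect_error(read_annotation(f, "gff3"), "line 2")
})

test_that("GTF exon grouping by transcript_id works", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr2\tsrc\texon\t51\t150\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'), f)
  ann <- read_annotation(f, "gtf")
  expect_equal(nrow(ann$transcripts), 2)
  expect_equal(ann$transcripts$gene_id[ann$transcripts$transcript_id == "t1"], "g1")
  expect_equal(sum(ann$exons$transcript_id == "t1"), 2)
})

test_that("GFF3 write/read round-trip preserves spans, strands, exon counts and biotype", {
  tr <- data.frame(
    transcript_id = c("t1", "t2", "m1"), gene_id = c("g1", "g2", "mir1"),
    chrom = c("chr1", "chr1", "chr2"), start = c(100, 900, 40),
    end = c(600, 1500, 160), strand = c("+", "-", "+"),
    biotype = c("coding", "coding", "pre_miRNA"),
    provenance = c("utr_extended", "cds_only", "cds_only"),
    stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = c("t1", "t1", "t2", "m1"),
                   start = c(100, 400, 900, 40), end = c(250, 600, 1500, 160))
  ann <- annotation_set(tr, ex)
  f <- tempfile(fileext = ".gff3")
  write_annotation(ann, f, "gff3")
  back <- read_annotation(f, "gff3")
  o <- order(back$transcripts$gene_id)
  cols <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
            "biotype", "provenance")
  expect_equal(back$transcripts[o, cols],
               ann$transcripts[order(ann$transcripts$gene_id), cols],
               ignore_attr = TRUE)
  expect_equal(table(back$exons$transcript_id), table(ann$exons$transcript_id))
})

test_that("BED6 round-trip preserves spans and strands", {
  ann <- make_ann(list(gX = c(10, 500, "+"), gY = c(1000, 1800, "-")))
  f <- tempfile(fileext = ".bed")
  write_annotation(ann, f, "bed")
  back <- read_annotation(f, "bed")
  o <- order(back$transcripts$gene_id)
  expect_equal(back$transcripts$start[o], ann$transcripts$start)
  expect_equal(back$transcripts$end[o], ann$transcripts$end)
  expect_equal(back$transcripts$strand[o], ann$transcripts$strand)
})

test_that("extend_with_assembly selects the longest same-strand overlapping transcript", {
  cds <- make_ann(list(gA = c(100, 400, "+")))
  asm <- make_ann(list(a1 = c(80, 450, "+"), a2 = c(90, 420, "+")))
  ext <- extend_with_assembly(cds, asm)
  expect_equal(ext$transcripts$start, 80)
  expect_equal(ext$transcripts$end, 450)
  expect_equal(ext$transcripts$provenance, "utr_extended")

  # strand mismatch: unchanged
  asm_minus <- make_ann(list(a1 = c(80, 450, "-")))
  ext2 <- extend_with_assembly(cds, asm_minus)
  expect_equal(ext2$transcripts$start, 100)
  expect_equal(ext2$transcripts$provenance, "cds_only")

  # no overlap at all: unchanged
  asm_far <- make_ann(list(a1 = c(5000, 6000, "+")))
  ext3 <- extend_with_assembly(cds, asm_far)
  expect_equal(ext3$transcripts$end, 400)
  expect_equal(ext3$transcripts$provenance, "cds_only")
})

test_that("an assembled transcript spanning two models goes to the larger overlap", {
  cds <- make_ann(list(gA = c(100, 400, "+"), gB = c(600, 1000, "+")))
  # overlaps gA by 100, gB by 300
  asm <- make_ann(list(a1 = c(300, 900, "+")))
  ext <- extend_with_assembly(cds, asm)
  tr <- ext$transcripts
  expect_equal(tr$provenance[tr$gene_id == "gA"], "cds_only")
  expect_equal(tr$provenance[tr$gene_id == "gB"], "utr_extended")
  expect_equal(tr$start[tr$gene_id == "gB"], 300)
})

test_that("extension never shortens: extended span contains the CDS span", {
  set.seed(71)
  for (rep in 1:10) {
    cds <- rand_ann(15)
    asm <- rand_ann(25)
    asm$transcripts$gene_id <- paste0("asm_", asm$transcripts$gene_id)
    asm$transcripts$transcript_id <- paste0("asm_", asm$transcripts$transcript_id)
    asm$exons$transcript_id <- paste0("asm_", asm$exons$transcript_id)
    ext <- suppressWarnings(extend_with_assembly(cds, asm))
    m <- match(cds$transcripts$gene_id, ext$transcripts$gene_id)
    expect_true(all(ext$transcripts$start[m] <= cds$transcripts$start))
    expect_true(all(ext$transcripts$end[m] >= cds$transcripts$end))
  }
})

host_with_exons <- function(strand, exons) {
  tr <- data.frame(transcript_id = "h1.1", gene_id = "h1", chrom = "chr1",
                   start = 0, end = 1, strand = strand,
                   stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = "h1.1",
                   start = vapply(exons, `[`, 0, 1),
                   end = vapply(exons, `[`, 0, 2))
  annotation_set(tr, ex)
}

mirna_at <- function(start, end, strand = "+", chrom = "chr1") {
  annotation_set(data.frame(transcript_id = "mir1.1", gene_id = "mir1",
                            chrom = chrom, start = start, end = end,
                            strand = strand, biotype = "pre_miRNA",
                            stringsAsFactors = FALSE))
}

test_that("pre-miRNA in the sole intron of a plus-strand host is intronic, ordinal 1", {
  hosts <- host_with_exons("+", list(c(100, 400), c(700, 900)))
  p <- place_mirna(mirna_at(500, 580), hosts)
  expect_equal(p$placement, "intronic")
  expect_equal(p$host_gene_id, "h1")
  expect_equal(p$intron_ordinal, 1L)
})

test_that("intron ordinals follow transcription order on the minus strand", {
  hosts <- host_with_exons("-", list(c(100, 200), c(300, 400), c(500, 600)))
  # coordinate-order intron 2 = [400, 500) is the FIRST intron transcribed
  p <- place_mirna(mirna_at(420, 480, strand = "-"), hosts)
  expect_equal(p$placement, "intronic")
  expect_equal(p$intron_ordinal, 1L)
  # coordinate-order intron 1 = [200, 300) is the second
  p2 <- place_mirna(mirna_at(220, 280, strand = "-"), hosts)
  expect_equal(p2$intron_ordinal, 2L)
})

test_that("1-nt exon overlap classifies as exon_overlapping; empty region intergenic", {
  hosts <- host_with_exons("+", list(c(100, 400), c(700, 900)))
  p <- place_mirna(mirna_at(399, 480), hosts)  # overlaps exon 1 by 1 nt
  expect_equal(p$placement, "exon_overlapping")
  p2 <- place_mirna(mirna_at(5000, 5100), hosts)
  expect_equal(p2$placement, "intergenic")
  expect_true(is.na(p2$intron_ordinal))
})

test_that("placement classes are mutually exclusive and exhaustive", {
  set.seed(99)
  hosts <- rand_ann(30)
  for (i in 1:40) {
    s <- sample.int(15000, 1)
    p <- place_mirna(mirna_at(s, s + 110, strand = sample(c("+", "-"), 1),
                              chrom = sample(c("chr1", "chr2"), 1)), hosts)
    expect_true(p$placement %in% c("intronic", "exon_overlapping", "intergenic"))
    expect_identical(!is.na(p$intron_ordinal), p$placement == "intronic")
  }
})
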