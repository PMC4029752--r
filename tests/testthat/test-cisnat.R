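test_that("an antisense overlap of 100 nt yields one convergent pair", {
  ann <- make_ann(list(gA = c(100, 500, "+"), gB = c(400, 800, "-")))
  p <- find_pairs(ann)
  expect_equal(nrow(p), 1)
  expect_equal(p$gene_a, "gA")
  expect_equal(p$gene_b, "gB")
  expect_equal(p$overlap_start, 400)
  expect_equal(p$overlap_end, 500)
  expect_equal(p$overlap_len, 100)
  expect_equal(p$orientation, "convergent")
})

test_that("the overlap filter is strict: 25 nt fails, 26 nt passes", {
  ann25 <- make_ann(list(gA = c(100, 500, "+"), gB = c(475, 800, "-")))
  expect_equal(nrow(find_pairs(ann25)), 0)
  ann26 <- make_ann(list(gA = c(100, 500, "+"), gB = c(474, 800, "-")))
  expect_equal(nrow(find_pairs(ann26)), 1)
})

test_that("overlaps of 2000 nt or more are rejected by the length cap", {
  ann <- make_ann(list(gA = c(0, 3000, "+"), gB = c(500, 2800, "-")))
  expect_equal(nrow(find_pairs(ann)), 0)          # overlap 2300
  expect_equal(nrow(find_pairs(ann, max_overlap = 5000)), 1)  # cap is a parameter
})

test_that("same-strand overlaps never form pairs", {
  ann <- make_ann(list(gA = c(100, 500, "+"), gB = c(400, 800, "+")))
  expect_equal(nrow(find_pairs(ann)), 0)
})

test_that("orientation classification covers the three canonical geometries", {
  expect_equal(classify_orientation(100, 500, 400, 800), "convergent")
  expect_equal(classify_orientation(400, 800, 100, 500), "divergent")
  expect_equal(classify_orientation(100, 900, 300, 500), "enclosed")
  expect_equal(classify_orientation(300, 500, 100, 900), "enclosed")
  # boundary ties resolve to enclosed
  expect_equal(classify_orientation(100, 500, 100, 400), "enclosed")
  expect_equal(classify_orientation(100, 500, 200, 500), "enclosed")
  expect_equal(classify_orientation(100, 500, 100, 500), "enclosed")
  expect_error(classify_orientation(100, 200, 300, 400), "overlap")
})

test_that("coordinate reflection swaps convergent and divergent, fixes enclosed", {
  set.seed(11)
  M <- 100000
  for (i in 1:200) {
    a <- sort(sample.int(M - 1, 2)); b <- sort(sample.int(M - 1, 2))
    if (min(a[2], b[2]) <= max(a[1], b[1])) next
    ori <- classify_orientation(a[1], a[2], b[1], b[2])
    # mirror the axis, keeping strand labels: [s,e) -> [M-e, M-s); every
    # transcript's 5' and 3' ends trade places, so head-to-head geometries
    # become tail-to-tail and vice versa
    refl <- classify_orientation(M - a[2], M - a[1], M - b[2], M - b[1])
    expected <- c(convergent = "divergent", divergent = "convergent",
                  enclosed = "enclosed")[[ori]]
    expect_equal(refl, expected)
    # mirroring AND flipping the strand labels is a rigid motion of the
    # stranded genome: classes are invariant
    same <- classify_orientation(M - b[2], M - b[1], M - a[2], M - a[1])
    expect_equal(same, ori)
  }
})

test_that("find_pairs + classify agree with the all-pairs oracle on random annotations", {
  set.seed(202)
  for (i in 1:20) {
    ann <- rand_ann(60)
    min_ov <- sample(c(1, 10, 26, 40), 1)
    max_ov <- sample(c(200, 800, 1999), 1)
    got <- find_pairs(ann, min_ov, max_ov)
    got <- got[order(got$pair_id), c("pair_id", "orientation")]
    want <- brute_force_pairs(ann, min_ov, max_ov)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("pairs overlapping a pre-miRNA locus by 1 nt are excluded and reported", {
  ann <- make_ann(list(gA = c(100, 500, "+"), gB = c(400, 800, "-"),
                       gC = c(2000, 2500, "+"), gD = c(2300, 2900, "-")))
  pairs <- find_pairs(ann)
  expect_equal(nrow(pairs), 2)
  mir <- annotation_set(data.frame(
    transcript_id = "m1", gene_id = "mir1", chrom = "chr1",
    start = 40, end = 101, strand = "-", biotype = "pre_miRNA"))  # 1 nt into gA
  res <- exclude_mirna_overlaps(pairs, mir, ann)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$gene_a, "gC")
  expect_equal(nrow(res$excluded), 1)
  expect_equal(res$excluded$gene, "gA")
  expect_equal(res$excluded$mirna_id, "mir1")
  # no pre-miRNA set: identity
  res2 <- exclude_mirna_overlaps(pairs, NULL, ann)
  expect_identical(res2$pairs, pairs)
})

test_that("the excluded report lists every precursor-overlapping pair", {
  genes <- list()
  for (i in 1:10) {
    genes[[sprintf("gP%02d", i)]] <- c(i * 10000, i * 10000 + 500, "+")
    genes[[sprintf("gM%02d", i)]] <- c(i * 10000 + 400, i * 10000 + 900, "-")
  }
  ann <- make_ann(genes)
  pairs <- find_pairs(ann)
  expect_equal(nrow(pairs), 10)
  mirs <- annotation_set(data.frame(
    transcript_id = sprintf("m%d", 1:8), gene_id = sprintf("mir%d", 1:8),
    chrom = "chr1", start = (1:8) * 10000 + 100, end = (1:8) * 10000 + 220,
    strand = "+", biotype = "pre_miRNA"))
  res <- exclude_mirna_overlaps(pairs, mirs, ann)
  expect_equal(nrow(res$excluded), 8)
  expect_equal(nrow(res$pairs), 2)
})

fake_pairs <- function(ids, orientation = "convergent") {
  ga <- paste0(ids, "_a"); gb <- paste0(ids, "_b")
  data.frame(pair_id = pair_id(ga, gb), gene_a = ga, gene_b = gb,
             chrom = "chr1", overlap_start = 0, overlap_end = 100,
             overlap_len = 100, orientation = orientation,
             stringsAsFactors = FALSE)
}

test_that("pair_set_union flags shared membership and obeys inclusion-exclusion", {
  s1 <- fake_pairs(c("P", "Q"))
  s2 <- fake_pairs(c("Q", "R"))
  u <- pair_set_union(list(one = s1, two = s2))
  expect_equal(nrow(u), 3)
  shared <- u$pair_id[u$in_one & u$in_two]
  expect_equal(shared, pair_id("Q_a", "Q_b"))
  expect_equal(nrow(u), nrow(s1) + nrow(s2) - length(shared))

  # empty second set: union equals first
  u2 <- pair_set_union(list(one = s1, two = s1[0, ]))
  expect_equal(sort(u2$pair_id), sort(s1$pair_id))
  expect_true(all(!u2$in_two))
})

test_that("union of 721 and 648 pairs sharing 338 gives 1031", {
  shared <- fake_pairs(sprintf("S%03d", 1:338))
  bre <- rbind(shared, fake_pairs(sprintf("B%03d", 1:383)))
  wut <- rbind(shared, fake_pairs(sprintf("W%03d", 1:310)))
  expect_equal(nrow(bre), 721)
  expect_equal(nrow(wut), 648)
  u <- pair_set_union(list(Bre = bre, Wut = wut))
  expect_equal(nrow(u), 1031)
  expect_equal(sum(u$in_Bre & u$in_Wut), 338)
})

test_that("conflicting orientations for one pair id across sets raise an error", {
  s1 <- fake_pairs("P", "convergent")
  s2 <- fake_pairs("P", "divergent")
  expect_error(pair_set_union(list(a = s1, b = s2)), "conflicting orientation")
})
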