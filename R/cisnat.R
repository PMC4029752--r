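# Antisense overlapping gene-pair detection and classification.

#' Canonical pair identity string
#'
#' Pair identity is the two gene ids joined by `|`, lexicographically smaller
#' id first, so set operations across varieties are order-independent.
#'
#' @param gene_a,gene_b gene id character vectors.
#' @return character vector of pair ids.
#' @export
pair_id <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "|")
}

#' Classify the overlap orientation of an antisense gene pair
#'
#' Given the spans of the plus-strand member (`[a1, a2)`) and minus-strand
#' member (`[b1, b2)`) of an overlapping opposite-strand pair, returns:
#' `enclosed` when one span contains the other (containment is tested first
#' and boundary ties resolve to enclosed), `convergent` when the 3' ends
#' overlap (`a1 < b1` and `a2 < b2`), `divergent` when the 5' ends overlap
#' (`b1 < a1` and `b2 < a2`). The three classes are mutually exclusive and
#' exhaustive over all overlapping geometries.
#'
#' @param a_start,a_end span of the `+` strand member (0-based half-open).
#' @param b_start,b_end span of the `-` strand member.
#' @return character vector in `{"convergent","divergent","enclosed"}`.
#' @export
classify_orientation <- function(a_start, a_end, b_start, b_end) {
  if (any(pmin(a_end, b_end) <= pmax(a_start, b_start)))
    stop("classify_orientation requires overlapping spans")
  out <- rep(NA_character_, length(a_start))
  enc <- (a_start <= b_start & a_end >= b_end) | (b_start <= a_start & b_end >= a_end)
  conv <- !enc & a_start < b_start & a_end < b_end
  div <- !enc & b_start < a_start & b_end < a_end
  out[enc] <- "enclosed"
  out[conv] <- "convergent"
  out[div] <- "divergent"
  stopifnot(!anyNA(out))
  out
}

#' Find cis-natural antisense transcript pairs
#'
#' Scans an annotation for every unordered pair of opposite-strand models
#' whose span overlap length L satisfies `min_overlap <= L <= max_overlap`.
#' The defaults encode an overlap of more than 25 nt and shorter than
#' 2000 nt. Overlap is computed on transcript spans (UTR-extended where
#' available). Pre-miRNA models in the set are ignored; they enter the
#' pipeline through [exclude_mirna_overlaps].
#'
#' @param annotations an [annotation_set].
#' @param min_overlap minimum overlap length in nt (default 26).
#' @param max_overlap maximum overlap length in nt (default 1999).
#' @return data.frame with one row per qualifying pair: `pair_id`, `gene_a`
#'   (the `+` strand member), `gene_b` (the `-` strand member), `chrom`,
#'   `overlap_start`, `overlap_end`, `overlap_len`, `orientation`.
#' @examples
#' ann <- annotation_set(data.frame(
#'   transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"), chrom = "chr1",
#'   start = c(100, 400), end = c(500, 800), strand = c("+", "-")))
#' find_pairs(ann)
#' @export
find_pairs <- function(annotations, min_overlap = 26, max_overlap = 1999) {
  stopifnot(min_overlap >= 1, max_overlap >= min_overlap)
  tr <- annotations$transcripts[annotations$transcripts$biotype == "coding", ,
                                drop = FALSE]
  empty <- data.frame(pair_id = character(), gene_a = character(),
                      gene_b = character(), chrom = character(),
                      overlap_start = numeric(), overlap_end = numeric(),
                      overlap_len = numeric(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tr) < 2) return(empty)
  gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start + 1L, tr$end),
                               strand = tr$strand)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE,
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  opp <- tr$strand[qi] != tr$strand[si]
  qi <- qi[opp]; si <- si[opp]
  if (length(qi) == 0) return(empty)
  # orient: a = + strand member, b = - strand member
  plus_first <- tr$strand[qi] == "+"
  ai <- ifelse(plus_first, qi, si)
  bi <- ifelse(plus_first, si, qi)
  ov_s <- pmax(tr$start[ai], tr$start[bi])
  ov_e <- pmin(tr$end[ai], tr$end[bi])
  len <- ov_e - ov_s
  keep <- len >= min_overlap & len <= max_overlap
  ai <- ai[keep]; bi <- bi[keep]; ov_s <- ov_s[keep]; ov_e <- ov_e[keep]
  len <- len[keep]
  if (length(ai) == 0) return(empty)
  out <- data.frame(
    pair_id = pair_id(tr$gene_id[ai], tr$gene_id[bi]),
    gene_a = tr$gene_id[ai], gene_b = tr$gene_id[bi],
    chrom = tr$chrom[ai],
    overlap_start = ov_s, overlap_end = ov_e, overlap_len = len,
    orientation = classify_orientation(tr$start[ai], tr$end[ai],
                                       tr$start[bi], tr$end[bi]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$overlap_start, out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude pairs overlapping miRNA precursor loci
#'
#' Small RNAs over a miRNA precursor may derive from the hairpin rather than
#' the antisense duplex, so any pair in which either member's span overlaps a
#' pre-miRNA locus by at least 1 nt (on either strand) is removed from the
#' pair list and reported separately.
#'
#' @param pairs data.frame from [find_pairs].
#' @param premirnas [annotation_set] of pre-miRNA loci, or `NULL` (no
#'   exclusion).
#' @param annotations the [annotation_set] the pairs were called from (used
#'   to recover member spans).
#' @return list with elements `pairs` (retained pairs) and `excluded`
#'   (data.frame `pair_id`, `gene`, `mirna_id` of dropped pairs).
#' @export
exclude_mirna_overlaps <- function(pairs, premirnas, annotations) {
  excluded <- data.frame(pair_id = character(), gene = character(),
                         mirna_id = character(), stringsAsFactors = FALSE)
  if (is.null(premirnas) || length(premirnas) == 0 || nrow(pairs) == 0)
    return(list(pairs = pairs, excluded = excluded))
  tr <- annotations$transcripts
  members <- data.frame(pair_id = rep(pairs$pair_id, 2),
                        gene = c(pairs$gene_a, pairs$gene_b),
                        stringsAsFactors = FALSE)
  m <- match(members$gene, tr$gene_id)
  if (anyNA(m)) stop("pair member(s) absent from annotation: ",
                     paste(unique(members$gene[is.na(m)]), collapse = ", "))
  gr_mem <- GenomicRanges::GRanges(tr$chrom[m],
                                   IRanges::IRanges(tr$start[m] + 1L, tr$end[m]))
  gr_mir <- span_granges(premirnas)
  hits <- GenomicRanges::findOverlaps(gr_mem, gr_mir, ignore.strand = TRUE)
  if (length(hits)) {
    excluded <- data.frame(
      pair_id = members$pair_id[S4Vectors::queryHits(hits)],
      gene = members$gene[S4Vectors::queryHits(hits)],
      mirna_id = S4Vectors::mcols(gr_mir)$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
    excluded <- excluded[!duplicated(excluded), , drop = FALSE]
    rownames(excluded) <- NULL
  }
  keep <- !pairs$pair_id %in% excluded$pair_id
  list(pairs = pairs[keep, , drop = FALSE], excluded = excluded)
}

#' Union of pair sets across varieties
#'
#' Combines named pair sets called against the same reference annotation into
#' a single table of unique pairs, flagging per-set membership. Pair identity
#' is the unordered gene-id pair ([pair_id]). Conflicting orientations for
#' the same pair across sets are an error (the same reference implies the
#' same geometry).
#'
#' @param sets named list of pair data.frames (as from [find_pairs]).
#' @return data.frame of unique pairs with one logical `in_<name>` column per
#'   input set.
#' @export
pair_set_union <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)),
            all(nzchar(names(sets))))
  all_pairs <- do.call(rbind, lapply(sets, function(p)
    p[, intersect(c("pair_id", "gene_a", "gene_b", "chrom", "overlap_start",
                    "overlap_end", "overlap_len", "orientation"), names(p)),
      drop = FALSE]))
  if ("orientation" %in% names(all_pairs)) {
    ok <- tapply(all_pairs$orientation, all_pairs$pair_id,
                 function(o) length(unique(o)) == 1)
    if (!all(ok))
      stop("conflicting orientations across sets for pair(s): ",
           paste(names(ok)[!ok], collapse = ", "))
  }
  uni <- all_pairs[!duplicated(all_pairs$pair_id), , drop = FALSE]
  for (nm in names(sets))
    uni[[paste0("in_", nm)]] <- uni$pair_id %in% sets[[nm]]$pair_id
  uni <- uni[order(uni$pair_id), , drop = FALSE]
  rownames(uni) <- NULL
  uni
}

#' Write pairs as a tab-delimited table or BED6 of overlap regions
#'
#' @param pairs a pair data.frame.
#' @param path output path.
#' @param format `"tsv"` (full table) or `"bed"` (overlap regions, name =
#'   pair id, strand `.` is not emitted - the region is strandless, so `+`
#'   placeholder per BED convention is avoided by writing BED4+score).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0",
                     pairs$chrom, as.integer(pairs$overlap_start),
                     as.integer(pairs$overlap_end), pairs$pair_id)
    writeLines(lines, path)
  }
  invisible(path)
}
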