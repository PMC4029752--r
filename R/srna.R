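# Small-RNA tag loading, nat-siRNA assignment and normalization.

#' Describe a set of small-RNA libraries
#'
#' @param name library names (unique).
#' @param condition condition labels (e.g. `"NT"`, `"HT"`, `"control"`).
#' @param replicate replicate indices.
#' @param total_reads total mapped read counts, the RP10M denominators;
#'   must be positive.
#' @return data.frame with one row per library.
#' @export
srna_libraries <- function(name, condition, replicate, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (anyDuplicated(name)) stop("library names must be unique")
  data.frame(name = as.character(name), condition = as.character(condition),
             replicate = as.integer(replicate),
             total_reads = as.numeric(total_reads), stringsAsFactors = FALSE)
}

#' Reads-per-ten-million normalization
#'
#' `rp10m(count, total) = count * 1e7 / total`, the abundance unit used for
#' the nat-siRNA expression filter. Linear in `count` for a fixed `total`.
#'
#' @param count raw read count(s).
#' @param total library total mapped reads (> 0).
#' @return normalized abundance(s).
#' @examples
#' rp10m(7, 14e6)  # 5
#' @export
rp10m <- function(count, total) {
  if (any(total <= 0)) stop("library total must be > 0")
  count * 1e7 / total
}

#' Read a small-RNA tag table
#'
#' A tag table is a TSV with a `sequence` column followed by one raw-count
#' column per library. Tags outside the 17-36 nt parsing window are dropped
#' with a message (they are not small-RNA candidates).
#'
#' @param path TSV path.
#' @return data.frame: `sequence`, `length`, `first_nt`, then the library
#'   count columns.
#' @export
read_tag_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sequence" %in% names(df)) stop("tag table requires a 'sequence' column")
  tag_table(df$sequence, df[, setdiff(names(df), "sequence"), drop = FALSE])
}

#' Assemble a tag table from sequences and counts
#'
#' @param sequence nucleotide strings over `A,C,G,T/U`.
#' @param counts data.frame of raw counts, one column per library.
#' @return tag data.frame as in [read_tag_table].
#' @export
tag_table <- function(sequence, counts) {
  sequence <- toupper(as.character(sequence))
  sequence <- chartr("U", "T", sequence)
  len <- nchar(sequence)
  keep <- len >= 17 & len <= 36
  if (!all(keep))
    message(sum(!keep), " tag(s) outside the 17-36 nt window dropped")
  df <- data.frame(sequence = sequence[keep], length = len[keep],
                   first_nt = substr(sequence[keep], 1, 1),
                   stringsAsFactors = FALSE)
  cbind(df, counts[keep, , drop = FALSE])
}

#' Read per-tag genomic alignments
#'
#' TSV columns: `sequence`, `chrom`, `start` (0-based), `strand`,
#' `mismatches`. SAM/BAM input (coordinate-sorted) is converted via
#' Rsamtools; the `NM` tag supplies mismatch counts (0 when absent).
#'
#' @param path input path.
#' @param format `"tsv"`, `"sam"` or `"bam"`.
#' @return data.frame: `sequence`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches` (end = start + tag length).
#' @export
read_alignments <- function(path, format = c("tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("sequence", "chrom", "start", "strand", "mismatches")
    if (!all(req %in% names(df)))
      stop("alignment TSV requires columns: ", paste(req, collapse = ", "))
    df$sequence <- chartr("U", "T", toupper(df$sequence))
    df$end <- df$start + nchar(df$sequence)
    return(df[, c("sequence", "chrom", "start", "end", "strand", "mismatches")])
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM/BAM input requires the Rsamtools package")
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(what = c("seq", "rname", "pos", "strand", "flag"),
                               tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(b$pos)
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(b$pos))
  nm[is.na(nm)] <- 0L
  seqs <- as.character(b$seq)[mapped]
  # SAM stores SEQ on the forward genome strand; recover the read sequence
  minus <- as.character(b$strand)[mapped] == "-"
  seqs[minus] <- revcomp(seqs[minus])
  data.frame(sequence = seqs,
             chrom = as.character(b$rname)[mapped],
             start = b$pos[mapped] - 1L,
             end = b$pos[mapped] - 1L + nchar(seqs),
             strand = as.character(b$strand)[mapped],
             mismatches = nm[mapped], stringsAsFactors = FALSE)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

library_columns <- function(tags, libraries) {
  libs <- libraries$name
  miss <- setdiff(libs, names(tags))
  if (length(miss))
    stop("tag table lacks count column(s) for library(ies): ",
         paste(miss, collapse = ", "))
  libs
}

#' Assign small-RNA tags to cis-NAT overlap regions
#'
#' A (pair, tag, alignment) triple is retained iff the alignment is a perfect
#' match (`mismatches == 0`), the tag length is within `[min_len, max_len]`,
#' the alignment interval lies fully inside the pair's overlap interval
#' (set `contained = FALSE` to accept any overlap), and the tag reaches at
#' least `min_rp10m` normalized reads in at least one library. A tag mapping
#' into several overlaps contributes its full count to each.
#'
#' @param pairs pair data.frame from [find_pairs].
#' @param tags tag data.frame from [read_tag_table]/[tag_table].
#' @param alignments alignment data.frame from [read_alignments].
#' @param libraries data.frame from [srna_libraries].
#' @param min_rp10m abundance threshold in RP10M (default 5).
#' @param min_len,max_len tag length window in nt (defaults 20 and 28).
#' @param contained require full containment in the overlap (default TRUE).
#' @return data.frame of retained assignments: `pair_id`, `sequence`,
#'   `aligned_strand`, `start`, `end`, `length`.
#' @export
assign_tags <- function(pairs, tags, alignments, libraries,
                        min_rp10m = 5, min_len = 20, max_len = 28,
                        contained = TRUE) {
  empty <- data.frame(pair_id = character(), sequence = character(),
                      aligned_strand = character(), start = numeric(),
                      end = numeric(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || nrow(tags) == 0 || nrow(alignments) == 0)
    return(empty)
  libs <- library_columns(tags, libraries)
  norm <- mapply(function(l, tot) rp10m(tags[[l]], tot),
                 libs, libraries$total_reads)
  norm <- matrix(norm, nrow = nrow(tags))
  abundant <- tags$sequence[apply(norm, 1, max) >= min_rp10m]

  al <- alignments
  al$length <- nchar(al$sequence)
  al <- al[al$mismatches == 0 & al$length >= min_len & al$length <= max_len &
           al$sequence %in% abundant, , drop = FALSE]
  if (nrow(al) == 0) return(empty)

  gr_al <- GenomicRanges::GRanges(al$chrom, IRanges::IRanges(al$start + 1L, al$end))
  gr_ov <- GenomicRanges::GRanges(pairs$chrom,
                                  IRanges::IRanges(pairs$overlap_start + 1L,
                                                   pairs$overlap_end))
  type <- if (contained) "within" else "any"
  hits <- GenomicRanges::findOverlaps(gr_al, gr_ov, type = type,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(pair_id = pairs$pair_id[si],
                    sequence = al$sequence[qi],
                    aligned_strand = al$strand[qi],
                    start = al$start[qi], end = al$end[qi],
                    length = al$length[qi], stringsAsFactors = FALSE)
  out <- out[order(out$pair_id, out$start, out$sequence, out$aligned_strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pair forward- and reverse-strand read totals
#'
#' Sums the raw counts (in one library) of retained tags over the genome
#' forward strand (`FR`) and reverse strand (`RR`) of each pair's overlap
#' region. Each retained alignment contributes the tag's full library count.
#'
#' @param assignments data.frame from [assign_tags].
#' @param tags tag data.frame carrying the library count columns.
#' @param library a single library name (a count column of `tags`).
#' @return data.frame: `pair_id`, `FR`, `RR`.
#' @export
pair_strand_totals <- function(assignments, tags, library) {
  if (!library %in% names(tags)) stop("unknown library: ", library)
  if (nrow(assignments) == 0)
    return(data.frame(pair_id = character(), FR = numeric(), RR = numeric(),
                      stringsAsFactors = FALSE))
  cnt <- tags[[library]][match(assignments$sequence, tags$sequence)]
  cnt[is.na(cnt)] <- 0
  fr <- tapply(cnt * (assignments$aligned_strand == "+"), assignments$pair_id, sum)
  rr <- tapply(cnt * (assignments$aligned_strand == "-"), assignments$pair_id, sum)
  data.frame(pair_id = names(fr), FR = as.numeric(fr), RR = as.numeric(rr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Length and first-nucleotide distributions of assigned nat-siRNAs
#'
#' Computed both over unique tag sequences (each counted once) and
#' read-weighted (each tag weighted by its summed raw counts across the given
#' libraries). Fractions sum to 1 when the input is nonempty.
#'
#' @param assignments data.frame from [assign_tags].
#' @param tags tag data.frame with count columns.
#' @param libraries data.frame from [srna_libraries]; read weighting sums
#'   raw counts over these libraries.
#' @return For [length_distribution], a data.frame `length`, `unique_frac`,
#'   `read_frac` over 20-28 nt; for [first_nt_distribution] the same over
#'   `A`, `C`, `G`, `U`.
#' @export
length_distribution <- function(assignments, tags, libraries) {
  u <- unique(assignments[, c("sequence", "length")])
  bins <- 20:28
  if (nrow(u) == 0)
    return(data.frame(length = integer(), unique_frac = numeric(),
                      read_frac = numeric()))
  w <- tag_read_weights(u$sequence, tags, libraries)
  uf <- tabulate(factor(u$length, levels = bins), nbins = length(bins))
  rf <- vapply(bins, function(b) sum(w[u$length == b]), 0)
  data.frame(length = bins, unique_frac = uf / sum(uf),
             read_frac = if (sum(rf) > 0) rf / sum(rf) else rf)
}

#' @rdname length_distribution
#' @export
first_nt_distribution <- function(assignments, tags, libraries) {
  u <- unique(assignments[, c("sequence"), drop = FALSE])
  lv <- c("A", "C", "G", "U")
  if (nrow(u) == 0)
    return(data.frame(first_nt = character(), unique_frac = numeric(),
                      read_frac = numeric()))
  fn <- chartr("T", "U", substr(u$sequence, 1, 1))
  w <- tag_read_weights(u$sequence, tags, libraries)
  uf <- tabulate(factor(fn, levels = lv), nbins = length(lv))
  rf <- vapply(lv, function(b) sum(w[fn == b]), 0)
  data.frame(first_nt = lv, unique_frac = uf / sum(uf),
             read_frac = if (sum(rf) > 0) rf / sum(rf) else rf,
             row.names = NULL)
}

tag_read_weights <- function(sequences, tags, libraries) {
  libs <- library_columns(tags, libraries)
  m <- match(sequences, tags$sequence)
  w <- rowSums(as.matrix(tags[m, libs, drop = FALSE]))
  w[is.na(w)] <- 0
  w
}
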