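#' @import methods
#' @importFrom stats rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Internal coordinates are 0-based half-open throughout; GFF3/GTF at the file
# boundary are 1-based inclusive. length = end - start.

#' Construct an annotation set of stranded transcript models
#'
#' An `annotation_set` holds one transcript model per gene: a stranded span on
#' a chromosome plus an ordered exon structure. It is the common currency of
#' the antisense-pair detection, miRNA-placement and simulation functions.
#' Coordinates are 0-based half-open.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` and optionally `biotype` (one of
#'   `"coding"`, `"pre_miRNA"`; default `"coding"`) and `provenance` (one of
#'   `"cds_only"`, `"utr_extended"`; default `"cds_only"`).
#' @param exons optional data.frame with columns `transcript_id`, `start`,
#'   `end` giving the exon structure; when omitted every model is single-exon.
#'   Exons must be non-overlapping; they are sorted by start and the model
#'   span is set to cover them exactly.
#' @return An object of class `annotation_set`: a list with data.frames
#'   `transcripts` and `exons`.
#' @examples
#' ann <- annotation_set(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = 100, end = 400, strand = "+"))
#' ann
#' @export
annotation_set <- function(transcripts, exons = NULL) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols))
    stop("transcripts is missing column(s): ", paste(missing_cols, collapse = ", "))
  tr <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  tr$transcript_id <- as.character(tr$transcript_id)
  tr$gene_id <- as.character(tr$gene_id)
  tr$chrom <- as.character(tr$chrom)
  tr$start <- as.numeric(tr$start)
  tr$end <- as.numeric(tr$end)
  tr$strand <- as.character(tr$strand)
  if (is.null(tr$biotype)) tr$biotype <- "coding"
  if (is.null(tr$provenance)) tr$provenance <- "cds_only"
  if (anyDuplicated(tr$gene_id))
    stop("gene_id must be unique within an annotation set; duplicated: ",
         paste(unique(tr$gene_id[duplicated(tr$gene_id)]), collapse = ", "))
  if (anyDuplicated(tr$transcript_id))
    stop("transcript_id must be unique within an annotation set")
  bad_strand <- !tr$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("strand must be '+' or '-' (unstranded records are rejected); offending model(s): ",
         paste(tr$transcript_id[bad_strand], collapse = ", "))
  if (!all(tr$biotype %in% c("coding", "pre_miRNA")))
    stop("biotype must be 'coding' or 'pre_miRNA'")

  if (is.null(exons)) {
    exons <- data.frame(transcript_id = tr$transcript_id,
                        start = tr$start, end = tr$end,
                        stringsAsFactors = FALSE)
  }
  ex <- as.data.frame(exons, stringsAsFactors = FALSE)
  ex$transcript_id <- as.character(ex$transcript_id)
  ex$start <- as.numeric(ex$start)
  ex$end <- as.numeric(ex$end)
  if (!all(ex$transcript_id %in% tr$transcript_id))
    stop("exons reference unknown transcript_id(s)")
  orphan <- setdiff(tr$transcript_id, ex$transcript_id)
  if (length(orphan))
    stop("model(s) without exons: ", paste(orphan, collapse = ", "))
  if (any(ex$start < 0) || any(ex$end <= ex$start))
    stop("coordinate error: exon start must be >= 0 and end > start")
  ex <- ex[order(match(ex$transcript_id, tr$transcript_id), ex$start), , drop = FALSE]
  ex$chrom <- tr$chrom[match(ex$transcript_id, tr$transcript_id)]
  ex$strand <- tr$strand[match(ex$transcript_id, tr$transcript_id)]
  # exon disjointness within each model
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- ex$start[idx]; e <- ex$end[idx]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping exons in model ", ex$transcript_id[idx[1]])
    }
  }
  # canonical span = exon extremes
  tr$start <- vapply(tr$transcript_id, function(t) min(ex$start[ex$transcript_id == t]), 0)
  tr$end <- vapply(tr$transcript_id, function(t) max(ex$end[ex$transcript_id == t]), 0)
  if (any(tr$start < 0) || any(tr$end <= tr$start))
    stop("coordinate error: start must be >= 0 and end > start")
  rownames(tr) <- NULL
  rownames(ex) <- NULL
  structure(list(transcripts = tr,
                 exons = ex[, c("transcript_id", "chrom", "start", "end", "strand")]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "models (",
      sum(x$transcripts$biotype == "pre_miRNA"), "pre-miRNA ) on",
      length(unique(x$transcripts$chrom)), "chromosome(s);",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$transcripts)

# GRanges view of model spans (1-based inclusive for IRanges arithmetic)
span_granges <- function(ann) {
  tr <- ann$transcripts
  gr <- GenomicRanges::GRanges(tr$chrom,
                               IRanges::IRanges(tr$start + 1L, tr$end),
                               strand = tr$strand)
  S4Vectors::mcols(gr)$gene_id <- tr$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tr$transcript_id
  S4Vectors::mcols(gr)$biotype <- tr$biotype
  gr
}

exon_granges <- function(ann) {
  ex <- ann$exons
  gr <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end),
                               strand = ex$strand)
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  gr
}

# ---------------------------------------------------------------------------
# Reading

# Light line-level scan so malformed input is reported with its line number;
# the actual parsing is delegated to rtracklayer::import.
validate_annotation_lines <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (dialect %in% c("gff3", "gtf")) {
      if (length(f) < 9)
        stop("parse error at line ", i, ": expected 9 tab-separated fields, got ",
             length(f))
      s1 <- suppressWarnings(as.numeric(f[4]))
      e1 <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s1) || is.na(e1))
        stop("parse error at line ", i, ": non-numeric coordinates")
      if (e1 < s1)
        stop("coordinate error at line ", i, ": end < start")
      if (!f[7] %in% c("+", "-"))
        stop("parse error at line ", i,
             ": unstranded or invalid strand '", f[7], "' (records must be + or -)")
    } else if (dialect == "bed") {
      if (length(f) < 6)
        stop("parse error at line ", i, ": BED6 requires 6 fields, got ", length(f))
      s0 <- suppressWarnings(as.numeric(f[2]))
      e0 <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s0) || is.na(e0))
        stop("parse error at line ", i, ": non-numeric coordinates")
      if (e0 <= s0)
        stop("coordinate error at line ", i, ": end <= start")
      if (!f[6] %in% c("+", "-"))
        stop("parse error at line ", i,
             ": unstranded or invalid strand '", f[6], "'")
    }
  }
  invisible(TRUE)
}

first_parent <- function(parent_list, n) {
  if (is.null(parent_list)) return(rep(NA_character_, n))
  vapply(as.list(parent_list), function(p) if (length(p)) p[[1]] else NA_character_,
         NA_character_)
}

mcol_chr <- function(gr, name) {
  v <- S4Vectors::mcols(gr)[[name]]
  if (is.null(v)) rep(NA_character_, length(gr)) else as.character(v)
}

#' Read a gene/transcript annotation
#'
#' Reads GFF3, GTF or BED6 into an [annotation_set]. File coordinates
#' (1-based inclusive for GFF3/GTF, 0-based half-open for BED) are converted
#' to the internal 0-based half-open convention. Multi-exon records sharing a
#' transcript identifier are grouped into one model. Unstranded (`.`) records
#' are rejected.
#'
#' For GFF3, rows of type `mRNA`/`transcript`/`pre_miRNA` define models
#' (`gene_id` taken from their `Parent` when present), `exon` rows are
#' attached via `Parent`, and bare `gene` rows or orphan exon groups become
#' models of their own. For GTF, `exon` rows are grouped by `transcript_id`.
#' BED6 yields one single-exon model per line (name = gene and transcript id).
#'
#' @param path file path.
#' @param dialect one of `"gff3"`, `"gtf"`, `"bed"`.
#' @param biotype biotype assigned to BED records (BED6 carries none);
#'   ignored for GFF3/GTF, where the feature type decides.
#' @return An [annotation_set].
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf", "bed"),
                            biotype = "coding") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_annotation_lines(path, dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "bed" else dialect)
  if (length(gr) == 0) stop("no records in ", path)

  if (dialect == "bed") {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm) || anyNA(nm)) stop("BED6 input requires a name field on every line")
    tr <- data.frame(transcript_id = nm, gene_id = nm,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     biotype = biotype, stringsAsFactors = FALSE)
    return(annotation_set(tr))
  }

  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   stringsAsFactors = FALSE)

  if (dialect == "gtf") {
    df$transcript_id <- mcol_chr(gr, "transcript_id")
    df$gene_id <- mcol_chr(gr, "gene_id")
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) ex <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
    if (nrow(ex) == 0) stop("no exon or transcript records in ", path)
    tx_ids <- unique(ex$transcript_id)
    tr <- data.frame(transcript_id = tx_ids,
                     gene_id = ex$gene_id[match(tx_ids, ex$transcript_id)],
                     chrom = ex$chrom[match(tx_ids, ex$transcript_id)],
                     start = 0, end = 1,
                     strand = ex$strand[match(tx_ids, ex$transcript_id)],
                     biotype = "coding", stringsAsFactors = FALSE)
    tr$gene_id[is.na(tr$gene_id)] <- tr$transcript_id[is.na(tr$gene_id)]
    exons <- ex[, c("transcript_id", "start", "end")]
    return(annotation_set(tr, exons))
  }

  # GFF3
  df$ID <- mcol_chr(gr, "ID")
  df$Parent <- first_parent(S4Vectors::mcols(gr)$Parent, length(gr))
  df$source <- mcol_chr(gr, "source")

  model_types <- c("mRNA", "transcript", "pre_miRNA", "miRNA_primary_transcript")
  is_model <- df$type %in% model_types
  is_exon <- df$type == "exon"
  is_gene <- df$type == "gene"

  models <- df[is_model, , drop = FALSE]
  # bare gene rows that parent no model row become models themselves
  bare_gene <- df[is_gene & !(df$ID %in% models$Parent), , drop = FALSE]
  if (nrow(bare_gene)) {
    bare_gene$Parent <- NA_character_
    models <- rbind(models, bare_gene)
  }
  # orphan exon groups (no declared model row) become models too
  ex <- df[is_exon, , drop = FALSE]
  if (nrow(ex) && anyNA(match(ex$Parent, models$ID))) {
    orphan_ids <- setdiff(unique(ex$Parent), models$ID)
    for (oid in orphan_ids) {
      oe <- ex[ex$Parent == oid, , drop = FALSE]
      models <- rbind(models, data.frame(
        chrom = oe$chrom[1], start = min(oe$start), end = max(oe$end),
        strand = oe$strand[1], type = "mRNA", ID = oid, Parent = NA_character_,
        source = oe$source[1], stringsAsFactors = FALSE))
    }
  }
  if (nrow(models) == 0) stop("no transcript models in ", path)
  if (anyNA(models$ID)) stop("GFF3 model rows must carry an ID attribute")

  tr <- data.frame(
    transcript_id = models$ID,
    gene_id = ifelse(is.na(models$Parent), models$ID, models$Parent),
    chrom = models$chrom, start = models$start, end = models$end,
    strand = models$strand,
    biotype = ifelse(models$type %in% c("pre_miRNA", "miRNA_primary_transcript"),
                     "pre_miRNA", "coding"),
    provenance = ifelse(models$source %in% c("cds_only", "utr_extended"),
                        models$source, "cds_only"),
    stringsAsFactors = FALSE)

  if (nrow(ex)) {
    keep <- ex$Parent %in% tr$transcript_id
    exons <- data.frame(transcript_id = ex$Parent[keep],
                        start = ex$start[keep], end = ex$end[keep],
                        stringsAsFactors = FALSE)
    # models with no exon children are single-exon
    no_child <- setdiff(tr$transcript_id, exons$transcript_id)
    if (length(no_child)) {
      m <- tr[match(no_child, tr$transcript_id), ]
      exons <- rbind(exons, data.frame(transcript_id = m$transcript_id,
                                       start = m$start, end = m$end))
    }
  } else {
    exons <- NULL
  }
  annotation_set(tr, exons)
}

# ---------------------------------------------------------------------------
# Writing

gff3_attr <- function(id, parent) {
  a <- character(length(id))
  has_id <- !is.na(id)
  has_p <- !is.na(parent)
  a[has_id & !has_p] <- paste0("ID=", id[has_id & !has_p])
  a[has_id & has_p] <- paste0("ID=", id[has_id & has_p], ";Parent=", parent[has_id & has_p])
  a[!has_id & has_p] <- paste0("Parent=", parent[!has_id & has_p])
  a
}

#' Write an annotation set
#'
#' GFF3 output carries the full model structure (gene, mRNA/pre_miRNA and
#' exon rows; provenance stored in the source column) and round-trips exactly
#' through [read_annotation]. BED6 writes one line per model span (exon
#' structure is collapsed, as the format requires).
#'
#' @param ann an [annotation_set].
#' @param path output file path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  tr <- ann$transcripts
  if (dialect == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     tr$chrom, as.integer(tr$start), as.integer(tr$end),
                     tr$gene_id, tr$strand)
    writeLines(lines, path)
    return(invisible(path))
  }
  ex <- ann$exons
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(tr))) {
    g <- tr[i, ]
    ftype <- if (g$biotype == "pre_miRNA") "pre_miRNA" else "mRNA"
    out <- c(out,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s", g$chrom, g$provenance,
              as.integer(g$start) + 1L, as.integer(g$end), g$strand,
              gff3_attr(g$gene_id, NA_character_)),
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", g$chrom, g$provenance, ftype,
              as.integer(g$start) + 1L, as.integer(g$end), g$strand,
              gff3_attr(g$transcript_id, g$gene_id)))
    gex <- ex[ex$transcript_id == g$transcript_id, , drop = FALSE]
    out <- c(out,
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s", g$chrom, g$provenance,
              as.integer(gex$start) + 1L, as.integer(gex$end), g$strand,
              gff3_attr(rep(NA_character_, nrow(gex)),
                        rep(g$transcript_id, nrow(gex)))))
  }
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# UTR extension by assembled transcripts

#' Extend CDS-only models with assembled transcripts
#'
#' Many plant genome releases annotate coding sequence only, without UTRs.
#' Given a set of assembled transcripts (e.g. from a reference-guided
#' assembler), each CDS model is linked to same-strand assembled transcripts
#' whose span overlaps it; the longest-span candidate replaces the model's
#' structure, stretched so the new span always covers the original CDS span
#' (`provenance = "utr_extended"`). Models with no overlapping assembly are
#' kept unchanged (`provenance = "cds_only"`). An assembled transcript
#' overlapping two CDS models is assigned to the one with the larger overlap
#' (ties to the lexicographically smaller gene id).
#'
#' @param cds_models [annotation_set] of CDS-only models.
#' @param assembled [annotation_set] of assembled transcripts (their gene ids
#'   are ignored; linkage is purely by same-strand span overlap).
#' @return An [annotation_set] with the same gene ids as `cds_models`.
#' @export
extend_with_assembly <- function(cds_models, assembled) {
  tr <- cds_models$transcripts
  chr_cds <- unique(tr$chrom)
  chr_asm <- unique(assembled$transcripts$chrom)
  only <- c(setdiff(chr_cds, chr_asm), setdiff(chr_asm, chr_cds))
  if (length(only))
    warning("chromosome(s) present in only one set: ",
            paste(only, collapse = ", "), "; models passed through unchanged")

  gr_cds <- span_granges(cds_models)
  gr_asm <- span_granges(assembled)
  hits <- GenomicRanges::findOverlaps(gr_asm, gr_cds, ignore.strand = FALSE)
  if (length(hits) == 0) return(cds_models)

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov_w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_asm)[qh], IRanges::ranges(gr_cds)[sh]))

  # assign each assembled transcript to one CDS model: largest overlap,
  # ties to smaller gene_id
  link <- data.frame(asm = qh, cds = sh, w = ov_w,
                     gene = tr$gene_id[sh], stringsAsFactors = FALSE)
  link <- link[order(link$asm, -link$w, link$gene), ]
  link <- link[!duplicated(link$asm), ]

  atr <- assembled$transcripts
  new_tr <- tr
  new_ex_list <- list()
  for (ci in unique(link$cds)) {
    cand <- link$asm[link$cds == ci]
    a <- atr[cand, , drop = FALSE]
    # longest span; ties to smaller start then transcript_id
    a <- a[order(-(a$end - a$start), a$start, a$transcript_id), ]
    best <- a[1, ]
    new_start <- min(best$start, tr$start[ci])
    new_end <- max(best$end, tr$end[ci])
    bex <- assembled$exons[assembled$exons$transcript_id == best$transcript_id, , drop = FALSE]
    bex <- bex[order(bex$start), ]
    bex$start[1] <- new_start
    bex$end[nrow(bex)] <- new_end
    # stretching terminal exons can swallow internal ones on pathological input
    if (nrow(bex) > 1 && any(bex$start[-1] < bex$end[-nrow(bex)])) {
      bex <- data.frame(transcript_id = best$transcript_id,
                        start = new_start, end = new_end,
                        chrom = bex$chrom[1], strand = bex$strand[1])
    }
    new_tr$start[ci] <- new_start
    new_tr$end[ci] <- new_end
    new_tr$provenance[ci] <- "utr_extended"
    bex$transcript_id <- tr$transcript_id[ci]
    new_ex_list[[tr$transcript_id[ci]]] <- bex[, c("transcript_id", "start", "end")]
  }
  old_ex <- cds_models$exons[!cds_models$exons$transcript_id %in% names(new_ex_list),
                             c("transcript_id", "start", "end"), drop = FALSE]
  annotation_set(new_tr, rbind(old_ex, do.call(rbind, new_ex_list)))
}

# ---------------------------------------------------------------------------
# pre-miRNA placement

#' Place pre-miRNA loci relative to host transcripts
#'
#' Classifies each pre-miRNA locus as `intronic` (fully contained within one
#' intron of a same-strand host transcript, with the intron index counted
#' 1-based in transcription order — reverse coordinate order on the minus
#' strand), `exon_overlapping` (overlaps any host exon on either strand by at
#' least 1 nt), or `intergenic`. The classes are mutually exclusive and
#' exhaustive; intron containment is tested first.
#'
#' @param mirnas [annotation_set] of pre-miRNA loci (`biotype = "pre_miRNA"`).
#' @param hosts [annotation_set] of candidate host transcripts.
#' @return data.frame with columns `mirna_id`, `host_gene_id`, `placement`,
#'   `intron_ordinal`.
#' @export
place_mirna <- function(mirnas, hosts) {
  mt <- mirnas$transcripts
  if (!all(mt$biotype == "pre_miRNA"))
    stop("all models in `mirnas` must have biotype 'pre_miRNA'")
  ht <- hosts$transcripts
  hex <- hosts$exons
  res <- data.frame(mirna_id = mt$gene_id,
                    host_gene_id = NA_character_,
                    placement = "intergenic",
                    intron_ordinal = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mt))) {
    m <- mt[i, ]
    same <- ht[ht$chrom == m$chrom & ht$strand == m$strand &
               ht$start <= m$start & ht$end >= m$end, , drop = FALSE]
    placed <- FALSE
    for (j in order(same$gene_id)) {
      h <- same[j, ]
      e <- hex[hex$transcript_id == h$transcript_id, , drop = FALSE]
      e <- e[order(e$start), ]
      if (nrow(e) < 2) next
      n_intron <- nrow(e) - 1L
      for (k in seq_len(n_intron)) {
        gap_s <- e$end[k]; gap_e <- e$start[k + 1]
        if (m$start >= gap_s && m$end <= gap_e) {
          res$placement[i] <- "intronic"
          res$host_gene_id[i] <- h$gene_id
          res$intron_ordinal[i] <- if (m$strand == "+") k else n_intron - k + 1L
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (placed) next
    # exon overlap on either strand
    cand <- hex[hex$chrom == m$chrom & hex$start < m$end & hex$end > m$start, , drop = FALSE]
    if (nrow(cand)) {
      g <- ht$gene_id[match(cand$transcript_id, ht$transcript_id)]
      res$placement[i] <- "exon_overlapping"
      res$host_gene_id[i] <- sort(g)[1]
    }
  }
  res
}
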