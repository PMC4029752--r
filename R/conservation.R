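# Cross-species conservation of antisense pairs via a homolog table.

#' Read a two-column homolog table
#'
#' TSV with species-1 gene ids in the first column and species-2 gene ids in
#' the second; many-to-many relationships are permitted (expected for
#' genomes with ancestral duplications). Duplicate rows are collapsed.
#'
#' @param path TSV path (header optional; columns are taken positionally).
#' @return data.frame with columns `gene_1`, `gene_2`.
#' @export
read_homolog_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "gene_1"))
    df <- df[-1, , drop = FALSE]
  homolog_table(df[[1]], df[[2]])
}

#' Assemble a homolog table
#'
#' @param gene_1,gene_2 paired gene-id vectors (species 1 and species 2).
#' @return data.frame with columns `gene_1`, `gene_2`, deduplicated, no
#'   empty ids.
#' @export
homolog_table <- function(gene_1, gene_2) {
  df <- data.frame(gene_1 = as.character(gene_1), gene_2 = as.character(gene_2),
                   stringsAsFactors = FALSE)
  df <- df[nzchar(df$gene_1) & nzchar(df$gene_2) & !is.na(df$gene_1) &
           !is.na(df$gene_2), , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find conserved antisense pairs between two species
#'
#' A species-1 pair (g, h) is conserved iff some species-2 pair (g', h')
#' exists with g' a homolog of g and h' a homolog of h (member order is
#' normalized, so matches in either order count). All qualifying
#' combinations are emitted; `copy_count` gives, for each species-2 pair,
#' the number of distinct species-1 pairs matched to it. Gene ids absent
#' from the table simply have no homologs.
#'
#' @param pairs_1,pairs_2 pair data.frames (as from [find_pairs]) in
#'   species 1 and species 2.
#' @param homologs data.frame from [homolog_table] (species-1 ids in
#'   `gene_1`).
#' @return data.frame: `pair_1`, `pair_2` (pair-id strings), `copy_count`.
#' @export
find_conserved_pairs <- function(pairs_1, pairs_2, homologs) {
  empty <- data.frame(pair_1 = character(), pair_2 = character(),
                      copy_count = integer(), stringsAsFactors = FALSE)
  if (nrow(pairs_1) == 0 || nrow(pairs_2) == 0 || nrow(homologs) == 0)
    return(empty)
  m1 <- data.frame(pid = pairs_1$pair_id, gene = pairs_1$gene_a,
                   stringsAsFactors = FALSE)
  m2 <- data.frame(pid = pairs_1$pair_id, gene = pairs_1$gene_b,
                   stringsAsFactors = FALSE)
  a <- merge(m1, homologs, by.x = "gene", by.y = "gene_1")
  b <- merge(m2, homologs, by.x = "gene", by.y = "gene_1")
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  comb <- merge(a[, c("pid", "gene_2")], b[, c("pid", "gene_2")],
                by = "pid", suffixes = c("_a", "_b"))
  comb$key <- pair_id(comb$gene_2_a, comb$gene_2_b)
  hit <- comb[comb$key %in% pairs_2$pair_id, c("pid", "key"), drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  rec <- unique(data.frame(pair_1 = hit$pid, pair_2 = hit$key,
                           stringsAsFactors = FALSE))
  copies <- table(rec$pair_2)
  rec$copy_count <- as.integer(copies[rec$pair_2])
  rec <- rec[order(rec$pair_1, rec$pair_2), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Summarize pair conservation
#'
#' @param records data.frame from [find_conserved_pairs].
#' @param pairs_1 the species-1 pair data.frame the records were computed
#'   from.
#' @param producing_subset character vector of species-1 pair ids that
#'   produce nat-siRNAs (must be a subset of `pairs_1$pair_id`).
#' @return one-row data.frame: `conserved_1` (distinct conserved species-1
#'   pairs), `distinct_2` (distinct species-2 partners), `specific_1`
#'   (species-1 pairs with no conserved partner), `conserved_producing`.
#' @export
conservation_summary <- function(records, pairs_1, producing_subset = character()) {
  if (length(producing_subset) && !all(producing_subset %in% pairs_1$pair_id))
    stop("producing_subset must be a subset of pairs_1 identities")
  conserved_ids <- unique(records$pair_1)
  data.frame(
    conserved_1 = length(conserved_ids),
    distinct_2 = length(unique(records$pair_2)),
    specific_1 = length(unique(pairs_1$pair_id)) - length(conserved_ids),
    conserved_producing = length(intersect(conserved_ids, producing_subset)))
}
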