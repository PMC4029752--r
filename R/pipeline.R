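# End-to-end orchestration: pair detection -> miRNA exclusion -> tag
# assignment -> strand-bias and condition-response calls.

#' Run the full antisense-pair / nat-siRNA pipeline
#'
#' Detects antisense pairs in the annotation, excludes pairs overlapping
#' pre-miRNA loci, assigns small-RNA tags to overlap regions under the
#' standard filters, and calls strand bias (FR/RR pooled across the given
#' libraries) and, when the libraries include NT/HT replicates 1 and 2,
#' replicate-concordant heat response. Structured per-stage counts are
#' logged to standard error when `verbose = TRUE`.
#'
#' @param genes [annotation_set] of gene models.
#' @param premirnas [annotation_set] of pre-miRNA loci, or `NULL`.
#' @param tags tag data.frame ([read_tag_table]/[tag_table]).
#' @param alignments alignment data.frame ([read_alignments]).
#' @param libraries data.frame from [srna_libraries].
#' @param min_overlap,max_overlap overlap-length window (defaults 26, 1999).
#' @param min_rp10m,min_len,max_len nat-siRNA filters (defaults 5, 20, 28).
#' @param fold,alpha response thresholds (defaults 2, 0.01).
#' @param verbose log per-stage counts to stderr.
#' @return list: `pairs`, `excluded`, `assignments`, `producing_ids`,
#'   `strand_totals` (per-pair FR/RR per library), `strand_bias`,
#'   `heat_response` (`NULL` without NT/HT replicates), `length_dist`,
#'   `first_nt_dist`.
#' @export
run_pipeline <- function(genes, premirnas, tags, alignments, libraries,
                         min_overlap = 26, max_overlap = 1999,
                         min_rp10m = 5, min_len = 20, max_len = 28,
                         fold = 2, alpha = 0.01, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message("[cisnat] ", ...)
  pairs <- find_pairs(genes, min_overlap, max_overlap)
  log_stage("find_pairs: ", length(genes), " models -> ", nrow(pairs), " pairs")
  excl <- exclude_mirna_overlaps(pairs, premirnas, genes)
  pairs <- excl$pairs
  log_stage("exclude_mirna_overlaps: ", nrow(excl$excluded),
            " pair(s) dropped, ", nrow(pairs), " retained")
  assignments <- assign_tags(pairs, tags, alignments, libraries,
                             min_rp10m = min_rp10m, min_len = min_len,
                             max_len = max_len)
  log_stage("assign_tags: ", nrow(tags), " tags, ", nrow(alignments),
            " alignments -> ", nrow(assignments), " assignments in ",
            length(unique(assignments$pair_id)), " pair(s)")
  producing_ids <- unique(assignments$pair_id)

  # FR/RR per pair per library; strand bias on totals pooled across libraries
  totals <- lapply(libraries$name, function(l)
    pair_strand_totals(assignments, tags, l))
  names(totals) <- libraries$name
  pooled <- NULL
  for (l in libraries$name) {
    t <- totals[[l]]
    if (is.null(pooled)) pooled <- t
    else {
      m <- match(t$pair_id, pooled$pair_id)
      pooled$FR <- pooled$FR + t$FR[m]
      pooled$RR <- pooled$RR + t$RR[m]
    }
  }
  strand_bias <- if (!is.null(pooled) && nrow(pooled))
    call_strand_bias(pooled$FR, pooled$RR, alpha = alpha,
                     pair_id = pooled$pair_id)
  else NULL
  if (!is.null(strand_bias))
    log_stage("strand bias: ", sum(strand_bias$biased), " of ",
              nrow(strand_bias), " producing pair(s)")

  heat <- NULL
  has_reps <- all(vapply(list(c("NT", 1), c("HT", 1), c("NT", 2), c("HT", 2)),
                         function(cr) any(libraries$condition == cr[1] &
                                          libraries$replicate == as.integer(cr[2])),
                         TRUE))
  if (has_reps && length(producing_ids)) {
    lib_of <- function(cond, rep)
      libraries$name[libraries$condition == cond & libraries$replicate == rep][1]
    per_lib <- function(nm) {
      t <- totals[[nm]]
      tot <- t$FR + t$RR
      tot[match(producing_ids, t$pair_id)]
    }
    heat <- call_heat_response(per_lib(lib_of("NT", 1)), per_lib(lib_of("HT", 1)),
                               per_lib(lib_of("NT", 2)), per_lib(lib_of("HT", 2)),
                               libraries, fold = fold, alpha = alpha,
                               pair_id = producing_ids)
    log_stage("heat response: ", sum(heat$significant), " significant pair(s)")
  }

  list(pairs = pairs, excluded = excl$excluded, assignments = assignments,
       producing_ids = producing_ids, strand_totals = totals,
       strand_bias = strand_bias, heat_response = heat,
       length_dist = length_distribution(assignments, tags, libraries),
       first_nt_dist = first_nt_distribution(assignments, tags, libraries))
}
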