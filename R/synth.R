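# Self-contained synthetic data: annotation, pre-miRNA loci, homolog table
# and small-RNA libraries with a machine-readable truth manifest.

derive_seed <- function(seed, k) as.integer((seed * 1009 + k) %% 2147483647)

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a desk-scale version of a two-condition, two-replicate
#' small-RNA experiment over an annotation of antisense gene pairs: library
#' sizes of 10 million reads (so the 5 RP10M abundance filter equals 5 raw
#' reads), ~50 reads per overlap strand at baseline, Poisson count noise,
#' an 8:1 planted strand-bias ratio and a 4-fold planted heat response.
#'
#' @param seed integer seed driving all randomness (per-library substreams
#'   are derived from it).
#' @param n_convergent,n_divergent,n_enclosed planted pair counts per
#'   orientation class.
#' @param n_singleton non-overlapping genes.
#' @param n_premirna_overlapping additional (convergent) pairs carrying a
#'   pre-miRNA locus inside one member, which the pipeline must exclude.
#' @param overlap_length_range `[min, max]` planted overlap length in nt;
#'   must lie within `[26, 1999]`.
#' @param libraries data.frame from [srna_libraries]; default NT1/HT1/NT2/HT2
#'   at 1e7 total reads each.
#' @param planted_strand_bias FR:RR mean ratio planted in strand-biased
#'   pairs (default 8).
#' @param planted_heat_fold HT/NT mean fold planted in heat-responsive pairs
#'   (default 4; down-regulated pairs use its reciprocal).
#' @param per_strand_mean baseline mean reads per overlap strand per library
#'   (default 50).
#' @param background_tag_rate mean number of tag species per non-pair gene
#'   (default 1).
#' @param n_strand_biased,n_heat_up,n_heat_down how many non-excluded pairs
#'   carry each planted effect.
#' @param overdispersion gamma-Poisson overdispersion of tag counts
#'   (variance = mean * (1 + overdispersion * mean)); 0 (default) gives pure
#'   Poisson noise, the sampling model the count-contrast test assumes.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_convergent = 12, n_divergent = 4, n_enclosed = 4,
                              n_singleton = 10, n_premirna_overlapping = 2,
                              overlap_length_range = c(60, 400),
                              libraries = srna_libraries(
                                c("NT1", "HT1", "NT2", "HT2"),
                                c("NT", "HT", "NT", "HT"),
                                c(1L, 1L, 2L, 2L), rep(1e7, 4)),
                              planted_strand_bias = 8,
                              planted_heat_fold = 4,
                              per_strand_mean = 50,
                              background_tag_rate = 1,
                              n_strand_biased = 6,
                              n_heat_up = 3, n_heat_down = 3,
                              overdispersion = 0) {
  counts <- c(n_convergent, n_divergent, n_enclosed, n_singleton,
              n_premirna_overlapping, n_strand_biased, n_heat_up, n_heat_down)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (overlap_length_range[1] < 26 || overlap_length_range[2] > 1999 ||
      overlap_length_range[1] > overlap_length_range[2])
    stop("overlap_length_range must lie within [26, 1999]")
  n_pairs <- n_convergent + n_divergent + n_enclosed
  if (n_strand_biased > n_pairs || n_heat_up + n_heat_down > n_pairs)
    stop("planted effects exceed the number of non-excluded pairs")
  if (planted_strand_bias < 1) stop("planted_strand_bias is an FR:RR ratio >= 1")
  if (planted_heat_fold < 1) stop("planted_heat_fold is a fold >= 1")
  structure(list(seed = as.integer(seed),
                 n_convergent = n_convergent, n_divergent = n_divergent,
                 n_enclosed = n_enclosed, n_singleton = n_singleton,
                 n_premirna_overlapping = n_premirna_overlapping,
                 overlap_length_range = overlap_length_range,
                 libraries = libraries,
                 planted_strand_bias = planted_strand_bias,
                 planted_heat_fold = planted_heat_fold,
                 per_strand_mean = per_strand_mean,
                 background_tag_rate = background_tag_rate,
                 n_strand_biased = n_strand_biased,
                 n_heat_up = n_heat_up, n_heat_down = n_heat_down,
                 overdispersion = overdispersion),
            class = "simulation_config")
}

#' Simulate an annotation with planted antisense pairs
#'
#' Lays out gene pairs of each orientation class along two synthetic
#' chromosomes, spaced so no unplanned overlaps arise, plus non-overlapping
#' singleton genes and (for `n_premirna_overlapping` extra convergent pairs)
#' a pre-miRNA locus inside the plus-strand member. Deterministic given the
#' config seed; identical configs produce byte-identical GFF3 via
#' [write_annotation].
#'
#' @param config a [simulation_config].
#' @return list: `genes` ([annotation_set]), `premirnas` ([annotation_set]
#'   or `NULL`), `manifest` (list with a per-pair truth data.frame `pairs`
#'   and the config).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  ovr <- config$overlap_length_range
  orientations <- c(rep("convergent", config$n_convergent),
                    rep("divergent", config$n_divergent),
                    rep("enclosed", config$n_enclosed),
                    rep("convergent", config$n_premirna_overlapping))
  mirna_flag <- c(rep(FALSE, config$n_convergent + config$n_divergent +
                        config$n_enclosed),
                  rep(TRUE, config$n_premirna_overlapping))
  n_pairs <- length(orientations)
  cursors <- c(chrS1 = 1000, chrS2 = 1000)
  genes <- list(); mirnas <- list(); truth <- list()
  gi <- 0L
  next_gene <- function() { gi <<- gi + 1L; sprintf("SYNG%04d", gi) }

  for (i in seq_len(n_pairs)) {
    chrom <- names(cursors)[(i %% 2) + 1L]
    p <- cursors[[chrom]]
    ov <- sample(ovr[1]:ovr[2], 1)
    ori <- orientations[i]
    if (ori == "convergent") {
      La <- ov + sample(300:1500, 1); Lb <- ov + sample(300:1500, 1)
      a <- c(p, p + La); b <- c(p + La - ov, p + La - ov + Lb)
    } else if (ori == "divergent") {
      La <- ov + sample(300:1500, 1); Lb <- ov + sample(300:1500, 1)
      b <- c(p, p + Lb); a <- c(p + Lb - ov, p + Lb - ov + La)
    } else {  # enclosed: minus member sits inside the plus member
      La <- ov + sample(300:1500, 1)
      off <- sample(seq_len(La - ov - 1), 1)
      a <- c(p, p + La); b <- c(p + off, p + off + ov)
    }
    id_a <- next_gene(); id_b <- next_gene()
    genes[[id_a]] <- data.frame(transcript_id = paste0(id_a, ".1"), gene_id = id_a,
                                chrom = chrom, start = a[1], end = a[2],
                                strand = "+", stringsAsFactors = FALSE)
    genes[[id_b]] <- data.frame(transcript_id = paste0(id_b, ".1"), gene_id = id_b,
                                chrom = chrom, start = b[1], end = b[2],
                                strand = "-", stringsAsFactors = FALSE)
    if (mirna_flag[i]) {
      mid <- sprintf("SYNMIR%03d", length(mirnas) + 1L)
      ms <- a[1] + 10
      mirnas[[mid]] <- data.frame(transcript_id = mid, gene_id = mid,
                                  chrom = chrom, start = ms, end = ms + 120,
                                  strand = "+", biotype = "pre_miRNA",
                                  stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      pair_id = pair_id(id_a, id_b), gene_plus = id_a, gene_minus = id_b,
      chrom = chrom, overlap_start = max(a[1], b[1]),
      overlap_end = min(a[2], b[2]), overlap_len = ov, orientation = ori,
      mirna_excluded = mirna_flag[i], stringsAsFactors = FALSE)
    cursors[[chrom]] <- max(a[2], b[2]) + 3000 + sample(0:2000, 1)
  }
  for (s in seq_len(config$n_singleton)) {
    chrom <- names(cursors)[(s %% 2) + 1L]
    p <- cursors[[chrom]]
    L <- sample(500:2000, 1)
    id <- next_gene()
    genes[[id]] <- data.frame(transcript_id = paste0(id, ".1"), gene_id = id,
                              chrom = chrom, start = p, end = p + L,
                              strand = sample(c("+", "-"), 1),
                              stringsAsFactors = FALSE)
    cursors[[chrom]] <- p + L + 3000 + sample(0:2000, 1)
  }

  pairs_df <- do.call(rbind, truth)
  # plant effects on non-excluded pairs only
  eligible <- pairs_df$pair_id[!pairs_df$mirna_excluded]
  biased <- if (config$n_strand_biased > 0)
    sample(eligible, config$n_strand_biased) else character()
  heat <- if (config$n_heat_up + config$n_heat_down > 0)
    sample(eligible, config$n_heat_up + config$n_heat_down) else character()
  heat_up <- utils::head(heat, config$n_heat_up)
  heat_down <- setdiff(heat, heat_up)

  pairs_df$true_bias_ratio <- 1
  # alternate which strand dominates among biased pairs
  if (length(biased)) {
    dominant_plus <- biased[seq_along(biased) %% 2 == 1]
    pairs_df$true_bias_ratio[pairs_df$pair_id %in% dominant_plus] <-
      config$planted_strand_bias
    pairs_df$true_bias_ratio[pairs_df$pair_id %in% setdiff(biased, dominant_plus)] <-
      1 / config$planted_strand_bias
  }
  pairs_df$true_heat_fold <- 1
  pairs_df$true_heat_fold[pairs_df$pair_id %in% heat_up] <- config$planted_heat_fold
  pairs_df$true_heat_fold[pairs_df$pair_id %in% heat_down] <- 1 / config$planted_heat_fold
  pairs_df$true_heat_direction <- ifelse(pairs_df$true_heat_fold > 1, "up",
                                         ifelse(pairs_df$true_heat_fold < 1,
                                                "down", "none"))
  rownames(pairs_df) <- NULL

  gene_set <- annotation_set(do.call(rbind, genes))
  mir_set <- if (length(mirnas)) annotation_set(do.call(rbind, mirnas)) else NULL
  list(genes = gene_set, premirnas = mir_set,
       manifest = list(pairs = pairs_df, config = unclass(config)))
}

sample_tag_species <- function(n, ov_start, ov_end) {
  len_lv <- 20:28
  len_p <- c(0.08, 0.30, 0.10, 0.08, 0.15, 0.08, 0.07, 0.07, 0.07)
  nt_p <- c(A = 0.40, C = 0.15, G = 0.20, T = 0.25)
  lens <- sample(len_lv, n, replace = TRUE, prob = len_p)
  lens <- pmin(lens, ov_end - ov_start)
  seqs <- vapply(lens, function(L) {
    paste0(sample(names(nt_p), 1, prob = nt_p),
           paste(sample(c("A", "C", "G", "T"), L - 1, replace = TRUE),
                 collapse = ""))
  }, "")
  starts <- ov_start + vapply(lens, function(L)
    sample(0:(ov_end - ov_start - L), 1), 0L)
  data.frame(sequence = seqs, start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

rcount <- function(n, lambda, overdispersion) {
  if (overdispersion > 0) {
    lam <- lambda * stats::rgamma(n, shape = 1 / overdispersion,
                                  scale = overdispersion)
    stats::rpois(n, lam)
  } else stats::rpois(n, lambda)
}

#' Simulate small-RNA libraries over a planted annotation
#'
#' Tag species (sequence, position, strand) are drawn once per overlap
#' strand, with lengths biased to 21 nt and first nucleotides biased to
#' adenine. Per-library raw counts are Poisson around per-strand means: the
#' baseline mean is split FR:RR according to each pair's planted strand-bias
#' ratio, and multiplied by the planted heat fold in HT libraries.
#' Background tag species are scattered inside singleton genes. Counts use a
#' named random substream per library, so adding or dropping a library never
#' perturbs the others. Deterministic given the config seed.
#'
#' @param sim result of [simulate_annotation].
#' @param config the same [simulation_config].
#' @return list: `tags` (tag table with per-library count columns),
#'   `alignments`, `libraries`, and `tag_truth` (`sequence`,
#'   `origin` = pair id or `"background"`, `strand`).
#' @export
simulate_srna_libraries <- function(sim, config) {
  stopifnot(inherits(config, "simulation_config"))
  pairs <- sim$manifest$pairs
  libs <- config$libraries
  set.seed(derive_seed(config$seed, 2L))

  species <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    b <- pr$true_bias_ratio
    fr_mean <- 2 * config$per_strand_mean * b / (1 + b)
    rr_mean <- 2 * config$per_strand_mean / (1 + b)
    for (strand in c("+", "-")) {
      n_sp <- 1L + stats::rpois(1, 2)
      sp <- sample_tag_species(n_sp, pr$overlap_start, pr$overlap_end)
      sp$chrom <- pr$chrom
      sp$strand <- strand
      sp$origin <- pr$pair_id
      sp$lambda <- (if (strand == "+") fr_mean else rr_mean) / n_sp
      sp$heat_fold <- pr$true_heat_fold
      species[[length(species) + 1L]] <- sp
    }
  }
  # background species inside singleton genes
  tr <- sim$genes$transcripts
  singles <- tr[!tr$gene_id %in% c(pairs$gene_plus, pairs$gene_minus), ,
                drop = FALSE]
  for (i in seq_len(nrow(singles))) {
    g <- singles[i, ]
    n_bg <- stats::rpois(1, config$background_tag_rate)
    if (n_bg == 0) next
    sp <- sample_tag_species(n_bg, g$start, g$end)
    sp$chrom <- g$chrom
    sp$strand <- g$strand
    sp$origin <- "background"
    sp$lambda <- 5
    sp$heat_fold <- 1
    species[[length(species) + 1L]] <- sp
  }
  sp <- do.call(rbind, species)
  if (is.null(sp) || nrow(sp) == 0) stop("no tag species generated")

  counts <- matrix(0, nrow(sp), nrow(libs), dimnames = list(NULL, libs$name))
  for (k in seq_len(nrow(libs))) {
    set.seed(derive_seed(config$seed, 100L + k))
    lam <- sp$lambda * if (libs$condition[k] == "HT") sp$heat_fold else 1
    counts[, k] <- rcount(nrow(sp), lam, config$overdispersion)
  }

  # collapse rare sequence collisions: counts sum, all alignments kept
  agg <- stats::aggregate(counts, by = list(sequence = sp$sequence), FUN = sum)
  tags <- tag_table(agg$sequence, agg[, libs$name, drop = FALSE])
  alignments <- data.frame(sequence = sp$sequence, chrom = sp$chrom,
                           start = sp$start, end = sp$end, strand = sp$strand,
                           mismatches = 0L, stringsAsFactors = FALSE)
  alignments <- alignments[!duplicated(alignments), , drop = FALSE]
  rownames(alignments) <- NULL
  tag_truth <- unique(data.frame(sequence = sp$sequence, origin = sp$origin,
                                 strand = sp$strand, stringsAsFactors = FALSE))
  list(tags = tags, alignments = alignments, libraries = libs,
       tag_truth = tag_truth)
}

#' Write a complete synthetic data set to a directory
#'
#' Emits `genes.gff3`, `premirna.gff3` (when present), `tags.tsv`,
#' `alignments.tsv`, `libraries.tsv`, `manifest.json` and `config.json`.
#'
#' @param sim result of [simulate_annotation].
#' @param srna result of [simulate_srna_libraries] (or `NULL` to write the
#'   annotation only).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, srna, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$genes, file.path(dir, "genes.gff3"), "gff3")
  if (!is.null(sim$premirnas))
    write_annotation(sim$premirnas, file.path(dir, "premirna.gff3"), "gff3")
  manifest <- sim$manifest
  if (!is.null(srna)) {
    write.table(srna$tags, file.path(dir, "tags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(srna$alignments, file.path(dir, "alignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(srna$libraries, file.path(dir, "libraries.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$tag_truth <- srna$tag_truth
  }
  cfg <- manifest$config
  cfg$libraries <- NULL
  jsonlite::write_json(manifest["pairs"], file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
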