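# Variety-level summary tables (orientation counts, nat-siRNA-producing
# fractions, strand-biased counts) with set algebra across pair sets.

#' Round half away from zero
#'
#' `round()` in R rounds half to even; summary percentages here use
#' round-half-up to `digits` decimals, the convention of the tables this
#' package reproduces.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a producing count with its percentage
#'
#' Renders `"N (P%)"` with the percentage = producing/total * 100 rounded
#' half-up to two decimals (`"0 (0.00%)"` when total is 0).
#'
#' @param producing,total non-negative counts.
#' @return character vector.
#' @export
format_producing <- function(producing, total) {
  pct <- ifelse(total > 0, round_half_up(producing / total * 100, 2), 0)
  sprintf("%d (%.2f%%)", as.integer(producing), pct)
}

#' Build the per-variety pair summary table
#'
#' For two pair sets called against the same reference, computes per-set,
#' shared, per-set-specific and union rows with orientation counts, the
#' nat-siRNA-producing count (with percentage of the row total) and the
#' strand-biased count.
#'
#' @param pair_sets named list of exactly two pair data.frames (from
#'   [find_pairs]).
#' @param producing_ids character vector of pair ids that produce
#'   nat-siRNAs.
#' @param biased_ids character vector of pair ids called strand biased.
#' @return data.frame with rows `<set1>`, `<set2>`, `Shared`,
#'   `Specific in <set1>`, `Specific in <set2>`, `Union`; columns
#'   `convergent`, `divergent`, `enclosed`, `total`, `producing`
#'   (formatted `"N (P%)"`), `strand_biased`.
#' @export
build_summary <- function(pair_sets, producing_ids = character(),
                          biased_ids = character()) {
  stopifnot(length(pair_sets) == 2, !is.null(names(pair_sets)))
  uni <- pair_set_union(pair_sets)  # errors on orientation conflicts
  n1 <- names(pair_sets)[1]; n2 <- names(pair_sets)[2]
  in1 <- uni[[paste0("in_", n1)]]; in2 <- uni[[paste0("in_", n2)]]
  subsets <- list(in1, in2, in1 & in2, in1 & !in2, in2 & !in1,
                  rep(TRUE, nrow(uni)))
  names(subsets) <- c(n1, n2, "Shared", paste("Specific in", n1),
                      paste("Specific in", n2), "Union")
  rows <- lapply(subsets, function(sel) {
    p <- uni[sel, , drop = FALSE]
    ori <- table(factor(p$orientation,
                        levels = c("convergent", "divergent", "enclosed")))
    total <- nrow(p)
    producing <- sum(p$pair_id %in% producing_ids)
    data.frame(convergent = as.integer(ori[["convergent"]]),
               divergent = as.integer(ori[["divergent"]]),
               enclosed = as.integer(ori[["enclosed"]]),
               total = total,
               producing = format_producing(producing, total),
               strand_biased = sum(p$pair_id %in% biased_ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(set = names(subsets), out)
  rownames(out) <- NULL
  out
}
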