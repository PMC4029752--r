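# Audic-Claverie count-contrast test and the two decision procedures built
# on it: strand-bias calling and replicate-concordant condition response.

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.finite(m), m + log1p(exp(pmin(a, b) - m)), m)
}

ac_log_point <- function(x, y, n1, n2) {
  logr <- log(n2) - log(n1)
  y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(n2 / n1)
}

#' Conditional point probability for a count contrast
#'
#' Probability of observing `y` reads of a tag in a library of total size
#' `N2` given `x` reads in a library of total size `N1`, under Poisson
#' sampling of the same underlying abundance:
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1 + N2/N1)^{-(x+y+1)}}
#' Evaluated in log space (log-gamma) for numerical stability at large
#' counts. This is the negative-binomial mass with size `x + 1` and success
#' probability `N1/(N1+N2)`.
#'
#' @param x,y non-negative read counts (vectorized, recycled).
#' @param n1,n2 positive library total read counts.
#' @param log return the log probability.
#' @return probability vector; never exactly zero for finite counts (values
#'   below double range are floored at the smallest positive double).
#' @examples
#' ac_point_probability(0, 0, 1e7, 1e7)   # 0.5
#' ac_point_probability(5, 5, 1e7, 1e7)   # 252/2048
#' @export
ac_point_probability <- function(x, y, n1, n2, log = FALSE) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be > 0")
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  lp <- ac_log_point(x, y, n1, n2)
  if (log) lp else pmax(exp(lp), .Machine$double.xmin)
}

# Both tails for a single contrast; the smaller tail is computed by direct
# log-space summation, the larger via 1 - other + point (the point mass is
# included in both tails).
ac_tails_one <- function(x, y, n1, n2) {
  r <- n2 / n1
  logr <- log(n2) - log(n1)
  l1pr <- log1p(r)
  point <- exp(ac_log_point(x, y, n1, n2))
  mode_y <- r * (x + 1)
  if (y <= mode_y) {
    lower <- exp(logsumexp(ac_log_point(x, 0:y, n1, n2)))
    lower <- min(lower, 1)
    upper <- min(max(1 - lower + point, point), 1)
  } else {
    # sum the upper tail from k = y until the geometric remainder is negligible
    logt <- ac_log_point(x, y, n1, n2)
    logsum <- logt
    k <- y
    repeat {
      logt <- logt + logr + log(x + k + 1) - log(k + 1) - l1pr
      k <- k + 1
      logsum <- logaddexp(logsum, logt)
      q <- exp(logr - l1pr) * (x + k + 1) / (k + 1)
      if (q < 1 && logt - logsum < log(1e-17 * (1 - q))) break
      if (k - y > 1e7) break  # safety valve; never reached for sane inputs
    }
    upper <- min(exp(logsum), 1)
    lower <- min(max(1 - upper + point, point), 1)
  }
  c(lower = max(lower, .Machine$double.xmin),
    upper = max(upper, .Machine$double.xmin),
    point = max(point, .Machine$double.xmin))
}

#' Tail significance for a count contrast
#'
#' Tail construction over the conditional distribution
#' [ac_point_probability]: `lower` is the probability of `y` or fewer reads,
#' `upper` of `y` or more (the observed point mass is included in both,
#' giving a conservative test), and `two` doubles the smaller tail, capped
#' at 1.
#'
#' @inheritParams ac_point_probability
#' @param sided `"two"` (default), `"lower"` or `"upper"`.
#' @return p-value vector in (0, 1].
#' @export
ac_p_value <- function(x, y, n1, n2, sided = c("two", "lower", "upper")) {
  sided <- match.arg(sided)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be > 0")
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  # contrasts repeat heavily in genome-scale input; compute unique ones once
  key <- paste(x, y, n1, n2)
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) {
    t <- ac_tails_one(x[i], y[i], n1[i], n2[i])
    switch(sided,
           lower = t[["lower"]],
           upper = t[["upper"]],
           two = min(1, 2 * min(t[["lower"]], t[["upper"]])))
  }, 0)
  unname(pu[match(key, key[u])])
}

# FR/RR and HT/NT ratio conventions: INF when the denominator alone is zero,
# 0 when the numerator alone is zero, NA when both are.
contrast_ratio <- function(num, den) {
  ifelse(num == 0 & den == 0, NA_real_,
         ifelse(den == 0, Inf, num / den))
}

#' Call strand bias of nat-siRNA production
#'
#' Reads from a cis-NAT overlap are split into forward-strand (`FR`) and
#' reverse-strand (`RR`) totals. A pair is strand biased when the FR/RR
#' ratio is greater than `ratio_hi` or less than `ratio_lo` and the
#' count-contrast p-value is below `alpha`. Ratio conventions: `Inf` when
#' `RR = 0 < FR`, `0` when `FR = 0 < RR`, `NA` (never biased) when both are
#' zero. Both strands come from the same library, so equal library totals
#' are used in the test.
#'
#' @param FR,RR forward- and reverse-strand read totals (vectorized).
#' @param ratio_hi,ratio_lo bias thresholds (defaults 2 and 0.5).
#' @param alpha significance level (default 0.01).
#' @param pair_id optional pair identifiers carried into the result.
#' @return data.frame: `pair_id` (if given), `FR`, `RR`, `ratio`, `p_value`,
#'   `biased`.
#' @export
call_strand_bias <- function(FR, RR, ratio_hi = 2, ratio_lo = 0.5,
                             alpha = 0.01, pair_id = NULL) {
  if (any(FR < 0) || any(RR < 0)) stop("read totals must be >= 0")
  ratio <- contrast_ratio(FR, RR)
  # the FR/RR labeling is arbitrary, but the conditional tail is not
  # symmetric in (x, y); conditioning on the larger total makes the call
  # invariant under relabeling the strands
  p <- ac_p_value(pmax(FR, RR), pmin(FR, RR), 1, 1, sided = "two")
  biased <- !is.na(ratio) & (ratio > ratio_hi | ratio < ratio_lo) & p < alpha
  out <- data.frame(FR = FR, RR = RR, ratio = ratio, p_value = p,
                    biased = biased, stringsAsFactors = FALSE)
  if (!is.null(pair_id)) out <- cbind(pair_id = pair_id, out)
  out
}

#' Call condition-responsive nat-siRNA accumulation across two replicates
#'
#' Compares per-pair nat-siRNA totals between a treatment (e.g. high
#' temperature, HT) and a control (normal temperature, NT) in each of two
#' replicates. Ratios are computed on RP10M-normalized totals; the
#' count-contrast test uses the raw counts with the true library sizes. A
#' pair is called responsive when both replicate ratios exceed `fold` (up)
#' or both fall below `1/fold` (down) and both p-values are below `alpha`.
#'
#' @param nt1,ht1,nt2,ht2 per-pair raw read totals in the four libraries
#'   (vectorized).
#' @param libraries data.frame from [srna_libraries] containing conditions
#'   `"NT"` and `"HT"` with replicates 1 and 2 (the library sizes).
#' @param fold fold-change threshold (default 2).
#' @param alpha significance level (default 0.01).
#' @param pair_id optional pair identifiers.
#' @return data.frame: `ratio_rep1`, `p_rep1`, `ratio_rep2`, `p_rep2`,
#'   `direction` (`up`/`down`/`none`), `significant`.
#' @export
call_heat_response <- function(nt1, ht1, nt2, ht2, libraries,
                               fold = 2, alpha = 0.01, pair_id = NULL) {
  lib_total <- function(cond, rep) {
    i <- which(libraries$condition == cond & libraries$replicate == rep)
    if (length(i) != 1)
      stop("missing replicate: need exactly one library with condition '",
           cond, "' and replicate ", rep)
    libraries$total_reads[i]
  }
  N_nt1 <- lib_total("NT", 1); N_ht1 <- lib_total("HT", 1)
  N_nt2 <- lib_total("NT", 2); N_ht2 <- lib_total("HT", 2)

  ratio1 <- contrast_ratio(rp10m(ht1, N_ht1), rp10m(nt1, N_nt1))
  ratio2 <- contrast_ratio(rp10m(ht2, N_ht2), rp10m(nt2, N_nt2))
  p1 <- ac_p_value(nt1, ht1, N_nt1, N_ht1, sided = "two")
  p2 <- ac_p_value(nt2, ht2, N_nt2, N_ht2, sided = "two")

  up <- !is.na(ratio1) & !is.na(ratio2) & ratio1 > fold & ratio2 > fold
  down <- !is.na(ratio1) & !is.na(ratio2) & ratio1 < 1 / fold & ratio2 < 1 / fold
  direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  significant <- direction != "none" & p1 < alpha & p2 < alpha
  out <- data.frame(ratio_rep1 = ratio1, p_rep1 = p1,
                    ratio_rep2 = ratio2, p_rep2 = p2,
                    direction = direction, significant = significant,
                    stringsAsFactors = FALSE)
  if (!is.null(pair_id)) out <- cbind(pair_id = pair_id, out)
  out
}

#' Serialize ratio columns with the INF convention
#'
#' Infinite ratios print as the literal `INF`, zero as `0.00`, others with
#' two decimals; `NA` prints as `NA`.
#'
#' @param r numeric ratio vector.
#' @return character vector.
#' @export
format_ratio <- function(r) {
  ifelse(is.na(r), "NA", ifelse(is.infinite(r), "INF", sprintf("%.2f", r)))
}

#' Write strand-bias or condition-response calls as TSV
#'
#' Ratio columns are serialized through [format_ratio] (`INF` literal).
#'
#' @param calls data.frame from [call_strand_bias] or [call_heat_response].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  for (col in intersect(c("ratio", "ratio_rep1", "ratio_rep2"), names(out)))
    out[[col]] <- format_ratio(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
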