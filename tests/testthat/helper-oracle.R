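# Independent oracles: an exact-rational evaluation of the count-contrast
# formula (python stdlib fractions; no floating point until the final
# conversion) and a vectorized all-pairs geometry classifier that shares no
# code with the package implementation.

# Exact p(y|x), lower and upper tails for all 0 <= x <= xmax, 0 <= y <= ymax
# and each library-size ratio N2/N1 = p/q. Returns a data.frame.
ac_oracle_grid <- function(xmax, ymax, ratios) {
  script <- c(
    "import sys",
    "import math",
    "from fractions import Fraction",
    "argv = [int(a) for a in sys.argv[1:]]",
    "xmax, ymax = argv[0], argv[1]",
    "ratios = list(zip(argv[2::2], argv[3::2]))",
    "rows = []",
    "for (p, q) in ratios:",
    "    for x in range(xmax + 1):",
    "        # point(0) = q^(x+1) / (p+q)^(x+1); recurrence over y",
    "        pt = Fraction(q ** (x + 1), (p + q) ** (x + 1))",
    "        lo = pt",
    "        for y in range(ymax + 1):",
    "            up = 1 - lo + pt",
    "            rows.append('%d %d %d %d %.17e %.17e %.17e'",
    "                        % (x, y, p, q, float(pt), float(lo), float(up)))",
    "            pt = pt * p * (x + y + 1) / ((y + 1) * (p + q))",
    "            lo = lo + pt",
    "sys.stdout.write('\\n'.join(rows))")
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", c(py, xmax, ymax, unlist(ratios)), stdout = TRUE)
  read.table(text = out,
             col.names = c("x", "y", "p", "q", "point", "lower", "upper"))
}

# All-pairs antisense finder + orientation classifier. Orientation is
# decided by an independent rule: enclosed iff the overlap equals the
# shorter span; convergent iff the plus member's 3' end falls strictly
# inside the minus span; divergent otherwise.
brute_force_pairs <- function(ann, min_overlap, max_overlap) {
  tr <- ann$transcripts[ann$transcripts$biotype == "coding", , drop = FALSE]
  n <- nrow(tr)
  if (n < 2)
    return(data.frame(pair_id = character(), orientation = character()))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, "row"]; j <- idx[, "col"]
  keep <- tr$chrom[i] == tr$chrom[j] & tr$strand[i] != tr$strand[j]
  i <- i[keep]; j <- j[keep]
  ov <- pmin(tr$end[i], tr$end[j]) - pmax(tr$start[i], tr$start[j])
  keep <- ov >= min_overlap & ov <= max_overlap
  i <- i[keep]; j <- j[keep]; ov <- ov[keep]
  pl <- ifelse(tr$strand[i] == "+", i, j)
  mi <- ifelse(tr$strand[i] == "+", j, i)
  shorter <- pmin(tr$end[pl] - tr$start[pl], tr$end[mi] - tr$start[mi])
  ori <- as.character(ifelse(ov == shorter, "enclosed",
                ifelse(tr$end[pl] > tr$start[mi] & tr$end[pl] < tr$end[mi],
                       "convergent", "divergent")))
  out <- data.frame(pair_id = pair_id(tr$gene_id[pl], tr$gene_id[mi]),
                    orientation = ori, stringsAsFactors = FALSE)
  out[order(out$pair_id), , drop = FALSE]
}
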