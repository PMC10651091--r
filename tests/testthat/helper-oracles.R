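# Brute-force oracles and small fixture builders used across the suite.
# Oracles deliberately use naive quadratic loops, independent of the
# interval machinery in the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_len = 500) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + 1 + floor(runif(n, 0, max_len)),
             stringsAsFactors = FALSE)
}

bf_overlaps1 <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# whole-region drop: keep rows of x overlapping no row of mask
bf_subtract <- function(x, mask) {
  keep <- vapply(seq_len(nrow(x)), function(i) {
    for (j in seq_len(nrow(mask)))
      if (bf_overlaps1(x[i, ], mask[j, ])) return(FALSE)
    TRUE
  }, logical(1))
  x[keep, , drop = FALSE]
}

# linear scan for the nearest genes entirely left / right of pos
bf_flanking <- function(genes, chrom, pos) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  left <- g[g$end <= pos, , drop = FALSE]
  right <- g[g$start >= pos, , drop = FALSE]
  up <- if (nrow(left)) {
    best <- max(left$end)
    cand <- left[left$end == best, , drop = FALSE]
    cand$gene_id[order(cand$gene_id)][1]
  } else NA_character_
  dn <- if (nrow(right)) {
    best <- min(right$start)
    cand <- right[right$start == best, , drop = FALSE]
    cand$gene_id[order(cand$gene_id)][1]
  } else NA_character_
  c(up = up, down = dn)
}

bf_window_counts <- function(frags, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(frags$chrom == w$chrom & frags$start < w$end & w$start < frags$end)
  }, numeric(1))
}

# textbook step-up Benjamini-Hochberg
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# G statistic via the mutual-information identity G = 2 N sum p log(p/(pr pc))
bf_g <- function(a, b, ta, tb) {
  o <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
  n <- sum(o)
  p <- o / n
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log(p / outer(pr, pc))
  2 * n * sum(terms[p > 0])
}

# non-overlapping toy annotation on one chromosome
toy_annotation <- function(starts = c(1000, 5000, 9000), len = 1000,
                           chrom_len = 20000, strand = "+") {
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                      chrom = "chr1", start = starts, end = starts + len,
                      strand = rep(strand, length.out = length(starts)),
                      stringsAsFactors = FALSE)
  genome_annotation(genes, c(chr1 = chrom_len))
}

# enhancer table with prescribed per-category row counts, flags consistent
# with the default category map
table_from_category_counts <- function(counts) {
  stopifnot(length(counts) == 7)
  inv <- stats::setNames(as.integer(names(default_category_map())),
                         default_category_map())
  category <- rep(1:7, counts)
  mask <- inv[as.character(category)]
  data.frame(chrom = "chr1",
             start = seq_along(category) * 1000,
             end = seq_along(category) * 1000 + 500,
             has_t_nmp = bitwAnd(mask, 1L) > 0,
             has_t_notop = bitwAnd(mask, 2L) > 0,
             has_foxa2 = bitwAnd(mask, 4L) > 0,
             mask = as.integer(mask), category = category,
             anchor = seq_along(category) * 1000 + 250,
             stringsAsFactors = FALSE)
}
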