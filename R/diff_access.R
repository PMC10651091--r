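#' Sliding-window fragment counts for two conditions
#'
#' Tiles each chromosome with windows of width \code{window} every
#' \code{step} bp and counts, per window, the fragments of each condition
#' overlapping it (a fragment counts in every window it touches).
#'
#' @param fragset_a,fragset_b [fragment_set()]s for the two conditions.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param window Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 100).
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{count_a}, \code{count_b}.
#' @export
window_counts <- function(fragset_a, fragset_b, chrom_sizes,
                          window = 1000, step = 100) {
  stopifnot(inherits(fragset_a, "fragment_set"),
            inherits(fragset_b, "fragment_set"),
            window >= step, step >= 1)
  tiles <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  }))
  count_in <- function(fs) {
    if (!nrow(fs$fragments)) return(integer(nrow(tiles)))
    lev <- union(unique(tiles$chrom), unique(fs$fragments$chrom))
    GenomicRanges::countOverlaps(.as_granges(tiles, lev),
                                 .as_granges(fs$fragments, lev))
  }
  tiles$count_a <- count_in(fragset_a)
  tiles$count_b <- count_in(fragset_b)
  tiles
}

#' G-test on a 2x2 fragment-count table
#'
#' Likelihood-ratio (G) test of whether a window's fragment count differs
#' between two libraries beyond library-size expectation. The table is
#' \code{{count_a, total_a - count_a; count_b, total_b - count_b}};
#' G = 2 * sum(O * ln(O / E)) over the four cells with expected values from
#' the margins (0 * ln 0 = 0, no continuity correction); the p-value is the
#' upper chi-square tail with 1 df. Vectorised over counts.
#'
#' @param count_a,count_b Window counts in conditions A and B.
#' @param total_a,total_b Library sizes (total fragments) of A and B.
#' @return List with numeric vectors \code{g_stat} and \code{p_value}.
#' @export
g_test <- function(count_a, count_b, total_a, total_b) {
  stopifnot(total_a > 0, total_b > 0,
            all(count_a >= 0), all(count_b >= 0),
            all(count_a <= total_a), all(count_b <= total_b))
  count_a <- as.numeric(count_a); count_b <- as.numeric(count_b)
  total_a <- as.numeric(total_a); total_b <- as.numeric(total_b)
  o <- cbind(count_a, total_a - count_a, count_b, total_b - count_b)
  n <- total_a + total_b
  colt_in <- count_a + count_b
  e <- cbind(total_a * colt_in, total_a * (n - colt_in),
             total_b * colt_in, total_b * (n - colt_in)) / n
  term <- o * log(o / e)
  term[o == 0] <- 0  # 0 * ln 0 = 0
  g <- 2 * rowSums(term)
  g <- pmax(g, 0)  # guard tiny negative rounding
  list(g_stat = g, p_value = stats::pchisq(g, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; input order is preserved.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Detect differentially accessible regions
#'
#' Per-window G-test against library-size expectation, Benjamini-Hochberg
#' adjustment across all tested windows, then significance and fold filters,
#' and finally merging of nearby significant windows of the same direction
#' into regions. The normalised fold change per window is
#' \code{((count_a + 0.5) / total_a) / ((count_b + 0.5) / total_b)} (the 0.5
#' pseudocount keeps zero-count windows finite). A merged region carries the
#' union span, the best (smallest) q-value, the largest |log2 fold| and the
#' largest G among its windows.
#'
#' @param windows Data frame from [window_counts()].
#' @param total_a,total_b Library sizes of the two conditions.
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param min_fold Minimum normalised fold change, as a ratio >= 1
#'   (default 2).
#' @param merge_gap Significant same-direction windows whose gap is smaller
#'   than this many bp are merged (default: one window step, inferred from
#'   the spacing of \code{windows}).
#' @return Data frame of class \code{"differential_regions"} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{direction}
#'   (\code{"A_up"}/\code{"B_up"}), \code{log2_fold}, \code{g_stat},
#'   \code{p_value}, \code{q_value}.
#' @export
detect_differential <- function(windows, total_a, total_b,
                                alpha = 0.05, min_fold = 2,
                                merge_gap = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_fold >= 1)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), log2_fold = numeric(),
                      g_stat = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("differential_regions", "data.frame")
  if (!nrow(windows)) return(empty)
  if (is.null(merge_gap)) {
    steps <- diff(windows$start[windows$chrom == windows$chrom[1]])
    merge_gap <- if (length(steps)) min(steps) else 100
  }
  gt <- g_test(windows$count_a, windows$count_b, total_a, total_b)
  q <- bh_adjust(gt$p_value)
  fold <- ((windows$count_a + 0.5) / total_a) / ((windows$count_b + 0.5) / total_b)
  lfc <- log2(fold)
  sig <- q <= alpha & pmax(fold, 1 / fold) >= min_fold
  if (!any(sig)) return(empty)
  w <- windows[sig, , drop = FALSE]
  w$direction <- ifelse(lfc[sig] > 0, "A_up", "B_up")
  w$log2_fold <- lfc[sig]
  w$g_stat <- gt$g_stat[sig]
  w$p_value <- gt$p_value[sig]
  w$q_value <- q[sig]
  # merge same-direction windows separated by < merge_gap, per chromosome
  out <- list()
  for (key in unique(paste(w$chrom, w$direction))) {
    ww <- w[paste(w$chrom, w$direction) == key, , drop = FALSE]
    ww <- ww[order(ww$start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(ww$start[-1] - cummax(ww$end)[-nrow(ww)] >= merge_gap)))
    for (g in unique(grp)) {
      m <- ww[grp == g, , drop = FALSE]
      i_best <- which.max(abs(m$log2_fold))
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        direction = m$direction[1],
        log2_fold = m$log2_fold[i_best],
        g_stat = max(m$g_stat),
        p_value = min(m$p_value),
        q_value = min(m$q_value), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("differential_regions", "data.frame")
  res
}

#' Remove differential regions overlapping promoters
#'
#' Whole-region drop of every differential region touching a promoter
#' interval (\code{[tss - flank, tss + flank]}); the filter that restricts
#' differential accessibility calls to promoter-distal, enhancer-like
#' regions.
#'
#' @param diff_regions A \code{"differential_regions"} data frame.
#' @param annotation A [genome_annotation()].
#' @param flank Promoter flank in bp (default 5000).
#' @return The filtered \code{"differential_regions"} data frame.
#' @export
exclude_promoters <- function(diff_regions, annotation, flank = 5000) {
  promoters <- promoter_regions(annotation, flank)
  out <- subtract_overlapping(diff_regions, promoters)
  class(out) <- c("differential_regions", "data.frame")
  out
}

#' Write differential regions as BED6+
#'
#' Name column is the direction, score is \code{-10 * log10(q)} (capped at
#' 1000), and four extra columns carry \code{log2_fold}, \code{g_stat},
#' \code{p_value}, \code{q_value}.
#'
#' @param diff_regions A \code{"differential_regions"} data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_diff_bed <- function(diff_regions, path) {
  x <- as.data.frame(diff_regions)
  x$name <- x$direction
  x$score <- round(pmin(1000, -10 * log10(pmax(x$q_value, 1e-100))), 1)
  x$strand <- rep("*", nrow(x))
  write_bed(x, path, extra = c("log2_fold", "g_stat", "p_value", "q_value"))
}
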