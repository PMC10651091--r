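#' Fragment sets
#'
#' A fragment set holds deduplicable paired-end-derived fragments: a data
#' frame of \code{chrom}, \code{start}, \code{end} sorted by (chrom, start,
#' end), with the library size (total fragment count) tracked alongside.
#'
#' @param fragments Data frame with \code{chrom}, \code{start}, \code{end}.
#' @return An object of class \code{"fragment_set"}.
#' @export
fragment_set <- function(fragments) {
  validate_regions(fragments)
  fragments <- fragments[order(fragments$chrom, fragments$start, fragments$end),
                         c("chrom", "start", "end"), drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(fragments = fragments, library_size = nrow(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments on %d chromosomes\n",
              x$library_size, length(unique(x$fragments$chrom))))
  invisible(x)
}

#' Reconstruct fragments from mate coordinates
#'
#' Each properly paired read pair is turned into one fragment spanning the
#' outermost mate coordinates, \code{[min(pos_a, pos_b), max(pos_a, pos_b))}.
#' Pairs longer than \code{max_insert} are dropped; pairs whose mates map to
#' different chromosomes are skipped. Both counts are recorded as attributes
#' \code{n_dropped_long} and \code{n_dropped_transchrom} on the result.
#'
#' @param pairs Data frame with columns \code{chrom}, \code{pos_a},
#'   \code{pos_b} (and optionally \code{chrom_b} for the second mate).
#' @param max_insert Maximum fragment length in bp (default 2000, the usual
#'   upper bound set when mapping ATAC libraries).
#' @return A [fragment_set()].
#' @export
fragments_from_pairs <- function(pairs, max_insert = 2000) {
  stopifnot(all(c("chrom", "pos_a", "pos_b") %in% names(pairs)))
  n_trans <- 0L
  if ("chrom_b" %in% names(pairs)) {
    trans <- pairs$chrom != pairs$chrom_b
    n_trans <- sum(trans)
    pairs <- pairs[!trans, , drop = FALSE]
  }
  start <- pmin(pairs$pos_a, pairs$pos_b)
  end <- pmax(pairs$pos_a, pairs$pos_b)
  long <- (end - start) > max_insert
  fs <- fragment_set(data.frame(chrom = pairs$chrom[!long],
                                start = start[!long], end = end[!long],
                                stringsAsFactors = FALSE))
  attr(fs, "n_dropped_long") <- sum(long)
  attr(fs, "n_dropped_transchrom") <- n_trans
  fs
}

#' Read a BEDPE file into mate pair records
#'
#' Uses the outermost coordinates of the two blocks as the mate positions.
#'
#' @param path BEDPE path (six tab-separated columns minimum).
#' @return Data frame with \code{chrom}, \code{pos_a}, \code{pos_b},
#'   \code{chrom_b}, suitable for [fragments_from_pairs()].
#' @export
read_bedpe <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) .stopf("BEDPE needs >= 6 columns: %s", path)
  data.frame(chrom = tab[[1]],
             pos_a = pmin(tab[[2]], tab[[5]]),
             pos_b = pmax(tab[[3]], tab[[6]]),
             chrom_b = tab[[4]], stringsAsFactors = FALSE)
}

#' Remove duplicate fragments
#'
#' Collapses exact (chrom, start, end) duplicates to a single fragment, the
#' standard PCR-duplicate filter for fragment-level ATAC data. Idempotent.
#'
#' @param fragset A [fragment_set()].
#' @return A deduplicated [fragment_set()].
#' @export
deduplicate_fragments <- function(fragset) {
  stopifnot(inherits(fragset, "fragment_set"))
  fragment_set(unique(fragset$fragments))
}

#' Drop fragments on given chromosomes
#'
#' Typically used to remove chrY (repetitive) and chrM (non-informative)
#' fragments from ATAC libraries.
#'
#' @param fragset A [fragment_set()].
#' @param names Character vector of chromosome names to drop.
#' @return A filtered [fragment_set()].
#' @export
drop_chromosomes <- function(fragset, names = c("chrY", "chrM")) {
  stopifnot(inherits(fragset, "fragment_set"))
  keep <- !(fragset$fragments$chrom %in% names)
  fragment_set(fragset$fragments[keep, , drop = FALSE])
}

#' Binned fragment coverage
#'
#' Each bin counts the number of fragments overlapping it (whole-fragment
#' overlap, not per-base pileup), matching fragment-level coverage of
#' elongated reads.
#'
#' @param fragset A [fragment_set()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 10).
#' @return An object of class \code{"coverage_track"}: list with
#'   \code{bins} (named list of per-chromosome count vectors),
#'   \code{bin_size} and \code{chrom_sizes}.
#' @export
coverage_track <- function(fragset, chrom_sizes, bin_size = 10) {
  stopifnot(inherits(fragset, "fragment_set"), bin_size >= 1)
  bins <- lapply(names(chrom_sizes), function(ch) {
    n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_size))
    f <- fragset$fragments[fragset$fragments$chrom == ch, , drop = FALSE]
    v <- integer(n)
    if (nrow(f)) {
      first <- pmax(0L, as.integer(f$start %/% bin_size)) + 1L
      last <- pmin(n - 1L, as.integer((f$end - 1) %/% bin_size)) + 1L
      ok <- first <= n & last >= 1L
      first <- first[ok]; last <- last[ok]
      # difference-array increments, then cumulative sum
      d <- integer(n + 1L)
      inc <- tabulate(first, nbins = n + 1L)
      dec <- tabulate(last + 1L, nbins = n + 1L)
      v <- cumsum(inc - dec)[seq_len(n)]
    }
    v
  })
  names(bins) <- names(chrom_sizes)
  structure(list(bins = bins, bin_size = bin_size, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, bin %d bp, max %g\n",
              length(x$bins), x$bin_size, max(c(0, unlist(x$bins)))))
  invisible(x)
}

#' Single-bp summit of a peak
#'
#' Returns the position (center of the maximal coverage bin, at bin
#' resolution) of the highest signal within the peak; ties are broken by the
#' leftmost maximal bin. A peak with zero coverage returns its midpoint and
#' carries attribute \code{low_confidence = TRUE}.
#'
#' @param peak One-row interval data frame (or list with chrom/start/end).
#' @param track A [coverage_track()].
#' @return Numeric base position with logical attribute
#'   \code{low_confidence}.
#' @export
summit <- function(peak, track) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  v <- track$bins[[peak$chrom]]
  if (is.null(v)) .stopf("chromosome %s not in track", peak$chrom)
  first <- as.integer(peak$start %/% bs) + 1L
  last <- as.integer((peak$end - 1) %/% bs) + 1L
  first <- max(1L, first); last <- min(length(v), last)
  if (first > last) .stopf("peak outside track bounds")
  w <- v[first:last]
  if (max(w) == 0) {
    pos <- floor((peak$start + peak$end) / 2)
    attr(pos, "low_confidence") <- TRUE
    return(pos)
  }
  b <- first + which.max(w) - 1L  # which.max takes the leftmost maximum
  pos <- (b - 1L) * bs + bs %/% 2
  attr(pos, "low_confidence") <- FALSE
  pos
}

#' Anchor-centered signal matrix
#'
#' Row i holds the coverage in \code{[anchor_i - flank, anchor_i + flank)}
#' binned at \code{bin} bp; the value of each output bin is the track value
#' at the bin center. Anchors near chromosome edges are zero-padded so the
#' matrix stays rectangular.
#'
#' @param anchors Data frame with \code{chrom} and \code{pos} (and optional
#'   \code{id} used as rownames).
#' @param track A [coverage_track()].
#' @param flank Half-window in bp.
#' @param bin Output bin width in bp; must divide \code{flank}.
#' @return Numeric matrix, one row per anchor, \code{2 * flank / bin}
#'   columns.
#' @export
signal_matrix <- function(anchors, track, flank = 2000, bin = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(bin)) bin <- track$bin_size
  if (flank %% bin != 0) .stopf("flank must be divisible by bin")
  ncol <- as.integer(2 * flank / bin)
  centers_off <- seq(-flank, flank - bin, by = bin) + bin / 2
  m <- matrix(0, nrow = nrow(anchors), ncol = ncol)
  for (i in seq_len(nrow(anchors))) {
    v <- track$bins[[anchors$chrom[i]]]
    if (is.null(v)) next
    pos <- anchors$pos[i] + centers_off
    b <- as.integer(pos %/% track$bin_size) + 1L
    ok <- b >= 1L & b <= length(v)
    m[i, ok] <- v[b[ok]]
  }
  rownames(m) <- if (!is.null(anchors$id)) anchors$id else NULL
  attr(m, "flank") <- flank
  attr(m, "bin") <- bin
  m
}

#' Average signal profile
#'
#' Column means of a signal matrix: the per-bin mean signal across anchors.
#'
#' @param m A matrix from [signal_matrix()].
#' @return Numeric vector of per-bin means.
#' @export
average_profile <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L) .stopf("empty signal matrix")
  colMeans(m)
}

#' Order anchors for heatmap display
#'
#' Two modes: \code{"by_pvalue"} sorts ascending on a \code{p_value} column;
#' \code{"by_category_then_random"} groups anchors by their \code{category}
#' column and shuffles within each category, reproducibly under \code{seed}.
#'
#' @param anchors Data frame of anchors with the column the mode requires.
#' @param mode Ordering mode.
#' @param seed Integer seed for the within-category shuffle.
#' @return The reordered anchor data frame.
#' @export
order_anchors <- function(anchors, mode = c("by_pvalue", "by_category_then_random"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "by_pvalue") {
    if (is.null(anchors$p_value)) .stopf("mode by_pvalue needs a p_value column")
    out <- anchors[order(anchors$p_value), , drop = FALSE]
  } else {
    if (is.null(anchors$category)) .stopf("mode by_category_then_random needs a category column")
    set.seed(seed)
    idx <- unlist(lapply(sort(unique(anchors$category)), function(cat) {
      i <- which(anchors$category == cat)
      if (length(i) > 1L) sample(i) else i
    }))
    out <- anchors[idx, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a coverage track as fixedStep wiggle
#'
#' One \code{fixedStep} block per non-empty chromosome; wiggle positions are
#' 1-based, step and span equal the bin size. Chromosomes with all-zero
#' coverage are omitted.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_wiggle <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$bins)) {
    v <- track$bins[[ch]]
    if (!length(v) || all(v == 0)) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, track$bin_size, track$bin_size), con)
    writeLines(format(v, scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}

#' Read a fixedStep wiggle file back into a coverage track
#'
#' Inverse of [write_wiggle()]; chromosomes absent from the file get all-zero
#' bins.
#'
#' @param path Wiggle path.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A [coverage_track()].
#' @export
read_wiggle <- function(path, chrom_sizes) {
  lines <- readLines(path)
  heads <- grep("^fixedStep", lines)
  bin_size <- NULL
  vals <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    h <- lines[heads[i]]
    ch <- sub(".*chrom=([^ ]+).*", "\\1", h)
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", h))
    if (is.null(bin_size)) bin_size <- step
    if (step != bin_size) .stopf("mixed step sizes in %s", path)
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    vals[[ch]] <- as.numeric(body)
  }
  if (is.null(bin_size)) bin_size <- 10L
  bins <- lapply(names(chrom_sizes), function(ch) {
    n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_size))
    v <- numeric(n)
    if (!is.null(vals[[ch]])) v[seq_along(vals[[ch]])] <- vals[[ch]]
    v
  })
  names(bins) <- names(chrom_sizes)
  structure(list(bins = bins, bin_size = bin_size, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}
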