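# Combinatorial categorisation of three TF peak sets and intersection of
# their single-bp summits with differentially accessible regions.
#
# Flag triples are encoded internally as a bitmask: 1 = T_NMP, 2 = T_NotoP,
# 4 = Foxa2.

.SOURCES <- c("T_NMP", "T_NotoP", "Foxa2")
.SOURCE_BIT <- c(T_NMP = 1L, T_NotoP = 2L, Foxa2 = 4L)

#' Default binding-category map
#'
#' Maps each of the seven non-empty combinations of the three peak sources
#' (T in the progenitor state, T in the target state, Foxa2 in the target
#' state) to a category id 1-7. The anchored assignments are: category 3 =
#' all three sources, category 5 = both target-state factors (T_NotoP +
#' Foxa2), category 7 = Foxa2 alone, category 2 = T_NMP alone. The remaining
#' assignments (1 = T_NMP + Foxa2, 4 = T_NMP + T_NotoP, 6 = T_NotoP alone)
#' are a documented convention and can be overridden.
#'
#' @return Named integer vector: names are flag bitmasks ("1".."7",
#'   1 = T_NMP, 2 = T_NotoP, 4 = Foxa2), values are category ids.
#' @export
default_category_map <- function() {
  c(`1` = 2L,  # T_NMP only
    `2` = 6L,  # T_NotoP only
    `4` = 7L,  # Foxa2 only
    `3` = 4L,  # T_NMP + T_NotoP
    `5` = 1L,  # T_NMP + Foxa2
    `6` = 5L,  # T_NotoP + Foxa2
    `7` = 3L)  # all three
}

.check_category_map <- function(map) {
  if (!setequal(names(map), as.character(1:7)) ||
      !setequal(as.integer(map), 1:7))
    .stopf("category map must be a bijection between flag masks 1..7 and categories 1..7")
  map
}

#' Read a narrowPeak file
#'
#' Standard ENCODE narrowPeak (BED6+4). When the 10th column (summit offset
#' from peak start) is present and non-negative, it supplies the absolute
#' summit position; otherwise the summit is \code{NA} and can be recomputed
#' from coverage later.
#'
#' @param path narrowPeak path.
#' @param source Optional source label attached to every peak.
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{summit}, \code{source}.
#' @export
read_narrowpeak <- function(path, source = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) .stopf("narrowPeak needs >= 3 columns: %s", path)
  df <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                   stringsAsFactors = FALSE)
  df$name <- if (ncol(tab) >= 4L) tab[[4]] else NA_character_
  df$score <- if (ncol(tab) >= 5L) as.numeric(tab[[5]]) else 0
  df$summit <- if (ncol(tab) >= 10L) {
    off <- as.numeric(tab[[10]])
    ifelse(is.na(off) | off < 0, NA_real_, df$start + off)
  } else NA_real_
  df$source <- source
  validate_regions(df)
  bad <- which(!is.na(df$summit) & (df$summit < df$start | df$summit >= df$end))
  if (length(bad)) .stopf("summit outside its peak at row %d of %s", bad[1], path)
  df
}

#' Remove blacklisted peaks
#'
#' Drops every peak overlapping a blacklist interval (regions with known
#' mapping artifacts).
#'
#' @param peaks Peak data frame.
#' @param blacklist Interval data frame of blacklist regions.
#' @return Filtered peak data frame.
#' @export
remove_blacklisted <- function(peaks, blacklist) {
  subtract_overlapping(peaks, blacklist)
}

#' Cluster three peak sets into combinatorial binding profiles
#'
#' Peaks from the three sources are clustered by transitive overlap; each
#' cluster becomes one binding profile whose region is the union span of its
#' peaks, whose flags record which sources contribute, and whose category is
#' looked up in the category map.
#'
#' @param t_nmp,t_notop,foxa2 Peak data frames (see [read_narrowpeak()]),
#'   already blacklist-filtered.
#' @param category_map Named integer vector, see [default_category_map()].
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{has_t_nmp}, \code{has_t_notop}, \code{has_foxa2}, \code{mask},
#'   \code{category} and a list-column-free \code{cluster} id; the
#'   contributing peaks are returned in attribute \code{"members"} (a data
#'   frame with a \code{cluster} column).
#' @export
combinatorial_profiles <- function(t_nmp, t_notop, foxa2,
                                   category_map = default_category_map()) {
  .check_category_map(category_map)
  sets <- list(T_NMP = t_nmp, T_NotoP = t_notop, Foxa2 = foxa2)
  all <- do.call(rbind, lapply(names(sets), function(s) {
    p <- sets[[s]]
    if (is.null(p) || !nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               score = if (!is.null(p$score)) p$score else 0,
               summit = if (!is.null(p$summit)) p$summit else NA_real_,
               source = s, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      has_t_nmp = logical(), has_t_notop = logical(),
                      has_foxa2 = logical(), mask = integer(),
                      category = integer(), cluster = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(all) || !nrow(all)) return(empty)
  gr <- .as_granges(all)
  # transitive-overlap clusters; min.gapwidth = 0 keeps abutting
  # (half-open non-overlapping) peaks in separate clusters
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  all$cluster <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  prof <- do.call(rbind, lapply(split(all, all$cluster), function(cl) {
    mask <- sum(.SOURCE_BIT[unique(cl$source)])
    data.frame(chrom = cl$chrom[1], start = min(cl$start), end = max(cl$end),
               has_t_nmp = "T_NMP" %in% cl$source,
               has_t_notop = "T_NotoP" %in% cl$source,
               has_foxa2 = "Foxa2" %in% cl$source,
               mask = as.integer(mask),
               category = as.integer(category_map[[as.character(mask)]]),
               cluster = cl$cluster[1], stringsAsFactors = FALSE)
  }))
  prof <- prof[order(prof$chrom, prof$start), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "members") <- all
  prof
}

#' Anchor position of a binding profile
#'
#' The anchor of each profile is the summit of its contributing peak from
#' the highest-precedence source present, with precedence
#' T_NMP > T_NotoP > Foxa2. When a cluster contains several peaks of that
#' source, the highest-score peak wins (ties: leftmost). A peak without a
#' stored summit has its summit recomputed from \code{coverage}; with
#' neither summit nor coverage the function errors.
#'
#' @param profiles Output of [combinatorial_profiles()] (with its
#'   \code{"members"} attribute).
#' @param coverage Optional [coverage_track()] used to recompute missing
#'   summits.
#' @return The profiles data frame with an added \code{anchor} column.
#' @export
anchor_maxima <- function(profiles, coverage = NULL) {
  members <- attr(profiles, "members")
  if (is.null(members)) .stopf("profiles lack their members attribute")
  anchors <- vapply(seq_len(nrow(profiles)), function(i) {
    cl <- members[members$cluster == profiles$cluster[i], , drop = FALSE]
    src <- .SOURCES[.SOURCES %in% cl$source][1]
    cand <- cl[cl$source == src, , drop = FALSE]
    cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
    top <- cand[1, , drop = FALSE]
    if (!is.na(top$summit)) return(as.numeric(top$summit))
    if (is.null(coverage))
      .stopf("peak at %s:%d-%d has no summit and no coverage track was given",
             top$chrom, top$start, top$end)
    as.numeric(summit(top, coverage))
  }, numeric(1))
  profiles$anchor <- anchors
  profiles
}

#' Intersect profile anchors with differentially accessible regions
#'
#' Defines candidate enhancers: every differential region (typically the
#' condition-A-up set) containing at least one profile anchor becomes one
#' enhancer row; its flags are the union of the flags of the contained
#' profiles, re-mapped to a category, and its anchor is taken from the
#' contained profile of the highest-precedence source (ties: leftmost).
#' Containment is half-open: an anchor equal to the region end is outside.
#'
#' @param profiles Output of [anchor_maxima()].
#' @param diff_regions Differential regions (usually filtered to direction
#'   \code{"A_up"} and promoter-excluded).
#' @param category_map See [default_category_map()].
#' @return Data frame of class \code{"enhancer_table"}: one row per
#'   differential region with \code{>= 1} anchor; columns \code{chrom},
#'   \code{start}, \code{end}, \code{has_t_nmp}, \code{has_t_notop},
#'   \code{has_foxa2}, \code{mask}, \code{category}, \code{anchor},
#'   \code{n_anchors}.
#' @export
intersect_maxima <- function(profiles, diff_regions,
                             category_map = default_category_map()) {
  .check_category_map(category_map)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      has_t_nmp = logical(), has_t_notop = logical(),
                      has_foxa2 = logical(), mask = integer(),
                      category = integer(), anchor = numeric(),
                      n_anchors = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("enhancer_table", "data.frame")
  if (!nrow(profiles) || !nrow(diff_regions)) return(empty)
  if (is.null(profiles$anchor)) .stopf("profiles lack anchors; run anchor_maxima() first")
  rows <- lapply(seq_len(nrow(diff_regions)), function(i) {
    r <- diff_regions[i, ]
    inside <- profiles$chrom == r$chrom &
      profiles$anchor >= r$start & profiles$anchor < r$end
    if (!any(inside)) return(NULL)
    p <- profiles[inside, , drop = FALSE]
    mask <- as.integer(bitwOr(bitwOr(
      if (any(p$has_t_nmp)) 1L else 0L,
      if (any(p$has_t_notop)) 2L else 0L),
      if (any(p$has_foxa2)) 4L else 0L))
    # representative anchor: highest-precedence source among contained
    # profiles, leftmost on ties
    prec <- ifelse(p$has_t_nmp, 1L, ifelse(p$has_t_notop, 2L, 3L))
    top <- p[order(prec, p$anchor), , drop = FALSE][1, ]
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               has_t_nmp = bitwAnd(mask, 1L) > 0L,
               has_t_notop = bitwAnd(mask, 2L) > 0L,
               has_foxa2 = bitwAnd(mask, 4L) > 0L,
               mask = mask,
               category = as.integer(category_map[[as.character(mask)]]),
               anchor = top$anchor, n_anchors = sum(inside),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enhancer_table", "data.frame")
  out
}

#' Category counts and fractions of an enhancer table
#'
#' Percentages of enhancers falling into named groups of categories,
#' reported to one decimal (half-up rounding).
#'
#' @param table An \code{"enhancer_table"} (or any data frame with a
#'   \code{category} column).
#' @param groups Named list of integer vectors of category ids.
#' @return Data frame with \code{group}, \code{count}, \code{total},
#'   \code{percent}.
#' @export
category_fractions <- function(table, groups) {
  if (!nrow(table)) .stopf("empty enhancer table")
  if (!all(unlist(groups) %in% 1:7)) .stopf("groups must reference categories 1..7")
  total <- nrow(table)
  counts <- vapply(groups, function(g) sum(table$category %in% g), numeric(1))
  data.frame(group = names(groups), count = as.integer(counts), total = total,
             percent = round_half_up(100 * counts / total, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an enhancer table as BED6+
#'
#' @param table An \code{"enhancer_table"}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_enhancer_bed <- function(table, path) {
  x <- as.data.frame(table)
  x$name <- sprintf("cat%d", x$category)
  x$score <- x$category
  x$strand <- rep("*", nrow(x))
  write_bed(x, path, extra = c("category", "mask", "anchor"))
}
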