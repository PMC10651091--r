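#' Construct a set of genomic intervals
#'
#' Intervals are the universal currency of the pipeline and are represented as
#' a plain data frame with columns \code{chrom}, \code{start}, \code{end} (and
#' optionally \code{strand}, \code{name}). All coordinates are 0-based
#' half-open: \code{start} is the first base covered, \code{end} the first base
#' not covered, so \code{end - start} is the length.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param strand Optional strand vector (\code{"+"}, \code{"-"} or \code{"*"}).
#' @param name Optional feature names.
#' @return A data frame of validated intervals.
#' @examples
#' regions("chr1", 100, 200)
#' @export
regions <- function(chrom, start, end, strand = NULL, name = NULL) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (!is.null(name)) df$name <- as.character(name)
  validate_regions(df)
  df
}

#' @rdname regions
#' @param x A data frame of intervals to validate.
#' @export
validate_regions <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    .stopf("interval with empty chromosome name")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    .stopf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
           bad[1], format(x$start[bad[1]]), format(x$end[bad[1]]))
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    .stopf("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Read a BED file
#'
#' Reads BED3+ intervals (tab-separated, 0-based half-open, taken verbatim).
#' \code{track} and \code{browser} lines and \code{#} comments are skipped.
#' Columns 4-6, when present, become \code{name}, \code{score}, \code{strand}.
#'
#' @param path Path to a BED file.
#' @return A data frame of intervals (see [regions()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)\\b|^#|^\\s*$", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(regions(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    .stopf("BED parse error at line %d: fewer than 3 columns", idx[which(ncol < 3L)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    .stopf("BED parse error at line %d: non-integer coordinates", idx[bad[1]])
  bad <- which(start >= end | start < 0)
  if (length(bad))
    .stopf("BED parse error at line %d: start >= end", idx[bad[1]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(ncol >= 4L)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5L))
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(ncol >= 6L)) {
    s <- vapply(fields, `[[`, "", 6L)
    s[s == "."] <- "*"
    df$strand <- s
  }
  validate_regions(df)
  df
}

#' Write intervals as BED
#'
#' Emits deterministically ordered (chrom, start, end) tab-separated BED with
#' any of the optional columns \code{name}, \code{score}, \code{strand} that
#' are present.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param extra Character vector of additional column names to append.
#' @return Invisibly, the path.
#' @export
write_bed <- function(x, path, extra = character()) {
  validate_regions(x)
  ord <- order(x$chrom, x$start, x$end)
  x <- x[ord, , drop = FALSE]
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  opt <- intersect(c("name", "score", "strand"), names(x))
  # BED columns are positional: fill gaps so later columns stay in place
  if (length(opt) || length(extra)) {
    cols <- c(cols, list(
      if ("name" %in% names(x)) x$name else ".",
      if ("score" %in% names(x)) x$score else 0,
      if ("strand" %in% names(x)) sub("\\*", ".", x$strand) else "."
    ))
  }
  for (e in extra) cols <- c(cols, list(x[[e]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a tab-separated file of chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  sizes <- as.numeric(tab$size)
  names(sizes) <- tab$chrom
  if (any(is.na(sizes) | sizes <= 0)) .stopf("invalid chromosome size in %s", path)
  sizes
}

#' Build a genome annotation from gene models
#'
#' @param genes Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"} or \code{"-"}).
#'   The TSS is derived from strand: \code{start} on \code{+},
#'   \code{end - 1} on \code{-}.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return An object of class \code{"genome_annotation"}: a list with
#'   elements \code{genes} (sorted by chrom, start, with a \code{tss}
#'   column) and \code{chrom_sizes}.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes)) {
    validate_regions(genes)
    if (!all(genes$strand %in% c("+", "-")))
      .stopf("gene strand must be '+' or '-'")
    missing <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(missing))
      .stopf("gene chromosome not in chrom_sizes: %s", missing[1])
    if (any(genes$end > chrom_sizes[genes$chrom]))
      .stopf("gene interval extends beyond its chromosome")
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes$tss <- numeric(0)
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosomes (%s bp)\n",
              nrow(x$genes), length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  invisible(x)
}

#' Read a gene annotation
#'
#' Two dialects are supported. \code{"gtf"} parses GTF via
#' \pkg{rtracklayer} (1-based closed coordinates, converted to the internal
#' 0-based half-open convention); one gene model per \code{gene_id} is built
#' as the union span of all its records. \code{"gene-bed"} expects BED6 with
#' the gene identifier in column 4, passed through verbatim.
#'
#' @param path Annotation file.
#' @param chrom_sizes Named numeric vector of chromosome lengths. For
#'   \code{"gene-bed"} it may be omitted, in which case each chromosome
#'   length is taken as the maximal gene end observed.
#' @param dialect \code{"gtf"} or \code{"gene-bed"}.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, chrom_sizes = NULL, dialect = c("gtf", "gene-bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (!length(gr)) .stopf("empty annotation: %s", path)
    if (is.null(gr$gene_id)) .stopf("GTF lacks gene_id attributes: %s", path)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) .stopf("unknown strand in annotation: %s", path)
    df <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
      end = as.numeric(GenomicRanges::end(gr)),
      strand = strand, stringsAsFactors = FALSE
    )
    # union span across a gene's transcripts/records
    genes <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1], stringsAsFactors = FALSE)
    }))
  } else {
    bed <- read_bed(path)
    if (!nrow(bed)) .stopf("empty annotation: %s", path)
    if (is.null(bed$name)) .stopf("gene-bed needs a name column: %s", path)
    if (is.null(bed$strand)) .stopf("gene-bed needs a strand column: %s", path)
    genes <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                        start = bed$start, end = bed$end,
                        strand = bed$strand, stringsAsFactors = FALSE)
  }
  if (is.null(chrom_sizes))
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
  genome_annotation(genes, chrom_sizes)
}

#' Pairwise interval overlap
#'
#' Half-open semantics: two intervals overlap iff they share a chromosome and
#' \code{a.start < b.end && b.start < a.end}. Abutting intervals do not
#' overlap.
#'
#' @param a,b Interval data frames, recycled row-wise against each other.
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Promoter regions around transcription start sites
#'
#' One interval \code{[tss - flank, tss + flank + 1)} per gene (so the flank
#' is symmetric around the TSS base itself), clipped to chromosome bounds.
#'
#' @param annotation A [genome_annotation()].
#' @param flank Flank in bp on each side of the TSS (default 5000).
#' @return Interval data frame with a \code{name} column of gene ids.
#' @export
promoter_regions <- function(annotation, flank = 5000) {
  stopifnot(inherits(annotation, "genome_annotation"), flank > 0)
  g <- annotation$genes
  if (!nrow(g)) return(regions(character(), numeric(), numeric()))
  sizes <- annotation$chrom_sizes[g$chrom]
  regions(g$chrom,
          pmax(0, g$tss - flank),
          pmin(sizes, g$tss + flank + 1),
          name = g$gene_id)
}

#' Drop regions overlapping a mask
#'
#' Whole-region semantics: any region touching any mask interval is removed
#' entirely (no trimming). Input order is preserved. This realises
#' promoter-exclusion and similar filters.
#'
#' @param x Interval data frame to filter.
#' @param mask Interval data frame of masked regions.
#' @return The rows of \code{x} overlapping no mask interval.
#' @export
subtract_overlapping <- function(x, mask) {
  validate_regions(x); validate_regions(mask)
  if (!nrow(x) || !nrow(mask)) return(x)
  hits <- .find_overlaps(x, mask)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop)) x[-drop, , drop = FALSE] else x
  rownames(out) <- NULL
  out
}

#' Closest flanking genes around a position
#'
#' "Upstream" and "downstream" are in reference-coordinate direction: the
#' upstream gene is the one with the greatest end at or left of the position
#' among genes lying entirely left of it; the downstream gene has the least
#' start at or right of the position among genes entirely right of it. Gene
#' strand is ignored. Ties are broken by lexicographically smaller gene id.
#'
#' @param chrom Chromosome name.
#' @param pos Base position (0-based).
#' @param annotation A [genome_annotation()].
#' @param exclude Gene ids to ignore (used when flanking a host gene).
#' @return List with elements \code{upstream} and \code{downstream}, each a
#'   one-row gene data frame or \code{NULL} at chromosome ends.
#' @export
closest_flanking_genes <- function(chrom, pos, annotation, exclude = character()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!chrom %in% names(annotation$chrom_sizes))
    .stopf("unknown chromosome: %s", chrom)
  g <- annotation$genes
  g <- g[g$chrom == chrom & !(g$gene_id %in% exclude), , drop = FALSE]
  pick <- function(cand, by, decreasing) {
    if (!nrow(cand)) return(NULL)
    o <- order(cand[[by]], cand$gene_id, decreasing = c(decreasing, FALSE),
               method = "radix")
    cand[o[1], , drop = FALSE]
  }
  list(
    upstream = pick(g[g$end <= pos, , drop = FALSE], "end", TRUE),
    downstream = pick(g[g$start >= pos, , drop = FALSE], "start", FALSE)
  )
}

#' Classify a region as genic or intergenic
#'
#' A region is genic iff it overlaps any gene body extended by \code{flank}
#' on both sides (i.e. it lies between \code{flank} bp before the gene start
#' and \code{flank} bp after the gene end); otherwise intergenic.
#'
#' @param x Interval data frame (one or more regions).
#' @param annotation A [genome_annotation()].
#' @param flank Extension in bp (default 5000).
#' @return Character vector, \code{"genic"} or \code{"intergenic"} per row.
#' @export
classify_location <- function(x, annotation, flank = 5000) {
  stopifnot(inherits(annotation, "genome_annotation"), flank > 0)
  validate_regions(x)
  g <- annotation$genes
  if (!nrow(g) || !nrow(x))
    return(rep("intergenic", nrow(x)))
  ext <- data.frame(chrom = g$chrom, start = pmax(0, g$start - flank),
                    end = g$end + flank)
  hits <- .find_overlaps(x, ext)
  out <- rep("intergenic", nrow(x))
  out[unique(S4Vectors::queryHits(hits))] <- "genic"
  out
}
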