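#' FPKM expression table
#'
#' A genes-by-samples matrix of FPKM values together with the condition and
#' stage of every sample (e.g. condition \code{"NotoP"} or \code{"MP"} at
#' stages \code{"E8.5"} and \code{"E9.5"}).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param condition Character vector, one condition label per column.
#' @param stage Character vector, one stage label per column.
#' @return An object of class \code{"fpkm_table"}.
#' @export
fpkm_table <- function(values, condition, stage) {
  stopifnot(is.matrix(values), ncol(values) == length(condition),
            ncol(values) == length(stage), all(values >= 0),
            !is.null(rownames(values)))
  structure(list(values = values, condition = as.character(condition),
                 stage = as.character(stage)), class = "fpkm_table")
}

#' @export
print.fpkm_table <- function(x, ...) {
  cat(sprintf("fpkm_table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(paste(x$condition, x$stage, sep = "_")), collapse = ", ")))
  invisible(x)
}

#' FPKM from raw counts
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \code{count * 1e9 / (length * total)}.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param lengths Named numeric vector of gene lengths in bp.
#' @param totals Numeric vector of mapped fragments per sample.
#' @param condition,stage Sample labels, passed to [fpkm_table()].
#' @return An [fpkm_table()].
#' @export
fpkm_from_counts <- function(counts, lengths, totals, condition, stage) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths) | lengths <= 0)) .stopf("missing or non-positive gene length")
  if (any(totals <= 0)) .stopf("non-positive library total")
  vals <- sweep(sweep(counts, 1, lengths, "/"), 2, totals, "/") * 1e9
  fpkm_table(vals, condition, stage)
}

# Mean FPKM per gene for one condition at one stage (averaging replicates).
.group_means <- function(table, condition, stage) {
  sel <- table$condition == condition & table$stage == stage
  if (!any(sel)) .stopf("no samples for condition %s at stage %s", condition, stage)
  rowMeans(table$values[, sel, drop = FALSE])
}

#' Condition-specific genes by two-stage fold change
#'
#' A gene is specific to condition A iff its FPKM exceeds the other
#' condition's by at least \code{fold} at \emph{both} stages (inclusive
#' boundary); symmetric for condition B. A pseudocount is added to both
#' sides of every comparison so zero-FPKM genes remain comparable. The two
#' sets are disjoint for any fold > 1.
#'
#' @param table An [fpkm_table()].
#' @param condition_a,condition_b Condition labels.
#' @param stages Character vector of the two stages required.
#' @param fold Fold-change threshold (default 3).
#' @param pseudocount FPKM pseudocount (default 0.1).
#' @return List with character vectors \code{a_specific} and
#'   \code{b_specific} of gene ids.
#' @export
specific_genes <- function(table, condition_a, condition_b,
                           stages = unique(table$stage), fold = 3,
                           pseudocount = 0.1) {
  stopifnot(inherits(table, "fpkm_table"), fold > 1, length(stages) >= 2)
  a_ok <- b_ok <- rep(TRUE, nrow(table$values))
  for (st in stages) {
    a <- .group_means(table, condition_a, st) + pseudocount
    b <- .group_means(table, condition_b, st) + pseudocount
    a_ok <- a_ok & (a >= fold * b)
    b_ok <- b_ok & (b >= fold * a)
  }
  list(a_specific = rownames(table$values)[a_ok],
       b_specific = rownames(table$values)[b_ok])
}

#' Classify genes by expression pattern
#'
#' Four classes: \code{not_expressed} when the maximal FPKM across all
#' samples is below \code{floor}; otherwise \code{A_specific} /
#' \code{B_specific} for members of the given specific sets; otherwise
#' \code{not_specific}.
#'
#' @param table An [fpkm_table()].
#' @param specific List from [specific_genes()].
#' @param floor Expression floor in FPKM (default 1).
#' @return Named character vector, one class per gene.
#' @export
classify_expression <- function(table, specific, floor = 1) {
  stopifnot(inherits(table, "fpkm_table"), floor >= 0)
  mx <- apply(table$values, 1, max)
  cls <- ifelse(mx < floor, "not_expressed",
         ifelse(rownames(table$values) %in% specific$a_specific, "A_specific",
         ifelse(rownames(table$values) %in% specific$b_specific, "B_specific",
                "not_specific")))
  names(cls) <- rownames(table$values)
  cls
}

#' Assign target genes to enhancer anchors
#'
#' Implements the location-dependent assignment rule: an intergenic anchor
#' (no gene body extended by \code{flank} contains it) is assigned to both
#' the closest upstream and downstream gene; a genic anchor is assigned to
#' every host gene whose extended body contains it, plus the closest
#' upstream and downstream non-host genes flanking the host span. Duplicates
#' are collapsed.
#'
#' @param enhancers An \code{"enhancer_table"} (needs \code{chrom} and
#'   \code{anchor} columns).
#' @param annotation A [genome_annotation()].
#' @param flank Gene-body extension in bp (default 5000).
#' @return Data frame with \code{enhancer_id} (row index of the enhancer),
#'   \code{gene_id}, \code{relation} (\code{"host"},
#'   \code{"upstream_neighbor"}, \code{"downstream_neighbor"}).
#' @export
assign_target_genes <- function(enhancers, annotation, flank = 5000) {
  stopifnot(inherits(annotation, "genome_annotation"), flank > 0)
  if (!nrow(annotation$genes)) .stopf("empty annotation")
  g <- annotation$genes
  out <- lapply(seq_len(nrow(enhancers)), function(i) {
    chrom <- enhancers$chrom[i]
    pos <- enhancers$anchor[i]
    gc <- g[g$chrom == chrom, , drop = FALSE]
    hosts <- gc[pos >= pmax(0, gc$start - flank) & pos < gc$end + flank, , drop = FALSE]
    rows <- list()
    if (nrow(hosts)) {
      rows[[1]] <- data.frame(enhancer_id = i, gene_id = hosts$gene_id,
                              relation = "host", stringsAsFactors = FALSE)
      span <- c(min(hosts$start), max(hosts$end))
      fl_up <- closest_flanking_genes(chrom, span[1], annotation,
                                      exclude = hosts$gene_id)$upstream
      fl_dn <- closest_flanking_genes(chrom, span[2], annotation,
                                      exclude = hosts$gene_id)$downstream
    } else {
      fl <- closest_flanking_genes(chrom, pos, annotation)
      fl_up <- fl$upstream; fl_dn <- fl$downstream
    }
    if (!is.null(fl_up))
      rows[[length(rows) + 1L]] <- data.frame(enhancer_id = i, gene_id = fl_up$gene_id,
                                              relation = "upstream_neighbor",
                                              stringsAsFactors = FALSE)
    if (!is.null(fl_dn))
      rows[[length(rows) + 1L]] <- data.frame(enhancer_id = i, gene_id = fl_dn$gene_id,
                                              relation = "downstream_neighbor",
                                              stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(enhancer_id = integer(), gene_id = character(),
                      relation = character(), stringsAsFactors = FALSE))
  res <- res[!duplicated(res[c("enhancer_id", "gene_id")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene neighbourhood domain
#'
#' The interval spanning from the outer boundary of the upstream neighbour's
#' gene body to the outer boundary of the downstream neighbour's body (the
#' gene body plus both flanking intergenic intervals plus both neighbour
#' bodies); clipped to the chromosome at its ends.
#'
#' @param gene_id Gene identifier.
#' @param annotation A [genome_annotation()].
#' @return One-row interval data frame.
#' @export
gene_domain <- function(gene_id, annotation) {
  g <- annotation$genes
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  if (!nrow(row)) .stopf("gene %s not in annotation", gene_id)
  fl <- closest_flanking_genes(row$chrom, row$start, annotation,
                               exclude = gene_id)
  up <- fl$upstream
  dn <- closest_flanking_genes(row$chrom, row$end, annotation,
                               exclude = gene_id)$downstream
  start <- if (!is.null(up)) up$start else 0
  end <- if (!is.null(dn)) dn$end else annotation$chrom_sizes[[row$chrom]]
  regions(row$chrom, min(start, row$start), max(end, row$end), name = gene_id)
}

#' Associate genes with enhancers in their neighbourhood
#'
#' A gene is associated with every enhancer whose anchor lies within the
#' gene's domain (see [gene_domain()]). Summarises the count and percentage
#' (one decimal) of genes with at least one associated enhancer.
#'
#' @param gene_ids Character vector of gene ids (e.g. a specific set).
#' @param enhancers An \code{"enhancer_table"}.
#' @param annotation A [genome_annotation()].
#' @return List of class \code{"enhancer_gene_map"} with \code{map} (data
#'   frame \code{gene_id}, \code{enhancer_id}, \code{category}),
#'   \code{n_genes}, \code{n_with_enhancer}, \code{percent}.
#' @export
associate <- function(gene_ids, enhancers, annotation) {
  maps <- lapply(gene_ids, function(gid) {
    dom <- gene_domain(gid, annotation)
    hit <- which(enhancers$chrom == dom$chrom &
                   enhancers$anchor >= dom$start & enhancers$anchor < dom$end)
    if (!length(hit)) return(NULL)
    data.frame(gene_id = gid, enhancer_id = hit,
               category = enhancers$category[hit], stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  if (is.null(map))
    map <- data.frame(gene_id = character(), enhancer_id = integer(),
                      category = integer(), stringsAsFactors = FALSE)
  n_with <- length(unique(map$gene_id))
  structure(list(map = map, n_genes = length(gene_ids),
                 n_with_enhancer = n_with,
                 percent = round_half_up(100 * n_with / max(1L, length(gene_ids)), 1)),
            class = "enhancer_gene_map")
}

#' @export
print.enhancer_gene_map <- function(x, ...) {
  cat(sprintf("enhancer_gene_map: %d of %d genes (%.1f%%) with >= 1 enhancer\n",
              x$n_with_enhancer, x$n_genes, x$percent))
  invisible(x)
}

#' UpSet-style category-combination table
#'
#' For each gene, the set of distinct categories among its associated
#' enhancers; genes are counted per exact combination, sorted by count
#' descending.
#'
#' @param map An \code{"enhancer_gene_map"} from [associate()].
#' @return Data frame with \code{combination} (comma-joined sorted category
#'   ids), \code{degree} (number of categories) and \code{count}.
#' @export
upset_table <- function(map) {
  stopifnot(inherits(map, "enhancer_gene_map"))
  if (!nrow(map$map))
    return(data.frame(combination = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  combos <- vapply(split(map$map$category, map$map$gene_id),
                   function(x) paste(sort(unique(x)), collapse = ","), "")
  tab <- table(combos)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), ",")),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn-partition counts of named gene sets
#'
#' Counts identifiers in every region of the Venn partition of the given
#' sets. Identifiers absent from \code{valid_ids} (when supplied) are
#' dropped first; the number dropped is reported in attribute
#' \code{"n_dropped"}.
#'
#' @param sets Named list of >= 2 character vectors.
#' @param valid_ids Optional universe of acceptable identifiers.
#' @return Data frame with one row per non-empty membership pattern:
#'   \code{combination} (comma-joined set names), \code{count}.
#' @export
set_overlap <- function(sets, valid_ids = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  n_dropped <- 0L
  if (!is.null(valid_ids)) {
    before <- sum(lengths(sets))
    sets <- lapply(sets, intersect, y = valid_ids)
    n_dropped <- before - sum(lengths(sets))
  }
  ids <- unique(unlist(sets))
  membership <- vapply(ids, function(id)
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = ","), "")
  tab <- table(membership)
  out <- data.frame(combination = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
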