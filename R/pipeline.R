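#' Pipeline parameters
#'
#' All tunables of the end-to-end analysis with their defaults: 1 kb
#' windows every 100 bp, Benjamini-Hochberg q <= 0.05 with a minimum
#' normalised fold change of 2, a 5 kb promoter flank, 10 bp coverage bins,
#' a 3-fold two-stage criterion for specific genes above a 1 FPKM
#' expression floor.
#'
#' @param window,step Sliding-window width and step in bp.
#' @param alpha Adjusted-significance threshold.
#' @param min_fold Minimum normalised fold change (ratio >= 1).
#' @param promoter_flank Promoter mask half-width in bp.
#' @param bin_size Coverage bin in bp.
#' @param max_insert Maximum fragment length in bp.
#' @param drop_chroms Chromosomes removed from ATAC fragment sets.
#' @param specific_fold Fold threshold for condition-specific genes.
#' @param expression_floor FPKM floor below which a gene counts as not
#'   expressed.
#' @param category_map Binding-category map, see [default_category_map()].
#' @param seed Seed for the (display-only) within-category anchor shuffle.
#' @return A list of class \code{"pipeline_params"}.
#' @export
pipeline_params <- function(window = 1000, step = 100, alpha = 0.05,
                            min_fold = 2, promoter_flank = 5000,
                            bin_size = 10, max_insert = 2000,
                            drop_chroms = c("chrY", "chrM"),
                            specific_fold = 3, expression_floor = 1,
                            category_map = default_category_map(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full enhancer-discovery pipeline
#'
#' Chains every stage on a fixture directory (as written by
#' [emit_fixture()], or any directory with the same file roles): fragment
#' reconstruction, deduplication and chromosome filtering; sliding-window
#' G-test differential accessibility with promoter exclusion; blacklist
#' filtering and combinatorial categorisation of the three TF peak sets;
#' summit intersection with condition-A-up regions to give the enhancer
#' table; specific-gene calling from the FPKM table; enhancer-gene
#' association and the UpSet summary. All intermediates are written to
#' \code{out_dir} together with machine- and human-readable reports.
#'
#' @param fixture_dir Input directory.
#' @param out_dir Output directory.
#' @param params A [pipeline_params()].
#' @param overwrite Allow writing into a non-empty output directory.
#' @return An object of class \code{"ocre_pipeline"}: list with the
#'   per-stage tables, the stage-count report and the parameters.
#' @export
run_pipeline <- function(fixture_dir, out_dir, params = pipeline_params(),
                         overwrite = FALSE) {
  p <- function(f) file.path(fixture_dir, f)
  if (!file.exists(p("chrom.sizes"))) .stopf("no chrom.sizes in %s", fixture_dir)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    .stopf("output directory %s is not empty; use overwrite = TRUE", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  chrom_sizes <- read_chrom_sizes(p("chrom.sizes"))
  annotation <- if (file.exists(p("genes.bed")))
    read_annotation(p("genes.bed"), chrom_sizes, dialect = "gene-bed")
  else genome_annotation(
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character()), chrom_sizes)
  counts$genes <- nrow(annotation$genes)

  load_frags <- function(f) {
    raw <- fragments_from_pairs(read_bedpe(p(f)), params$max_insert)
    n_raw <- raw$library_size
    fs <- drop_chromosomes(deduplicate_fragments(raw), params$drop_chroms)
    list(fs = fs, n_raw = n_raw)
  }
  fa <- load_frags("fragments_a.bedpe")
  fb <- load_frags("fragments_b.bedpe")
  counts$fragments_a_raw <- fa$n_raw
  counts$fragments_b_raw <- fb$n_raw
  counts$fragments_a <- fa$fs$library_size
  counts$fragments_b <- fb$fs$library_size

  wins <- window_counts(fa$fs, fb$fs, chrom_sizes, params$window, params$step)
  diff <- detect_differential(wins, fa$fs$library_size, fb$fs$library_size,
                              alpha = params$alpha, min_fold = params$min_fold)
  counts$differential_regions <- nrow(diff)
  write_diff_bed(diff, file.path(out_dir, "differential_regions.bed"))
  diff_np <- exclude_promoters(diff, annotation, params$promoter_flank)
  counts$differential_regions_nonpromoter <- nrow(diff_np)
  write_diff_bed(diff_np, file.path(out_dir, "differential_regions_nonpromoter.bed"))
  a_up <- diff_np[diff_np$direction == "A_up", , drop = FALSE]
  counts$a_up_regions <- nrow(a_up)

  blacklist <- if (file.exists(p("blacklist.bed"))) read_bed(p("blacklist.bed"))
               else regions(character(), numeric(), numeric())
  peaks <- lapply(c(t_nmp = "t_nmp.narrowPeak", t_notop = "t_notop.narrowPeak",
                    foxa2 = "foxa2.narrowPeak"), function(f) {
    if (!file.exists(p(f)))
      return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character(), score = numeric(), summit = numeric(),
                        source = character(), stringsAsFactors = FALSE))
    remove_blacklisted(read_narrowpeak(p(f)), blacklist)
  })
  counts$peaks_t_nmp <- nrow(peaks$t_nmp)
  counts$peaks_t_notop <- nrow(peaks$t_notop)
  counts$peaks_foxa2 <- nrow(peaks$foxa2)

  cov_a <- coverage_track(fa$fs, chrom_sizes, params$bin_size)
  profiles <- combinatorial_profiles(peaks$t_nmp, peaks$t_notop, peaks$foxa2,
                                     params$category_map)
  counts$binding_profiles <- nrow(profiles)
  if (nrow(profiles)) profiles <- anchor_maxima(profiles, cov_a)
  enhancers <- intersect_maxima(profiles, a_up, params$category_map)
  counts$enhancers <- nrow(enhancers)
  write_enhancer_bed(enhancers, file.path(out_dir, "enhancers.bed"))

  fractions <- if (nrow(enhancers))
    category_fractions(enhancers, c(
      list(t_alone = c(2, 4, 6), foxa2_only = 7, t_and_foxa2 = c(1, 3, 5)),
      stats::setNames(as.list(1:7), sprintf("cat%d", 1:7))))
  else NULL

  expression <- specific <- classes <- assoc <- upset <- NULL
  if (file.exists(p("fpkm.tsv")) && nrow(annotation$genes)) {
    expression <- read_fpkm(p("fpkm.tsv"))
    specific <- specific_genes(expression, "NotoP", "MP",
                               fold = params$specific_fold)
    classes <- classify_expression(expression, specific,
                                   params$expression_floor)
    counts$a_specific_genes <- length(specific$a_specific)
    counts$b_specific_genes <- length(specific$b_specific)
    utils::write.table(
      data.frame(gene_id = names(classes), class = unname(classes)),
      file.path(out_dir, "expression_classes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(enhancers)) {
      assoc <- associate(specific$a_specific, enhancers, annotation)
      counts$a_specific_with_enhancer <- assoc$n_with_enhancer
      upset <- upset_table(assoc)
      utils::write.table(assoc$map, file.path(out_dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(upset, file.path(out_dir, "upset.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      targets <- assign_target_genes(enhancers, annotation,
                                     params$promoter_flank)
      utils::write.table(targets, file.path(out_dir, "target_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  result <- structure(list(
    counts = counts, fractions = fractions, params = params,
    annotation = annotation, diff_regions = diff_np, enhancers = enhancers,
    specific = specific, classes = classes, association = assoc,
    upset = upset, out_dir = out_dir), class = "ocre_pipeline")
  pipeline_report(result, out_dir)
  result
}

#' Write pipeline reports
#'
#' Emits \code{report.tsv} (stage counts plus parameter values, one
#' key/value pair per line) and \code{report.txt} (human-readable summary
#' with category fractions and the association rate).
#'
#' @param result An \code{"ocre_pipeline"} object.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
pipeline_report <- function(result, out_dir) {
  stopifnot(inherits(result, "ocre_pipeline"))
  kv <- c(lapply(result$counts, as.character),
          lapply(result$params[c("window", "step", "alpha", "min_fold",
                                 "promoter_flank", "bin_size", "max_insert",
                                 "specific_fold", "expression_floor", "seed")],
                 as.character))
  tsv <- file.path(out_dir, "report.tsv")
  utils::write.table(data.frame(key = names(kv), value = unlist(kv)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- file.path(out_dir, "report.txt")
  lines <- c("ocre pipeline report", "====================", "",
             sprintf("%-34s %s", paste0(names(result$counts), ":"),
                     unlist(lapply(result$counts, as.character))))
  if (!is.null(result$fractions)) {
    lines <- c(lines, "", "category fractions:",
               sprintf("  %-12s %d/%d (%.1f%%)", result$fractions$group,
                       result$fractions$count, result$fractions$total,
                       result$fractions$percent))
  }
  if (!is.null(result$association)) {
    a <- result$association
    lines <- c(lines, "",
               sprintf("condition-A specific genes with >= 1 enhancer: %d of %d (%.1f%%)",
                       a$n_with_enhancer, a$n_genes, a$percent))
  }
  writeLines(lines, txt)
  invisible(c(tsv, txt))
}

#' @export
print.ocre_pipeline <- function(x, ...) {
  cat("ocre pipeline result\n")
  for (k in names(x$counts)) cat(sprintf("  %-32s %s\n", k, x$counts[[k]]))
  if (!is.null(x$association))
    cat(sprintf("  association: %d of %d genes (%.1f%%)\n",
                x$association$n_with_enhancer, x$association$n_genes,
                x$association$percent))
  invisible(x)
}

#' @export
summary.ocre_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$fractions)) {
    cat("category fractions:\n")
    print(object$fractions, row.names = FALSE)
  }
  if (!is.null(object$upset) && nrow(object$upset)) {
    cat("per-gene category combinations:\n")
    print(object$upset, row.names = FALSE)
  }
  invisible(object)
}
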