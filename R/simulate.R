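# Synthetic-data generator: toy genomes, fragment libraries with planted
# differentially accessible windows, TF peak sets with known combinatorial
# structure, and FPKM tables with planted condition-specific genes. Every
# generator is deterministic under the master seed; each stage derives its
# own sub-seed so stages can be re-run independently.

#' Simulation configuration
#'
#' Bundles all tunables of the synthetic-data generator with the default toy
#' conditions: a 2 x 200 kb genome with 20 genes and 30 planted enhancers,
#' negative-binomially varying window accessibility at a mean depth of 50
#' fragments per 1 kb window, a 4-fold accessibility gain at planted
#' enhancers in condition A, lognormal fragment lengths (median 200 bp), a
#' 10 percent duplicate rate, and 5 planted specific genes per condition at
#' 10-fold expression difference.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes (0 allowed for gene-free genomes).
#' @param n_enhancers Number of planted enhancers.
#' @param category_probabilities Probabilities of the 7 binding categories
#'   for planted enhancers (must sum to 1).
#' @param accessibility_fold Accessibility fold change at planted enhancers
#'   in condition A (1 = null simulation).
#' @param mean_depth Mean fragments per window.
#' @param dispersion Across-window negative-binomial dispersion of the
#'   shared accessibility rate (0 = constant rate, i.e. pure Poisson
#'   counts).
#' @param window Window width in bp used for planting and fragment
#'   placement.
#' @param duplicate_rate Fraction of the emitted library that is injected
#'   PCR-style duplicates.
#' @param fragment_meanlog,fragment_sdlog Lognormal fragment-length
#'   parameters (defaults give a 200 bp median, ATAC-scale inserts).
#' @param min_gene_length,max_gene_length Gene length range in bp.
#' @param min_gap Minimum intergenic gap in bp.
#' @param promoter_flank Promoter mask half-width in bp.
#' @param peak_halfwidth Half-width of simulated TF peaks in bp.
#' @param summit_jitter Max absolute jitter of peak summits around the
#'   planted position in bp.
#' @param n_blacklist Number of blacklist regions per genome.
#' @param n_decoys Number of decoy peaks placed inside blacklist regions.
#' @param n_specific_genes Planted specific genes per condition.
#' @param specific_fold Expression fold of planted specific genes.
#' @param fpkm_sigma Lognormal noise sigma on FPKM values.
#' @param seed Master seed.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 200000,
                       n_genes = 20, n_enhancers = 30,
                       category_probabilities = rep(1 / 7, 7),
                       accessibility_fold = 4, mean_depth = 50,
                       dispersion = 0.1, window = 1000,
                       duplicate_rate = 0.1,
                       fragment_meanlog = log(200), fragment_sdlog = 0.25,
                       min_gene_length = 2000, max_gene_length = 6000,
                       min_gap = 5000, promoter_flank = 5000,
                       peak_halfwidth = 250, summit_jitter = 20,
                       n_blacklist = 3, n_decoys = 5,
                       n_specific_genes = 5, specific_fold = 10,
                       fpkm_sigma = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$category_probabilities) - 1) > 1e-9 ||
      length(cfg$category_probabilities) != 7)
    .stopf("category_probabilities must be 7 values summing to 1")
  stopifnot(cfg$accessibility_fold >= 1, cfg$mean_depth > 0,
            cfg$dispersion >= 0, cfg$duplicate_rate >= 0,
            cfg$duplicate_rate < 1,
            cfg$n_genes == 0 || cfg$n_specific_genes * 2 <= cfg$n_genes)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome annotation
#'
#' Genes are placed per chromosome with random lengths and random
#' intergenic gaps, never closer than \code{min_gap}, with random strands.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
make_genome <- function(config) {
  set.seed(.derive_seed(config$seed, 1L))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(config$chrom_length, length(chroms)), chroms)
  n <- config$n_genes
  if (n == 0)
    return(genome_annotation(
      data.frame(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), stringsAsFactors = FALSE),
      sizes))
  per <- diff(floor(seq(0, n, length.out = length(chroms) + 1)))
  rows <- list()
  k <- 0L
  for (ci in seq_along(chroms)) {
    m <- per[ci]
    if (m == 0) next
    lens <- round(stats::runif(m, config$min_gene_length, config$max_gene_length))
    need <- sum(lens) + (m + 1) * config$min_gap
    if (need > config$chrom_length)
      .stopf(paste("cannot place %d genes on a %d bp chromosome with min gap %d;",
                   "reduce n_genes or min_gap, or increase chrom_length"),
             m, config$chrom_length, config$min_gap)
    free <- config$chrom_length - need
    # split the slack into m+1 random extra gaps
    cuts <- sort(stats::runif(m, 0, free))
    extra <- diff(c(0, cuts, free))
    pos <- config$min_gap + extra[1]
    for (j in seq_len(m)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("g%03d", k), chrom = chroms[ci],
        start = pos, end = pos + lens[j],
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      pos <- pos + lens[j] + config$min_gap + extra[j + 1]
    }
  }
  genome_annotation(do.call(rbind, rows), sizes)
}

#' Plant enhancers with known binding categories
#'
#' Enhancer positions are centers of windows chosen away from promoter
#' masks (promoters extended by two windows, so downstream merged
#' differential regions cannot touch a promoter) and at least three windows
#' apart from each other (so merged regions of neighbouring enhancers never
#' fuse). Each enhancer draws a true binding category from
#' \code{category_probabilities}; the implied source flags use the default
#' category map.
#'
#' @param annotation A [genome_annotation()] from [make_genome()].
#' @param config A [sim_config()].
#' @return Data frame (the ground truth) with \code{chrom},
#'   \code{window_start}, \code{window_end}, \code{pos}, \code{category},
#'   \code{mask}, \code{has_t_nmp}, \code{has_t_notop}, \code{has_foxa2}.
#' @export
plant_enhancers <- function(annotation, config) {
  set.seed(.derive_seed(config$seed, 2L))
  w <- config$window
  if (config$n_enhancers == 0)
    return(data.frame(chrom = character(), window_start = numeric(),
                      window_end = numeric(), pos = numeric(),
                      category = integer(), mask = integer(),
                      has_t_nmp = logical(), has_t_notop = logical(),
                      has_foxa2 = logical(), stringsAsFactors = FALSE))
  mask_regions <- if (nrow(annotation$genes))
    promoter_regions(annotation, config$promoter_flank + 2 * w)
  else regions(character(), numeric(), numeric())
  cand <- do.call(rbind, lapply(names(annotation$chrom_sizes), function(ch) {
    len <- annotation$chrom_sizes[[ch]]
    starts <- seq(0, len - w, by = w)
    data.frame(chrom = ch, start = starts, end = starts + w, widx = seq_along(starts),
               stringsAsFactors = FALSE)
  }))
  cand <- subtract_overlapping(cand, mask_regions)
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  picked <- list()
  taken <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(picked) == config$n_enhancers) break
    ch <- cand$chrom[i]; wi <- cand$widx[i]
    if (any(abs(taken[[ch]] %||% integer(0) - wi) < 3L)) next
    taken[[ch]] <- c(taken[[ch]], wi)
    picked[[length(picked) + 1L]] <- cand[i, ]
  }
  if (length(picked) < config$n_enhancers)
    .stopf(paste("only %d of %d enhancers could be placed;",
                 "reduce n_enhancers or n_genes, or enlarge the genome"),
           length(picked), config$n_enhancers)
  truth <- do.call(rbind, picked)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  category <- sample(1:7, nrow(truth), replace = TRUE,
                     prob = config$category_probabilities)
  inv_map <- stats::setNames(as.integer(names(default_category_map())),
                             default_category_map())
  mask <- inv_map[as.character(category)]
  data.frame(chrom = truth$chrom, window_start = truth$start,
             window_end = truth$end, pos = truth$start + w %/% 2,
             category = category, mask = as.integer(mask),
             has_t_nmp = bitwAnd(mask, 1L) > 0,
             has_t_notop = bitwAnd(mask, 2L) > 0,
             has_foxa2 = bitwAnd(mask, 4L) > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate two fragment libraries with planted differential windows
#'
#' Each window carries a latent accessibility rate shared by both
#' conditions, drawn from a gamma distribution so that window counts are
#' negative-binomially dispersed across the genome (\code{dispersion = 0}
#' fixes the rate, giving pure Poisson counts). Condition A's rate is
#' multiplied by \code{accessibility_fold} in windows containing a planted
#' enhancer; both conditions then draw Poisson counts from their rates, so
#' under the null the two libraries are exchangeable. Fragments get
#' lognormal lengths and are placed uniformly within their window;
#' duplicates are injected at \code{duplicate_rate} (as a fraction of the
#' emitted library).
#'
#' @param truth Ground-truth enhancers from [plant_enhancers()] (or an
#'   empty data frame for a null library).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param config A [sim_config()].
#' @return List with [fragment_set()]s \code{a} and \code{b} and the
#'   per-condition counts of injected duplicates in attributes
#'   \code{"n_duplicates_a"} / \code{"n_duplicates_b"}.
#' @export
simulate_fragments <- function(truth, chrom_sizes, config) {
  set.seed(.derive_seed(config$seed, 3L))
  w <- config$window
  frag_pool <- function(n, ws, we) {
    len <- pmin(we - ws - 1,
                pmax(50, round(stats::rlnorm(n, config$fragment_meanlog,
                                             config$fragment_sdlog))))
    start <- ws + floor(stats::runif(n) * (we - ws - len))
    data.frame(start = start, end = start + len)
  }
  frags_a <- list(); frags_b <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - w, by = w)
    planted <- truth$window_start[truth$chrom == ch]
    fold <- ifelse(starts %in% planted, config$accessibility_fold, 1)
    rate <- if (config$dispersion > 0)
      stats::rgamma(length(starts), shape = 1 / config$dispersion,
                    scale = config$mean_depth * config$dispersion)
    else rep(config$mean_depth, length(starts))
    na <- stats::rpois(length(starts), rate * fold)
    nb <- stats::rpois(length(starts), rate)
    for (j in seq_along(starts)) {
      if (na[j] > 0) {
        f <- frag_pool(na[j], starts[j], starts[j] + w)
        frags_a[[length(frags_a) + 1L]] <- data.frame(chrom = ch, f)
      }
      if (nb[j] > 0) {
        f <- frag_pool(nb[j], starts[j], starts[j] + w)
        frags_b[[length(frags_b) + 1L]] <- data.frame(chrom = ch, f)
      }
    }
  }
  finish <- function(lst) {
    df <- if (length(lst)) do.call(rbind, lst)
          else data.frame(chrom = character(), start = numeric(), end = numeric())
    n_dup <- 0L
    if (config$duplicate_rate > 0 && nrow(df)) {
      n_dup <- round(nrow(df) * config$duplicate_rate / (1 - config$duplicate_rate))
      dup <- df[sample(nrow(df), n_dup, replace = TRUE), , drop = FALSE]
      df <- rbind(df, dup)
    }
    fs <- fragment_set(df)
    attr(fs, "n_duplicates") <- n_dup
    fs
  }
  a <- finish(frags_a)
  b <- finish(frags_b)
  out <- list(a = a, b = b)
  attr(out, "n_duplicates_a") <- attr(a, "n_duplicates")
  attr(out, "n_duplicates_b") <- attr(b, "n_duplicates")
  out
}

#' Simulate TF peak sets and a blacklist
#'
#' Every planted enhancer receives one peak per true source flag, with
#' jittered boundaries and a summit at the planted position (plus-minus
#' \code{summit_jitter}). Decoy peaks are placed inside blacklist regions
#' (windows free of enhancers) to exercise blacklist filtering.
#'
#' @param truth Ground truth from [plant_enhancers()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param config A [sim_config()].
#' @return List with peak data frames \code{t_nmp}, \code{t_notop},
#'   \code{foxa2} and an interval data frame \code{blacklist}.
#' @export
simulate_peaks <- function(truth, chrom_sizes, config) {
  set.seed(.derive_seed(config$seed, 4L))
  hw <- config$peak_halfwidth
  jit <- function(n) if (config$summit_jitter > 0)
    sample(seq(-config$summit_jitter, config$summit_jitter), n, replace = TRUE)
  else integer(n)
  make_set <- function(flag_col, source) {
    t <- truth[truth[[flag_col]], , drop = FALSE]
    if (!nrow(t))
      return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character(), score = numeric(), summit = numeric(),
                        source = character(), stringsAsFactors = FALSE))
    s <- t$pos + jit(nrow(t))
    start <- pmin(s, t$pos) - hw - abs(jit(nrow(t)))
    end <- pmax(s, t$pos) + hw + abs(jit(nrow(t)))
    data.frame(chrom = t$chrom, start = pmax(0, start), end = end,
               name = sprintf("%s_peak%d", source, seq_len(nrow(t))),
               score = round(stats::runif(nrow(t), 100, 1000)),
               summit = s, source = source, stringsAsFactors = FALSE)
  }
  t_nmp <- make_set("has_t_nmp", "T_NMP")
  t_notop <- make_set("has_t_notop", "T_NotoP")
  foxa2 <- make_set("has_foxa2", "Foxa2")
  # blacklist regions in enhancer-free windows, decoy peaks inside them
  w <- config$window
  cand <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - w, by = w)
    data.frame(chrom = ch, start = starts, end = starts + w,
               stringsAsFactors = FALSE)
  }))
  if (nrow(truth))
    cand <- subtract_overlapping(
      cand, regions(truth$chrom, pmax(0, truth$window_start - w), truth$window_end + w))
  bl <- cand[sample(nrow(cand), min(config$n_blacklist, nrow(cand))), , drop = FALSE]
  bl <- bl[order(bl$chrom, bl$start), , drop = FALSE]
  rownames(bl) <- NULL
  decoys <- list(t_nmp = t_nmp, t_notop = t_notop, foxa2 = foxa2)
  if (config$n_decoys > 0 && nrow(bl)) {
    pick <- bl[sample(nrow(bl), config$n_decoys, replace = TRUE), , drop = FALSE]
    src <- sample(c("T_NMP", "T_NotoP", "Foxa2"), config$n_decoys, replace = TRUE)
    ctr <- floor((pick$start + pick$end) / 2)
    dec <- data.frame(chrom = pick$chrom, start = ctr - hw, end = ctr + hw,
                      name = sprintf("decoy%d", seq_len(nrow(pick))),
                      score = round(stats::runif(nrow(pick), 100, 1000)),
                      summit = ctr, source = src, stringsAsFactors = FALSE)
    decoys$t_nmp <- rbind(t_nmp, dec[dec$source == "T_NMP", ])
    decoys$t_notop <- rbind(t_notop, dec[dec$source == "T_NotoP", ])
    decoys$foxa2 <- rbind(foxa2, dec[dec$source == "Foxa2", ])
  }
  list(t_nmp = decoys$t_nmp, t_notop = decoys$t_notop, foxa2 = decoys$foxa2,
       blacklist = bl[, c("chrom", "start", "end")])
}

#' Simulate an FPKM table with planted specific genes
#'
#' Baseline expression is lognormal (median 10 FPKM); the first
#' \code{n_specific_genes} sampled genes are multiplied by
#' \code{specific_fold} in condition A at both stages, a disjoint set
#' symmetric for condition B; every value then receives multiplicative
#' lognormal noise with sigma \code{fpkm_sigma}.
#'
#' @param annotation A [genome_annotation()].
#' @param config A [sim_config()].
#' @return List with the [fpkm_table()] (\code{table}), and ground-truth
#'   gene id vectors \code{a_specific}, \code{b_specific}.
#' @export
simulate_fpkm <- function(annotation, config) {
  set.seed(.derive_seed(config$seed, 5L))
  ids <- annotation$genes$gene_id
  if (!length(ids)) .stopf("cannot simulate FPKM for an empty annotation")
  ns <- config$n_specific_genes
  pick <- sample(ids, 2 * ns)
  a_set <- sort(pick[seq_len(ns)])
  b_set <- sort(pick[ns + seq_len(ns)])
  base <- stats::rlnorm(length(ids), log(10), 1)
  cond <- c("NotoP", "MP", "NotoP", "MP")
  stage <- c("E8.5", "E8.5", "E9.5", "E9.5")
  vals <- matrix(base, nrow = length(ids), ncol = 4)
  rownames(vals) <- ids
  colnames(vals) <- paste(cond, stage, sep = "_")
  vals[ids %in% a_set, cond == "NotoP"] <-
    vals[ids %in% a_set, cond == "NotoP"] * config$specific_fold
  vals[ids %in% b_set, cond == "MP"] <-
    vals[ids %in% b_set, cond == "MP"] * config$specific_fold
  if (config$fpkm_sigma > 0)
    vals <- vals * matrix(stats::rlnorm(length(vals), 0, config$fpkm_sigma),
                          nrow = nrow(vals))
  list(table = fpkm_table(vals, cond, stage),
       a_specific = a_set, b_specific = b_set)
}

#' Write an FPKM table as TSV
#'
#' Columns are named \code{condition_stage}; [read_fpkm()] reverses this.
#'
#' @param table An [fpkm_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fpkm <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fpkm
#' @export
read_fpkm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  parts <- strsplit(colnames(vals), "_", fixed = TRUE)
  fpkm_table(vals,
             condition = vapply(parts, `[[`, "", 1L),
             stage = vapply(parts, function(p) paste(p[-1], collapse = "_"), ""))
}

#' Emit a complete synthetic fixture to disk
#'
#' Runs every generator and writes the standard-format inputs the pipeline
#' consumes (chrom.sizes, gene BED, fragment BEDPE per condition, three
#' narrowPeak files, blacklist BED, FPKM TSV) plus ground-truth tables and a
#' manifest linking each file to its role with an MD5 checksum. Byte-stable
#' under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the \code{dir}, the generated objects and
#'   the manifest data frame.
#' @export
emit_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- make_genome(config)
  truth <- plant_enhancers(annotation, config)
  frags <- simulate_fragments(truth, annotation$chrom_sizes, config)
  peaks <- simulate_peaks(truth, annotation$chrom_sizes, config)
  expr <- if (nrow(annotation$genes)) simulate_fpkm(annotation, config) else NULL

  p <- function(f) file.path(dir, f)
  writeLines(sprintf("%s\t%d", names(annotation$chrom_sizes),
                     as.integer(annotation$chrom_sizes)), p("chrom.sizes"))
  g <- annotation$genes
  if (nrow(g))
    write_bed(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                         name = g$gene_id, score = 0, strand = g$strand),
              p("genes.bed"))
  write_pairs <- function(fs, f) {
    fr <- fs$fragments
    half <- pmin(50, floor((fr$end - fr$start) / 2))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", fr$chrom,
                     as.integer(fr$start), as.integer(fr$start + half),
                     fr$chrom, as.integer(fr$end - half), as.integer(fr$end))
    writeLines(lines, p(f))
  }
  write_pairs(frags$a, "fragments_a.bedpe")
  write_pairs(frags$b, "fragments_b.bedpe")
  write_np <- function(pk, f) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t0\t-1\t-1\t%d", pk$chrom,
                     as.integer(pk$start), as.integer(pk$end), pk$name,
                     as.integer(pk$score), as.integer(pk$summit - pk$start))
    writeLines(lines, p(f))
  }
  write_np(peaks$t_nmp, "t_nmp.narrowPeak")
  write_np(peaks$t_notop, "t_notop.narrowPeak")
  write_np(peaks$foxa2, "foxa2.narrowPeak")
  write_bed(peaks$blacklist, p("blacklist.bed"))
  if (!is.null(expr)) {
    write_fpkm(expr$table, p("fpkm.tsv"))
    utils::write.table(
      data.frame(gene_id = c(expr$a_specific, expr$b_specific),
                 set = rep(c("a_specific", "b_specific"),
                           c(length(expr$a_specific), length(expr$b_specific)))),
      p("truth_specific_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(truth, p("truth_enhancers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("chrom.sizes", if (nrow(g)) "genes.bed",
             "fragments_a.bedpe", "fragments_b.bedpe",
             "t_nmp.narrowPeak", "t_notop.narrowPeak", "foxa2.narrowPeak",
             "blacklist.bed", if (!is.null(expr)) c("fpkm.tsv", "truth_specific_genes.tsv"),
             "truth_enhancers.tsv")
  roles <- c("chrom_sizes", if (nrow(g)) "annotation",
             "fragments_condition_a", "fragments_condition_b",
             "peaks_t_nmp", "peaks_t_notop", "peaks_foxa2",
             "blacklist", if (!is.null(expr)) c("fpkm", "truth_specific_genes"),
             "truth_enhancers")
  manifest <- data.frame(role = roles, file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(dir = dir, annotation = annotation, truth = truth,
                 fragments = frags, peaks = peaks, expression = expr,
                 manifest = manifest))
}
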