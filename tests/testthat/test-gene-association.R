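test_that("FPKM equals the direct arithmetic definition", {
  counts <- matrix(c(100L, 0L, 50L, 10L), nrow = 2,
                   dimnames = list(c("gA", "gB"), NULL))
  tab <- fpkm_from_counts(counts, c(gA = 1000, gB = 2000),
                          totals = c(1e6, 2e6),
                          condition = c("NotoP", "MP"),
                          stage = c("E8.5", "E8.5"))
  expect_equal(unname(tab$values["gA", 1]), 100)  # 100 * 1e9 / (1000 * 1e6)
  expect_equal(unname(tab$values["gB", 1]), 0)
  expect_equal(unname(tab$values["gA", 2]), 25)
  expect_error(fpkm_from_counts(counts, c(gA = 0, gB = 2000), c(1e6, 1e6),
                                c("a", "b"), c("s", "s")), "length")

  set.seed(41)
  cm <- matrix(rpois(40, 200), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  lens <- setNames(sample(500:3000, 10), rownames(cm))
  tots <- runif(4, 5e5, 2e6)
  tab <- fpkm_from_counts(cm, lens, tots, rep("A", 4), rep("s", 4))
  for (i in 1:10) for (j in 1:4)
    expect_equal(tab$values[i, j], cm[i, j] * 1e9 / (lens[[i]] * tots[j]))
})

make_fpkm <- function(a1, a2, b1, b2, ids = sprintf("g%02d", seq_along(a1))) {
  vals <- cbind(a1, b1, a2, b2)
  rownames(vals) <- ids
  fpkm_table(vals, condition = c("NotoP", "MP", "NotoP", "MP"),
             stage = c("E8.5", "E8.5", "E9.5", "E9.5"))
}

test_that("specific genes require the fold at both stages, boundary inclusive", {
  # with pseudocount 0: 9 vs 3 is exactly 3-fold at both stages -> specific
  tab <- make_fpkm(a1 = c(9, 9), a2 = c(9, 2), b1 = c(3, 3), b2 = c(3, 3))
  sp <- specific_genes(tab, "NotoP", "MP", fold = 3, pseudocount = 0)
  expect_equal(sp$a_specific, "g01")   # g02 fails stage 2
  expect_equal(sp$b_specific, character(0))
  # disjointness for any fold > 1
  tab <- make_fpkm(a1 = runif(20, 0, 20), a2 = runif(20, 0, 20),
                   b1 = runif(20, 0, 20), b2 = runif(20, 0, 20))
  sp <- specific_genes(tab, "NotoP", "MP", fold = 1.5)
  expect_length(intersect(sp$a_specific, sp$b_specific), 0L)
  expect_error(specific_genes(tab, "NotoP", "MP", stages = c("E8.5", "E10")),
               "no samples")
})

test_that("expression classes follow floor-then-specificity precedence", {
  tab <- make_fpkm(a1 = c(0, 30, 5, 0.2), a2 = c(0, 30, 5, 0.2),
                   b1 = c(0, 3, 5, 0.05), b2 = c(0, 3, 5, 0.05))
  sp <- specific_genes(tab, "NotoP", "MP", fold = 3)
  cls <- classify_expression(tab, sp, floor = 1)
  expect_equal(unname(cls),
               c("not_expressed", "A_specific", "not_specific",
                 "not_expressed"))  # g04 is 4-fold but below floor
})

test_that("target-gene assignment follows the genic/intergenic rule", {
  # genes U(0,1000), G(20000,30000), D(50000,51000)
  genes <- data.frame(gene_id = c("U", "G", "D"), chrom = "chr1",
                      start = c(0, 20000, 50000),
                      end = c(1000, 30000, 51000), strand = "+")
  ann <- genome_annotation(genes, c(chr1 = 100000))
  enh <- data.frame(chrom = "chr1", anchor = c(25000, 40000, 60000))
  asg <- assign_target_genes(enh, ann, flank = 5000)
  # genic anchor: host plus both neighbours
  expect_setequal(asg$gene_id[asg$enhancer_id == 1], c("G", "U", "D"))
  expect_equal(asg$relation[asg$enhancer_id == 1 & asg$gene_id == "G"], "host")
  # intergenic anchor: both flanking genes only
  expect_setequal(asg$gene_id[asg$enhancer_id == 2], c("G", "D"))
  # anchor right of all genes: single existing neighbour
  expect_equal(asg$gene_id[asg$enhancer_id == 3], "D")

  # overlapping genes: both hosts plus flanks
  genes2 <- rbind(genes, data.frame(gene_id = "G2", chrom = "chr1",
                                    start = 24000, end = 32000, strand = "-"))
  ann2 <- genome_annotation(genes2, c(chr1 = 100000))
  asg2 <- assign_target_genes(data.frame(chrom = "chr1", anchor = 25000),
                              ann2, flank = 5000)
  expect_setequal(asg2$gene_id, c("G", "G2", "U", "D"))
  expect_equal(sort(asg2$gene_id[asg2$relation == "host"]), c("G", "G2"))
})

test_that("gene domains span neighbour bodies and clip at chromosome ends", {
  genes <- data.frame(gene_id = c("U", "G", "D"), chrom = "chr1",
                      start = c(0, 500, 900), end = c(100, 600, 1000),
                      strand = "+")
  ann <- genome_annotation(genes, c(chr1 = 1000))
  dom <- gene_domain("G", ann)
  expect_equal(c(dom$start, dom$end), c(0, 1000))
  dom <- gene_domain("U", ann)  # first gene: domain starts at 0
  expect_equal(c(dom$start, dom$end), c(0, 600))
})

test_that("domain association agrees with assignment-based association for interior genes", {
  set.seed(43)
  for (rep in 1:5) {
    starts <- sort(sample(seq(0, 90000, by = 100), 12))
    starts <- starts[c(TRUE, diff(starts) > 3000)]
    genes <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                        chrom = "chr1", start = starts, end = starts + 2000,
                        strand = "+")
    ann <- genome_annotation(genes, c(chr1 = 100000))
    enh <- data.frame(chrom = "chr1",
                      anchor = floor(runif(40, 200, 99000)))
    # the two formulations are only claimed to agree away from the flank
    # margins just outside gene bodies, so keep anchors out of those strips
    fl <- 200
    margin <- vapply(enh$anchor, function(p)
      any((p >= genes$start - fl & p < genes$start) |
            (p >= genes$end & p < genes$end + fl)), logical(1))
    enh <- enh[!margin, , drop = FALSE]
    enh$start <- enh$anchor - 100; enh$end <- enh$anchor + 100
    enh$category <- sample(1:7, nrow(enh), replace = TRUE)
    asg <- assign_target_genes(enh, ann, flank = fl)
    interior <- genes$gene_id[-c(1, nrow(genes))]
    for (gid in interior) {
      dom <- gene_domain(gid, ann)
      by_domain <- which(enh$anchor >= dom$start & enh$anchor < dom$end)
      by_assign <- asg$enhancer_id[asg$gene_id == gid]
      expect_setequal(by_domain, by_assign)
    }
  }
})

test_that("association summary counts genes with at least one enhancer", {
  genes <- data.frame(gene_id = c("U", "G", "D"), chrom = "chr1",
                      start = c(0, 40000, 80000),
                      end = c(1000, 41000, 81000), strand = "+")
  ann <- genome_annotation(genes, c(chr1 = 120000))
  enh <- data.frame(chrom = "chr1", anchor = 40500, category = 3L)
  a <- associate(c("U", "G", "D"), enh, ann)
  # the single enhancer sits in every gene's domain here
  expect_equal(a$n_with_enhancer, 3L)
  expect_equal(a$percent, 100.0)
  none <- associate(c("U", "G", "D"), enh[0, ], ann)
  expect_equal(none$n_with_enhancer, 0L)
  expect_equal(none$percent, 0.0)
  # invariant under enhancer order
  enh2 <- data.frame(chrom = "chr1", anchor = c(100000, 40500, 500),
                     category = c(1L, 3L, 2L))
  a1 <- associate(c("U", "G", "D"), enh2, ann)
  a2 <- associate(c("D", "G", "U"), enh2[c(3, 1, 2), ], ann)
  expect_equal(a1$percent, a2$percent)
})

test_that("UpSet table counts exact category combinations with set semantics", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:4), chrom = "chr1",
                      start = c(0, 30000, 60000, 90000),
                      end = c(1000, 31000, 61000, 91000), strand = "+")
  ann <- genome_annotation(genes, c(chr1 = 200000))
  map <- structure(list(map = data.frame(
    gene_id = c("g01", "g01", "g01", "g02", "g03"),
    enhancer_id = 1:5,
    category = c(3L, 3L, 5L, 4L, 4L)),
    n_genes = 4L, n_with_enhancer = 3L, percent = 75.0),
    class = "enhancer_gene_map")
  up <- upset_table(map)
  expect_equal(sum(up$count), 3L)  # rows sum to genes with >= 1 enhancer
  expect_equal(up$count[up$combination == "3,5"], 1L)  # {3,3,5} -> {3,5}
  expect_equal(up$count[up$combination == "4"], 2L)
  expect_equal(up$degree[up$combination == "3,5"], 2L)
})

test_that("set overlap enumerates the Venn partition and drops unmatched ids", {
  ov <- set_overlap(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(ov$count[ov$combination == "A,B"], 1L)
  expect_equal(ov$count[ov$combination == "A"], 1L)
  expect_equal(ov$count[ov$combination == "B"], 1L)
  same <- set_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$combination, "A,B")
  expect_equal(same$count, 2L)

  ov <- set_overlap(list(A = c("a", "zz"), B = "a"), valid_ids = c("a", "b"))
  expect_equal(attr(ov, "n_dropped"), 1L)
  expect_equal(ov$combination, "A,B")

  # four random sets against an inclusion-exclusion (bitmask) oracle
  set.seed(44)
  universe <- sprintf("id%03d", 1:100)
  sets <- lapply(1:4, function(i) sample(universe, sample(20:60, 1)))
  names(sets) <- LETTERS[1:4]
  ov <- set_overlap(sets)
  for (id in unique(unlist(sets))) {
    memb <- paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
                  collapse = ",")
    expect_true(memb %in% ov$combination)
  }
  counts <- setNames(ov$count, ov$combination)
  oracle <- table(vapply(unique(unlist(sets)), function(id)
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = ","), ""))
  expect_equal(counts[names(oracle)], unclass(oracle)[names(oracle)],
               ignore_attr = TRUE)
})
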