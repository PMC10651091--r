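test_that("narrowPeak reading recovers summits from the offset column", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t100\t600\tpk1\t250\t.\t5.5\t-1\t-1\t120",
               "chr1\t1000\t1400\tpk2\t100\t.\t2.0\t-1\t-1\t-1"), path)
  pk <- read_narrowpeak(path, source = "T_NMP")
  expect_equal(pk$summit, c(220, NA))
  expect_equal(pk$source, c("T_NMP", "T_NMP"))
  writeLines("chr1\t100\t600\tpk1\t250\t.\t5.5\t-1\t-1\t900", path)
  expect_error(read_narrowpeak(path), "summit")
})

test_that("blacklist filtering matches the brute-force oracle and never adds peaks", {
  set.seed(31)
  for (rep in 1:10) {
    peaks <- rand_regions(30)
    bl <- rand_regions(5)
    got <- remove_blacklisted(peaks, bl)
    want <- bf_subtract(peaks, bl)
    expect_equal(got$start, want$start)
    expect_lte(nrow(got), nrow(peaks))
    for (i in seq_len(nrow(got)))
      for (j in seq_len(nrow(bl)))
        expect_false(bf_overlaps1(got[i, ], bl[j, ]))
  }
  peaks <- rand_regions(10)
  expect_equal(remove_blacklisted(peaks, peaks[0, ]), peaks)
})

make_peaks <- function(df, source) {
  df$name <- sprintf("%s_%d", source, seq_len(nrow(df)))
  df$score <- if (is.null(df$score)) rep(500, nrow(df)) else df$score
  df$summit <- if (is.null(df$summit)) floor((df$start + df$end) / 2) else df$summit
  df$source <- source
  df
}

test_that("combinatorial profiles flag contributing sources per overlap cluster", {
  t_nmp <- make_peaks(data.frame(chrom = "chr1", start = 100, end = 400), "T_NMP")
  t_notop <- make_peaks(data.frame(chrom = "chr1", start = c(300, 5000),
                                   end = c(600, 5400)), "T_NotoP")
  foxa2 <- make_peaks(data.frame(chrom = c("chr1", "chr2"),
                                 start = c(500, 100), end = c(800, 400)), "Foxa2")
  prof <- combinatorial_profiles(t_nmp, t_notop, foxa2)
  expect_equal(nrow(prof), 3L)
  # transitive cluster 100-800 carries all three sources -> category 3
  all3 <- prof[prof$start == 100 & prof$chrom == "chr1", ]
  expect_true(all3$has_t_nmp && all3$has_t_notop && all3$has_foxa2)
  expect_equal(all3$category, 3L)
  expect_equal(c(all3$start, all3$end), c(100, 800))
  # isolated Foxa2 peak -> category 7
  solo <- prof[prof$chrom == "chr2", ]
  expect_false(solo$has_t_nmp || solo$has_t_notop)
  expect_equal(solo$category, 7L)
  # isolated T_NotoP peak -> category 6
  expect_equal(prof$category[prof$start == 5000], 6L)
})

test_that("profile flags equal a union-find oracle and ignore input order", {
  set.seed(32)
  for (rep in 1:5) {
    sets <- lapply(c("T_NMP", "T_NotoP", "Foxa2"), function(s)
      make_peaks(rand_regions(15, chroms = "chr1", max_pos = 8000,
                              max_len = 400), s))
    prof <- combinatorial_profiles(sets[[1]], sets[[2]], sets[[3]])

    # union-find over pairwise overlaps
    all <- do.call(rbind, lapply(sets, function(p) p[c("chrom", "start", "end", "source")]))
    parent <- seq_len(nrow(all))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(all) - 1)) for (j in (i + 1):nrow(all))
      if (bf_overlaps1(all[i, ], all[j, ])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    roots <- vapply(seq_len(nrow(all)), find, integer(1))
    oracle <- sort(vapply(split(all$source, roots), function(srcs)
      paste(sort(unique(srcs)), collapse = "+"), ""))
    got <- sort(vapply(seq_len(nrow(prof)), function(i)
      paste(sort(c("T_NMP", "T_NotoP", "Foxa2")[c(prof$has_t_nmp[i],
                                                  prof$has_t_notop[i],
                                                  prof$has_foxa2[i])]),
            collapse = "+"), ""))
    expect_equal(got, unname(oracle))

    # clustering is symmetric: shuffling rows within each set changes nothing
    shuf <- lapply(sets, function(p) p[sample(nrow(p)), , drop = FALSE])
    prof2 <- combinatorial_profiles(shuf[[1]], shuf[[2]], shuf[[3]])
    expect_identical(prof[names(prof) != "cluster"],
                     prof2[names(prof2) != "cluster"])
  }
})

test_that("anchors follow the source-precedence and score rules", {
  t_nmp <- make_peaks(data.frame(chrom = "chr1", start = 100, end = 400,
                                 summit = 250, score = 300), "T_NMP")
  foxa2 <- make_peaks(data.frame(chrom = "chr1", start = 300, end = 700,
                                 summit = 500, score = 900), "Foxa2")
  none <- t_nmp[0, ]
  prof <- anchor_maxima(combinatorial_profiles(t_nmp, none, foxa2))
  expect_equal(prof$anchor, 250)  # T_NMP outranks Foxa2 despite lower score

  prof <- anchor_maxima(combinatorial_profiles(none, none, foxa2))
  expect_equal(prof$anchor, 500)  # single option

  # two same-source peaks in one cluster: highest score wins
  t2 <- make_peaks(data.frame(chrom = "chr1", start = c(100, 350),
                              end = c(400, 600), summit = c(250, 450),
                              score = c(300, 800)), "T_NMP")
  prof <- anchor_maxima(combinatorial_profiles(t2, none, none))
  expect_equal(prof$anchor, 450)

  # missing summit falls back to the coverage summit
  t3 <- make_peaks(data.frame(chrom = "chr1", start = 100, end = 400,
                              score = 10), "T_NMP")
  t3$summit <- NA_real_
  prof <- combinatorial_profiles(t3, none, none)
  expect_error(anchor_maxima(prof), "no summit")
  cov <- coverage_track(fragment_set(data.frame(chrom = "chr1", start = 200,
                                                end = 260)),
                        c(chr1 = 1000), 10)
  expect_equal(anchor_maxima(prof, cov)$anchor, 205)
})

test_that("maxima intersection keeps regions containing anchors (half-open)", {
  prof <- data.frame(chrom = "chr1", start = c(1400, 1900, 2900),
                     end = c(1600, 2100, 3100),
                     has_t_nmp = c(FALSE, TRUE, FALSE),
                     has_t_notop = c(TRUE, FALSE, FALSE),
                     has_foxa2 = c(TRUE, FALSE, TRUE),
                     mask = c(6L, 1L, 4L), category = c(5L, 2L, 7L),
                     cluster = 1:3, anchor = c(1500, 2000, 3000))
  dr <- data.frame(chrom = "chr1", start = c(1000, 2500, 4000),
                   end = c(2000, 3500, 4500), direction = "A_up")
  et <- intersect_maxima(prof, dr)
  expect_equal(nrow(et), 2L)  # anchor 2000 == region end is outside
  expect_equal(et$start, c(1000, 2500))
  # region 1 contains only the T_NotoP+Foxa2 anchor
  expect_equal(et$category[1], 5L)
  expect_equal(et$anchor[1], 1500)
  expect_equal(et$category[2], 7L)

  # random fixture: membership equals a brute-force containment scan
  set.seed(33)
  prof <- data.frame(chrom = "chr1", anchor = floor(runif(12, 0, 5000)))
  prof$start <- prof$anchor - 50; prof$end <- prof$anchor + 50
  prof$has_t_nmp <- sample(c(TRUE, FALSE), 12, replace = TRUE)
  prof$has_t_notop <- sample(c(TRUE, FALSE), 12, replace = TRUE)
  prof$has_foxa2 <- !prof$has_t_nmp & !prof$has_t_notop
  prof$mask <- prof$has_t_nmp + 2 * prof$has_t_notop + 4 * prof$has_foxa2
  prof$category <- default_category_map()[as.character(prof$mask)]
  prof$cluster <- 1:12
  dr <- rand_regions(10, chroms = "chr1", max_pos = 5000, max_len = 800)
  et <- intersect_maxima(prof, dr)
  want <- which(vapply(seq_len(nrow(dr)), function(i)
    any(prof$anchor >= dr$start[i] & prof$anchor < dr$end[i]), logical(1)))
  expect_equal(nrow(et), length(want))
  expect_equal(et$start, dr$start[want])
})

test_that("category fractions partition the table and report one decimal", {
  tab <- table_from_category_counts(c(3, 2, 5, 1, 4, 2, 3))
  fr <- category_fractions(tab, list(g1 = c(2, 4, 6), g2 = 7,
                                     g3 = c(1, 3, 5)))
  expect_equal(sum(fr$count), nrow(tab))  # groups partition {1..7}
  expect_equal(fr$percent[fr$group == "g2"],
               round(100 * 3 / 20, 1))
  all_one <- category_fractions(tab, list(everything = 1:7))
  expect_equal(all_one$percent, 100.0)
  expect_error(category_fractions(tab[0, ], list(a = 1)), "empty")
})

test_that("category map must be a bijection", {
  bad <- default_category_map()
  bad[1] <- 3L
  expect_error(combinatorial_profiles(NULL, NULL, NULL, category_map = bad),
               "bijection")
})
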