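test_that("two-list Venn regions and coefficients match the cohort-scale example", {
  # two top-500 lists sharing 198 genes
  a <- sprintf("G%04d", 1:500)
  b <- c(sprintf("G%04d", 1:198), sprintf("H%04d", 1:302))
  ov <- venn_overlap(list(A = a, B = b))
  expect_identical(unname(ov$region_counts[c("A_only", "AB", "B_only")]),
                   c(302L, 198L, 302L))
  expect_equal(ov$overlap_coefficient, 0.396)
  expect_equal(ov$jaccard, 198 / 802)
  # identical lists
  same <- venn_overlap(list(A = a, B = a))
  expect_equal(same$overlap_coefficient, 1)
  expect_identical(unname(same$region_counts["AB"]), 500L)
  # empty list flagged with zero coefficients
  expect_warning(venn_overlap(list(A = c("x", "x"), B = "y")),
                 "duplicates")
  empt <- venn_overlap(list(A = character(0), B = c("y", "z")))
  expect_identical(empt$overlap_coefficient, 0)
  expect_true("empty-list" %in% empt$flags)
})

test_that("three-list Venn reproduces pairwise intersection totals", {
  # top-500 lists: young cohort shares 92 with D and 52 with ND
  young <- sprintf("Y%04d", 1:500)
  d <- c(young[1:92], sprintf("D%04d", 1:408))
  nd <- c(young[93:144], sprintf("N%04d", 1:448))
  ov <- venn_overlap(list(young = young, D = d, ND = nd))
  rc <- ov$region_counts
  expect_identical(unname(rc["AB"] + rc["ABC"]), 92L)
  expect_identical(unname(rc["AC"] + rc["ABC"]), 52L)
  expect_identical(sum(rc), length(unique(c(young, d, nd))))
})

test_that("Venn regions equal brute-force set arithmetic on random lists", {
  set.seed(77)
  pool <- sprintf("G%03d", 1:120)
  for (i in 1:200) {
    a <- sample(pool, sample(5:60, 1))
    b <- sample(pool, sample(5:60, 1))
    c_ <- sample(pool, sample(5:60, 1))
    ov <- venn_overlap(list(A = a, B = b, C = c_))
    rc <- ov$region_counts
    expect_identical(unname(rc["A_only"]),
                     length(setdiff(setdiff(a, b), c_)))
    expect_identical(unname(rc["AB"]),
                     length(setdiff(intersect(a, b), c_)))
    expect_identical(unname(rc["ABC"]),
                     length(intersect(intersect(a, b), c_)))
    expect_identical(sum(rc), length(union(union(a, b), c_)))
  }
})

test_that("similarity matrix equals pairwise overlap coefficients", {
  lists <- list(x = sprintf("G%02d", 1:20), y = sprintf("G%02d", 11:40),
                z = sprintf("H%02d", 1:10))
  m <- similarity_matrix(lists)
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m, t(m))
  expect_equal(m["x", "y"],
               venn_overlap(lists[c("x", "y")])$overlap_coefficient)
  expect_equal(m["x", "z"], 0) # disjoint
  # nested lists: coefficient 1 by the min denominator
  nested <- similarity_matrix(list(a = sprintf("G%02d", 1:5),
                                   b = sprintf("G%02d", 1:20)))
  expect_equal(nested["a", "b"], 1)
})

test_that("r-distribution comparison detects shifts and is antisymmetric", {
  set.seed(15)
  a <- rnorm(500, 0.3, 0.1)
  self <- compare_r_distributions(a, a)
  expect_equal(self$median_difference, 0)
  expect_gt(self$p_value, 0.9)
  b <- a + 0.2
  shift <- compare_r_distributions(b, a)
  expect_lt(shift$p_value, 0.001)
  expect_gt(shift$median_difference, 0.19)
  swapped <- compare_r_distributions(a, b)
  expect_equal(swapped$median_difference, -shift$median_difference)
  expect_equal(swapped$p_value, shift$p_value)
  # degenerate all-equal input
  deg <- compare_r_distributions(rep(0.5, 20), rep(0.5, 20))
  expect_equal(deg$p_value, 1)
  expect_identical(deg$flag, "degenerate-all-equal")
  expect_error(compare_r_distributions(a[1:5], a), ">= 10")
  welch <- compare_r_distributions(b, a, test = "welch_t")
  expect_lt(welch$p_value, 0.001)
})

test_that("median split halves distinct values and sends ties to Lo", {
  # even cohorts with distinct values split exactly in half
  for (n in c(152L, 180L)) {
    v <- stats::setNames(seq_len(n) / 10, sprintf("S%04d", seq_len(n)))
    ms <- median_split(sample(v))
    expect_identical(length(ms$lo_samples), n %/% 2L)
    expect_identical(length(ms$hi_samples), n %/% 2L)
    expect_length(intersect(ms$lo_samples, ms$hi_samples), 0L)
  }
  # ties at the median go to Lo
  v <- stats::setNames(c(1, 2, 2, 3), sprintf("S%d", 1:4))
  ms <- median_split(v)
  expect_identical(sort(ms$lo_samples), c("S1", "S2", "S3"))
  expect_identical(ms$hi_samples, "S4")
  # guards
  expect_error(median_split(v[1:3]), ">= 4")
  expect_error(median_split(stats::setNames(rep(1, 6),
                                            sprintf("S%d", 1:6))),
               "identical")
})

test_that("median split respects stratum filters", {
  set.seed(2)
  md <- data.frame(sample_id = sprintf("S%03d", 1:40),
                   donor_id = sprintf("D%03d", 1:40),
                   dementia = rep(c("D", "ND"), 20),
                   stringsAsFactors = FALSE)
  v <- stats::setNames(rnorm(40), md$sample_id)
  ms <- median_split(v, md, c(dementia = "D"))
  expect_identical(length(ms$lo_samples) + length(ms$hi_samples), 20L)
  expect_true(all(md$dementia[match(c(ms$lo_samples, ms$hi_samples),
                                    md$sample_id)] == "D"))
})

test_that("marker tests detect planted group differences and flag gaps", {
  set.seed(44)
  n <- 100
  md <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   donor_id = sprintf("D%03d", 1:n),
                   stringsAsFactors = FALSE)
  guide <- stats::setNames(rnorm(n), md$sample_id)
  ms <- median_split(guide)
  hi <- md$sample_id %in% ms$hi_samples
  md$shifted <- rnorm(n) + 2 * hi        # Hi + 2 pooled sd
  md$nullmk <- rnorm(n)                  # no effect
  md$sparse <- ifelse(seq_len(n) <= 2, 1, NA) # nearly all missing
  res <- marker_tests(ms, md, c("shifted", "nullmk", "sparse"))
  tests <- res$tests
  expect_lt(tests$p_value[tests$marker == "shifted"], 0.001)
  expect_gt(tests$mean_hi[tests$marker == "shifted"],
            tests$mean_lo[tests$marker == "shifted"])
  expect_gt(tests$p_value[tests$marker == "nullmk"], 0.001)
  expect_identical(tests$flag[tests$marker == "sparse"],
                   "insufficient-values")
  expect_true(is.na(tests$p_value[tests$marker == "sparse"]))
  expect_warning(marker_tests(ms, md, c("shifted", "ghost")), "ghost")
  # nonparametric option
  mw <- marker_tests(ms, md, "shifted", test = "mann_whitney")
  expect_lt(mw$tests$p_value[1], 0.001)
})

test_that("marker test p-values are uniform under a global null", {
  set.seed(123)
  n <- 40
  md_base <- data.frame(sample_id = sprintf("S%02d", 1:n),
                        donor_id = sprintf("D%02d", 1:n),
                        stringsAsFactors = FALSE)
  pvals <- vapply(1:2000, function(i) {
    guide <- stats::setNames(rnorm(n), md_base$sample_id)
    md <- md_base
    md$mk <- rnorm(n)
    ms <- median_split(guide)
    marker_tests(ms, md, "mk")$tests$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("guide-marker correlation recovers exact and null relationships", {
  g <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(guide_marker_correlation(g, g)$r, 1)
  expect_equal(guide_marker_correlation(g, -g)$r, -1)
  set.seed(6)
  gm <- guide_marker_correlation(rnorm(500), rnorm(500))
  expect_lt(abs(gm$r), 0.15)
  expect_identical(gm$n, 500L)
  # missing pairs dropped; too few pairs is an error
  expect_identical(
    guide_marker_correlation(c(g, NA), c(1, NA, 3, 4, 5, 6, 7, 8))$n, 6L)
  expect_error(guide_marker_correlation(c(1, 2, NA), c(1, NA, 3)),
               ">= 3 complete pairs")
  sp <- guide_marker_correlation(g, g^3, method = "spearman")
  expect_equal(sp$r, 1)
})
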