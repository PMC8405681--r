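test_that("enrichment score reproduces hand-computed running sums", {
  p <- make_profile(c(5, 4, 3, 2, 1))
  # set at ranks {1, 3}: P_hit jumps 5/8 then 1; extreme deviation 2/3
  es13 <- enrichment_score(p, p$entries$gene_id[c(1, 3)])
  expect_equal(es13$ES, 2 / 3, tolerance = 1e-12)
  # set at ranks {4, 5}: all misses precede all hits -> ES = -1
  es45 <- enrichment_score(p, p$entries$gene_id[c(4, 5)])
  expect_equal(es45$ES, -1, tolerance = 1e-12)
  expect_identical(sort(es45$leading_edge),
                   sort(p$entries$gene_id[c(4, 5)]))
  # singleton at the top: P_hit jumps to 1 at position 1
  es1 <- enrichment_score(p, p$entries$gene_id[1])
  expect_equal(es1$ES, 1, tolerance = 1e-12)
  expect_identical(es1$leading_edge, p$entries$gene_id[1])
  # degenerate guards
  expect_error(enrichment_score(p, p$entries$gene_id), "whole ranked list")
  expect_error(enrichment_score(p, "NOT_A_GENE"), "no gene")
})

test_that("enrichment score equals exhaustive evaluation for every proper subset", {
  z <- c(3.1, 2.3, 1.7, 1.1, 0.6, -0.2, -0.9, -1.4, -2.2, -3.0)
  p <- make_profile(z)
  ids <- p$entries$gene_id
  n <- length(ids)
  worst <- 0
  for (code in 1:(2^n - 2)) {
    hit <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    es <- enrichment_score(p, ids[hit])$ES
    worst <- max(worst, abs(es - oracle_es(z, hit)))
  }
  expect_lt(worst, 1e-12)
})

test_that("ES stays in [-1, 1] and is antisymmetric under list reversal at w = 0", {
  set.seed(17)
  for (trial in 1:25) {
    z <- sort(rnorm(40), decreasing = TRUE)
    p <- make_profile(z)
    ids <- p$entries$gene_id
    set_ids <- sample(ids, sample(2:15, 1))
    es <- enrichment_score(p, set_ids, weight_exponent = 0)$ES
    expect_gte(es, -1); expect_lte(es, 1)
    p_rev <- make_profile(rev(z), gene_ids = rev(ids))
    es_rev <- enrichment_score(p_rev, set_ids, weight_exponent = 0)$ES
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("running sum output matches its own extremum bookkeeping", {
  set.seed(23)
  z <- sort(rnorm(100), decreasing = TRUE)
  p <- make_profile(z)
  set_ids <- sample(p$entries$gene_id, 12)
  es <- enrichment_score(p, set_ids)
  expect_false(es$ES == 0) # no tied extrema in this fixture
  dev <- c(0, es$running_sum)
  expect_equal(max(abs(dev)), abs(es$ES), tolerance = 1e-12)
  expect_equal(es$running_sum[length(es$running_sum)], 0,
               tolerance = 1e-12)
})

test_that("permutation null is deterministic and NES obeys its definition", {
  set.seed(3)
  z <- sort(rnorm(200), decreasing = TRUE)
  p <- make_profile(z)
  set_ids <- p$entries$gene_id[c(1:5, 8, 13, 30, 77, 150)]
  cfg <- enrichment_config(n_permutations = 500, seed = 11)
  a <- permutation_null(p, set_ids, cfg, keep_perm = TRUE)
  b <- permutation_null(p, set_ids, cfg)
  expect_identical(a[c("ES", "NES", "p_nominal")],
                   b[c("ES", "NES", "p_nominal")])
  # NES and p recomputed from the returned permutation scores
  same <- a$perm_es[a$perm_es >= 0]
  expect_equal(a$NES, a$ES / mean(abs(same)), tolerance = 1e-12)
  expect_equal(a$p_nominal,
               (1 + sum(abs(same) >= abs(a$ES))) / (1 + length(same)),
               tolerance = 1e-12)
  # observed ES beyond every same-sign permutation -> p at the floor
  top <- permutation_null(p, p$entries$gene_id[1:10], cfg,
                          keep_perm = TRUE)
  n_same <- sum(top$perm_es >= 0)
  expect_equal(top$p_nominal, 1 / (n_same + 1), tolerance = 1e-12)
})

test_that("restriction intersects both directions and drops small sets", {
  p <- make_profile(sort(rnorm(30), decreasing = TRUE))
  ids <- p$entries$gene_id
  coll <- gene_set_collection(list(
    big = ids[1:10], tiny = ids[1:2],
    absent = c("X1", "X2", "X3", "X4", "X5"),
    mixed = c(ids[5:12], "X9")))
  res <- restrict_to_measured(coll, p, min_set_size = 3,
                              max_set_size = 25)
  expect_identical(sort(names(res$collection$sets)), c("big", "mixed"))
  expect_identical(res$collection$sets$mixed, ids[5:12])
  # ranked list restricted to genes in >= 1 retained set
  expect_identical(res$profile$entries$gene_id,
                   ids[ids %in% union(ids[1:10], ids[5:12])])
  expect_identical(res$profile$entries$rank,
                   seq_len(nrow(res$profile$entries)))
  # brute-force sizes agree
  log <- res$log
  expect_identical(log$size_measured[log$set_name == "absent"], 0L)
  expect_identical(log$size_measured[log$set_name == "mixed"], 8L)
  expect_error(restrict_to_measured(
    gene_set_collection(list(a = c("X1", "X2", "X3"))), p, 3, 25),
    "no gene set")
})

test_that("BH adjustment matches the literal step-up on known and random inputs", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("run_enrichment ranks a planted set first and is order invariant", {
  set.seed(5)
  n <- 400
  z <- sort(rnorm(n), decreasing = TRUE)
  p <- make_profile(z)
  ids <- p$entries$gene_id
  planted <- ids[sort(sample(1:40, 20))] # concentrated at the top
  decoys <- lapply(1:19, function(i) sample(ids, 20))
  names(decoys) <- sprintf("DECOY_%02d", 1:19)
  coll <- gene_set_collection(c(list(PLANTED = planted), decoys))
  cfg <- enrichment_config(n_permutations = 2000, min_set_size = 5,
                           max_set_size = 200, seed = 42)
  tab <- run_enrichment(p, coll, cfg)
  expect_s3_class(tab, "EnrichmentTable")
  expect_identical(nrow(tab), 20L)
  best <- tab$set_name[which.max(tab$NES)]
  expect_identical(best, "PLANTED")
  expect_lte(tab$p_adjusted[tab$set_name == "PLANTED"], 0.05)
  # invariant to the order sets appear in the collection
  coll_rev <- gene_set_collection(rev(coll$sets))
  tab_rev <- run_enrichment(p, coll_rev, cfg)
  expect_equal(as.data.frame(tab)[names(tab)],
               as.data.frame(tab_rev)[names(tab_rev)],
               tolerance = 1e-15)
  # full determinism
  tab2 <- run_enrichment(p, coll, cfg)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # empty collection after restriction
  tiny <- gene_set_collection(list(s = ids[1:3]))
  expect_error(run_enrichment(p, tiny, cfg), "no gene set")
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  z <- sort(rnorm(300), decreasing = TRUE)
  p <- make_profile(z)
  ids <- p$entries$gene_id
  stats <- stats::setNames(z, ids)
  for (trial in 1:20) {
    set_ids <- sample(ids, sample(5:50, 1))
    ours <- enrichment_score(p, set_ids)$ES
    if (ours == 0) next # tied extrema resolve by exact equality in fgsea
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(ids %in% set_ids),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("significant and top pathway helpers slice the table correctly", {
  tab <- data.frame(set_name = c("a", "b", "c", "d"),
                    size_measured = 10L, ES = c(0.5, -0.4, 0.3, -0.6),
                    NES = c(2.5, -1.9, 1.2, -2.8),
                    p_nominal = c(0.001, 0.01, 0.2, 0.0005),
                    p_adjusted = c(0.004, 0.02, 0.26, 0.002),
                    leading_edge = "", stringsAsFactors = FALSE)
  class(tab) <- c("EnrichmentTable", "data.frame")
  expect_identical(significant_sets(tab)$set_name, c("a", "b", "d"))
  expect_identical(top_pathways(tab, 2)$set_name, c("d", "a"))
  expect_identical(top_pathways(tab, 2, "positive")$set_name, c("a", "c"))
})
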