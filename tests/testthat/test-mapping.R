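test_that("co-occurrence similarity follows the Dice formula and its bounds", {
  expect_equal(cooccurrence_similarity(5, 5, 5), 1)
  expect_equal(cooccurrence_similarity(1, 100, 100), 0.01)
  expect_equal(cooccurrence_similarity(2, 4, 4), 0.5)
  expect_error(cooccurrence_similarity(0, 3, 3))
  expect_error(cooccurrence_similarity(5, 4, 4))
  withr::with_seed(1, {
    for (i in 1:50) {
      a <- sample(25:200, 1); b <- sample(25:200, 1)
      expect_equal(cooccurrence_similarity(25, a, b), 2 * 25 / (a + b))
    }
  })
  # monotone in support at fixed marginals
  s_vals <- cooccurrence_similarity(1:5, 10, 10)
  expect_true(all(diff(s_vals) > 0))
})

test_that("a singleton corpus yields one mapping with S = 1", {
  corpus <- annotation_corpus(list(p1 = "d1"), list(p1 = "g1"))
  tab <- build_initial_mappings(corpus)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 1L)
  expect_equal(tab$s, 1)
})

test_that("marginals count each map's full protein set", {
  # d1 on p1..p4, g1 on p3..p6: co-annotated {p3, p4}
  corpus <- annotation_corpus(
    stats::setNames(rep(list("d1"), 4), sprintf("p%d", 1:4)),
    stats::setNames(rep(list("g1"), 4), sprintf("p%d", 3:6)))
  tab <- build_initial_mappings(corpus)
  expect_equal(tab$n, 2L)
  expect_equal(tab$n_domain, 4L)
  expect_equal(tab$n_go, 4L)
  expect_equal(tab$s, 0.5)
})

test_that("initial mappings equal the brute-force double loop", {
  for (seed in c(11, 12, 13)) {
    corpus <- random_corpus(seed)
    tab <- build_initial_mappings(corpus)
    oracle <- oracle_mapping_table(corpus)
    expect_equal(as.data.frame(tab)[names(oracle)], oracle, info = seed)
  }
  expect_error(
    build_initial_mappings(annotation_corpus(list(p1 = "d1"),
                                             list(p2 = "g1"))),
    "no protein")
})

test_that("record-level randomization is seeded and conserves record marginals", {
  corpus <- random_corpus(21)
  tab <- build_initial_mappings(corpus)
  r1 <- randomize_mappings(tab, seed = 7)
  r2 <- randomize_mappings(tab, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "provenance"), "randomized")
  r3 <- randomize_mappings(tab, seed = 8)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
  rec0 <- attr(tab, "records")
  rec1 <- attr(r1, "records")
  expect_equal(nrow(rec1), nrow(rec0))
  expect_equal(sort(rec1$domain_id), sort(rec0$domain_id))
  expect_equal(sort(rec1$go_id), sort(rec0$go_id))
  expect_error(randomize_mappings(r1, seed = 1), "original")
})

test_that("pair-level randomization permutes the table in place", {
  tab <- fake_mapping_table(s = seq(0.1, 1, length.out = 10), n = 2:11)
  r <- randomize_mappings(tab, seed = 3, unit = "pair")
  expect_equal(nrow(r), nrow(tab))
  expect_equal(sort(r$domain_id), sort(tab$domain_id))
  expect_equal(sort(r$go_id), sort(tab$go_id))
  expect_equal(sort(r$n), sort(tab$n))
})

test_that("single-row table randomizes to itself", {
  corpus <- annotation_corpus(list(p1 = "d1"), list(p1 = "g1"))
  tab <- build_initial_mappings(corpus)
  r <- randomize_mappings(tab, seed = 42)
  expect_equal(as.data.frame(r), as.data.frame(tab), ignore_attr = TRUE)
  expect_identical(attr(r, "provenance"), "randomized")
})

test_that("KS statistic matches an explicit ECDF sweep", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_gt(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
  withr::with_seed(4, {
    a <- runif(50); b <- rbeta(50, 2, 1)
  })
  expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_statistic(a, b))
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("threshold selection picks the minimal separating pair", {
  withr::with_seed(42, {
    orig <- fake_mapping_table(s = runif(150, 0.75, 0.98),
                               n = sample(2:6, 150, TRUE))
    rand <- fake_mapping_table(s = runif(150, 0.02, 0.22),
                               n = sample(2:6, 150, TRUE))
  })
  sel <- select_thresholds(orig, rand)
  expect_false(sel$no_separation)
  expect_equal(sel$selected, list(s_min = 0.1, n_min = 1L),
               ignore_attr = TRUE)
  expect_equal(nrow(sel$grid), 30L)
  # identical distributions cannot reject
  sel0 <- select_thresholds(orig, orig)
  expect_true(sel0$no_separation)
  expect_null(sel0$selected)
  # degenerate single-cell grid with alpha = 1 trivially selects whenever the
  # cell is testable (here: two overlapping but distinct distributions)
  withr::with_seed(43, {
    rand2 <- fake_mapping_table(s = runif(150, 0.4, 0.9),
                                n = sample(2:6, 150, TRUE))
  })
  sel1 <- select_thresholds(orig, rand2, s_grid = 0.3, n_grid = 2L, alpha = 1)
  expect_equal(sel1$selected$s_min, 0.3)
  # cells that empty a table are untestable, not errors
  sel2 <- select_thresholds(orig, rand, s_grid = 0.99, n_grid = 10L)
  expect_false(any(sel2$grid$testable))
})

test_that("filtering is strict on S, inclusive on n, and monotone", {
  tab <- fake_mapping_table(s = c(0.2, 0.21, 0.5, 0.19, 0.3),
                            n = c(5L, 1L, 2L, 2L, 2L))
  out <- filter_mappings(tab, s_min = 0.2, n_min = 2L)
  expect_equal(out$s, c(0.5, 0.3))          # 0.2 exact and n=1 both dropped
  expect_equal(nrow(filter_mappings(tab, s_min = 0, n_min = 1L)), nrow(tab))
  for (s_min in c(0, 0.2, 0.4)) {
    a <- nrow(filter_mappings(tab, s_min, 1L))
    b <- nrow(filter_mappings(tab, s_min + 0.1, 1L))
    expect_lte(b, a)
    expect_lte(nrow(filter_mappings(tab, s_min, 3L)), a)
  }
})

test_that("mapping tables round-trip through TSV", {
  corpus <- random_corpus(31)
  tab <- build_initial_mappings(corpus)
  path <- tempfile(fileext = ".tsv")
  write_mapping_table(tab, path)
  back <- read_mapping_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
})
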