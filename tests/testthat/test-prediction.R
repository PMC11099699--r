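test_that("min-max scaling maps onto (floor, 1] and preserves order", {
  expect_equal(minmax_scale(c(2, 4, 6), floor = 0.01), c(0.01, 0.505, 1))
  expect_equal(minmax_scale(c(7, 7, 7)), c(1, 1, 1))
  withr::with_seed(2, x <- rnorm(50))
  y <- minmax_scale(x)
  expect_equal(cor(rank(x), rank(y)), 1)
  expect_true(all(y >= 0.01 & y <= 1))
})

test_that("predictions propagate mapping scores to domain-bearing proteins", {
  dag <- toy_dag()
  maps <- fake_mapping_table(s = 0.39, n = 25L,
                             domain_id = "d1", go_id = "GO:0000005")
  preds <- predict_functions(maps, list(p1 = "d1", p2 = "dX"), dag = dag,
                             score_mode = "S")
  # p2 carries no mapped domain; p1 gets the term and its non-root ancestors
  expect_setequal(preds$protein_id, "p1")
  expect_setequal(preds$go_id, c("GO:0000005", "GO:0000004", "GO:0000003",
                                 "GO:0000002"))
  expect_true(all(preds$score == 0.39))
})

test_that("multiple domains reaching one term keep the maximum score", {
  maps <- fake_mapping_table(s = c(0.3, 0.7), n = c(2L, 3L),
                             domain_id = c("d1", "d2"),
                             go_id = c("g1", "g1"))
  preds <- predict_functions(maps, list(p1 = c("d1", "d2")))
  expect_equal(nrow(preds), 1L)
  expect_equal(preds$score, 0.7)
})

test_that("the prediction join equals a brute-force two-table join", {
  withr::with_seed(23, {
    maps <- fake_mapping_table(
      s = runif(12, 0.2, 0.9), n = sample(2:5, 12, TRUE),
      domain_id = sample(sprintf("d%d", 1:4), 12, TRUE),
      go_id = sample(sprintf("g%d", 1:6), 12, TRUE))
    maps <- maps[!duplicated(paste(maps$domain_id, maps$go_id)), ]
    pd <- lapply(1:5, function(i) sample(sprintf("d%d", 1:4),
                                         sample(1:2, 1)))
    names(pd) <- sprintf("p%d", 1:5)
  })
  preds <- predict_functions(maps, pd)
  want <- list()
  for (p in names(pd)) {
    for (i in seq_len(nrow(maps))) {
      if (maps$domain_id[[i]] %in% pd[[p]]) {
        k <- paste(p, maps$go_id[[i]])
        want[[k]] <- max(want[[k]] %||% 0, maps$s[[i]])
      }
    }
  }
  got <- stats::setNames(preds$score, paste(preds$protein_id, preds$go_id))
  expect_mapequal(as.list(got), want)
})

test_that("E-mode predictions use min-max scaled evidence", {
  maps <- fake_mapping_table(s = c(0.5, 0.6, 0.7), n = c(2L, 2L, 2L),
                             domain_id = c("d1", "d2", "d3"),
                             go_id = c("g1", "g2", "g3"))
  expect_error(predict_functions(maps, list(p1 = "d1"), score_mode = "E"),
               "'e' column")
  maps$e <- c(2, 4, 6)
  preds <- predict_functions(maps, list(p1 = c("d1", "d2", "d3")),
                             score_mode = "E")
  expect_equal(sort(preds$score), c(0.01, 0.505, 1))
  # reference mode scores everything at 1
  ref_preds <- predict_functions(maps, list(p1 = "d1"),
                                 score_mode = "reference")
  expect_equal(ref_preds$score, 1)
})

test_that("DAG-consistency raises ancestors to the best child score", {
  dag <- toy_dag()
  maps <- fake_mapping_table(s = c(0.8, 0.3), n = c(3L, 2L),
                             domain_id = c("d1", "d1"),
                             go_id = c("GO:0000005", "GO:0000003"))
  preds <- predict_functions(maps, list(p1 = "d1"), dag = dag)
  sc <- stats::setNames(preds$score, preds$go_id)
  expect_equal(unname(sc[["GO:0000003"]]), 0.8)  # lifted above its own 0.3
  expect_equal(unname(sc[["GO:0000005"]]), 0.8)
  expect_false("GO:0000001" %in% preds$go_id)    # root excluded
  # per protein, every parent scores at least its child
  for (i in seq_len(nrow(preds))) {
    anc <- setdiff(ancestors(dag, preds$go_id[[i]]), unname(dag$roots))
    if (length(anc))
      expect_true(all(sc[anc] >= preds$score[[i]]))
  }
})

test_that("naive baseline scores terms by training frequency", {
  train <- list(p1 = c("g1", "root"), p2 = c("g1", "g2", "root"),
                p3 = "root", p4 = c("g2", "root"))
  preds <- naive_baseline(train, targets = c("t1", "t2"))
  sc <- preds[preds$protein_id == "t1", ]
  lk <- stats::setNames(sc$score, sc$go_id)
  expect_equal(unname(lk[["g1"]]), 0.5)
  expect_equal(unname(lk[["g2"]]), 0.5)
  expect_equal(unname(lk[["root"]]), 1)
  # identical across targets
  sc2 <- preds[preds$protein_id == "t2", ]
  expect_equal(sc2$score[order(sc2$go_id)], sc$score[order(sc$go_id)])
  expect_error(naive_baseline(list(), "t1"), "empty")
})

test_that("hybrid merge keeps maxima and is idempotent and commutative", {
  a <- domap:::new_prediction_set(
    data.frame(protein_id = c("p1", "p1"), go_id = c("g1", "g2"),
               score = c(0.3, 0.5), stringsAsFactors = FALSE), mode = "S")
  b <- domap:::new_prediction_set(
    data.frame(protein_id = c("p1", "p2"), go_id = c("g1", "g3"),
               score = c(0.8, 0.4), stringsAsFactors = FALSE), mode = "naive")
  m <- merge_hybrid(list(a, b))
  lk <- stats::setNames(m$score, paste(m$protein_id, m$go_id))
  expect_equal(unname(lk[["p1 g1"]]), 0.8)
  expect_equal(nrow(m), 3L)
  expect_equal(as.data.frame(merge_hybrid(list(a, a))), as.data.frame(a),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(merge_hybrid(list(a, b))),
               as.data.frame(merge_hybrid(list(b, a))), ignore_attr = TRUE)
  expect_error(merge_hybrid(list(a)), "at least two")
})

test_that("predictions round-trip through the CAFA-style TSV", {
  a <- domap:::new_prediction_set(
    data.frame(protein_id = c("p1", "p2"), go_id = c("g1", "g2"),
               score = c(0.123456, 1), stringsAsFactors = FALSE), mode = "S")
  path <- tempfile(fileext = ".tsv")
  write_predictions(a, path)
  back <- read_predictions(path)
  expect_equal(as.data.frame(back), as.data.frame(a), tolerance = 1e-6)
})
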