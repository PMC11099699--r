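test_that("triplets enumerate the co-annotation Cartesian product", {
  corpus <- annotation_corpus(list(p1 = "d1"), list(p1 = "g1"))
  ts <- build_triplets(corpus)
  expect_equal(nrow(ts$records), 1L)
  expect_equal(nrow(ts$pairs), 1L)

  corpus2 <- annotation_corpus(list(p1 = c("d1", "d2")),
                               list(p1 = c("g1", "g2", "g3")))
  ts2 <- build_triplets(corpus2)
  expect_equal(nrow(ts2$records), 6L)
  expect_equal(nrow(ts2$pairs), 6L)

  # matches an exhaustive triple loop on a random corpus
  corpus3 <- random_corpus(17)
  ts3 <- build_triplets(corpus3)
  info <- oracle_em_setup(corpus3)
  got <- sort(paste(ts3$records$domain_id, ts3$records$protein_id,
                    ts3$records$go_id))
  want <- sort(vapply(info$trips,
                      function(t) paste(t[["d"]], t[["p"]], t[["g"]]),
                      character(1)))
  expect_equal(got, want)

  # restriction limits the generated pairs
  keep <- ts3$pairs[1:2, ]
  ts4 <- build_triplets(corpus3, restrict_to = keep)
  expect_true(all(pairkey <- paste(ts4$records$domain_id, ts4$records$go_id)
                  %in% paste(keep$domain_id, keep$go_id)))
})

test_that("theta initialization is the Jaccard index of the protein sets", {
  # domain on {p1,p2,p3}, term on {p2,p3,p4}: M=2, K=0, Z=2, theta = 0.5
  corpus <- annotation_corpus(
    list(p1 = "d1", p2 = "d1", p3 = "d1"),
    list(p2 = "g1", p3 = "g1", p4 = "g1"))
  tm <- initialize_theta(build_triplets(corpus), corpus)
  expect_equal(tm$pairs$M, 2)
  expect_equal(tm$pairs$K, 0)
  expect_equal(tm$pairs$Z, 2L)
  expect_equal(tm$pairs$theta_init, 0.5)

  # identical protein sets: Z = 0, theta = 1
  corpus2 <- annotation_corpus(list(p1 = "d1", p2 = "d1"),
                               list(p1 = "g1", p2 = "g1"))
  tm2 <- initialize_theta(build_triplets(corpus2), corpus2)
  expect_equal(tm2$pairs$theta_init, 1)

  # property: equals an independently computed Jaccard on random corpora
  for (seed in c(41, 42)) {
    corpus3 <- random_corpus(seed)
    tm3 <- initialize_theta(build_triplets(corpus3), corpus3)
    for (i in seq_len(nrow(tm3$pairs))) {
      expect_equal(tm3$pairs$theta_init[[i]],
                   oracle_jaccard(corpus3, tm3$pairs$domain_id[[i]],
                                  tm3$pairs$go_id[[i]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("log-likelihood sums hand-computable pair contributions", {
  corpus <- single_pair_corpus(1, 0)    # M=1, Z=1
  tm <- initialize_theta(build_triplets(corpus), corpus)
  expect_equal(tm$pairs$theta, 0.5)
  expect_equal(log_likelihood(tm, em_config()), 2 * log(0.5))

  # all theta = 1 with K = Z = 0 contributes zero when alpha = 0
  corpus2 <- annotation_corpus(list(p1 = "d1"), list(p1 = "g1"))
  tm2 <- initialize_theta(build_triplets(corpus2), corpus2)
  expect_equal(log_likelihood(tm2, em_config()), 0)

  # five-pair fixture against a spreadsheet-style sum
  corpus3 <- random_corpus(55, n_prot = 10L, n_dom = 3L, n_go = 3L)
  tm3 <- initialize_theta(build_triplets(corpus3), corpus3)
  cfg <- em_config(alpha = 0.5, beta = 0.25)
  eps <- cfg$epsilon
  by_hand <- 0
  for (i in seq_len(nrow(tm3$pairs))) {
    r <- tm3$pairs[i, ]
    by_hand <- by_hand + (r$M + 0.5) * log(max(r$theta, eps)) +
      (r$K + r$Z + 0.25) * log(max(1 - r$theta, eps))
  }
  expect_equal(log_likelihood(tm3, cfg), by_hand)
})

test_that("a lone pair saturates to its fixed point in one iteration", {
  # single co-annotated protein, no competitors: U = theta/theta = 1,
  # then theta = 1/(1+Z)
  for (z in c(0L, 1L, 2L, 3L, 5L)) {
    corpus <- single_pair_corpus(z, 0)
    ts <- build_triplets(corpus)
    tm <- initialize_theta(ts, corpus)
    tm1 <- em_iterate(tm, ts, em_config())
    expect_equal(tm1$pairs$theta, 1 / (1 + z), info = z)
    tm2 <- em_iterate(tm1, ts, em_config())
    expect_equal(tm2$pairs$theta, 1 / (1 + z), info = z)   # stable
  }
})

test_that("pinned pairs stay at zero through iterations", {
  corpus <- three_pair_corpus()
  ts <- build_triplets(corpus)
  tm <- initialize_theta(ts, corpus)
  pin <- c("d1", "g1")
  for (i in 1:5) tm <- em_iterate(tm, ts, em_config(), pinned_zero = pin)
  i <- which(tm$pairs$domain_id == "d1" & tm$pairs$go_id == "g1")
  expect_equal(tm$pairs$theta[[i]], 0)
  expect_true(all(tm$pairs$theta[-i] > 0))
})

test_that("EM conserves M + K = n and keeps responsibilities in [0, 1]", {
  for (seed in c(61, 62)) {
    corpus <- random_corpus(seed)
    ts <- build_triplets(corpus)
    tm <- initialize_theta(ts, corpus)
    for (i in 1:8) {
      tm <- em_iterate(tm, ts, em_config())
      expect_true(all(abs(tm$pairs$M + tm$pairs$K - tm$pairs$n) < 1e-12))
      expect_true(all(tm$pairs$theta >= 0 & tm$pairs$theta <= 1))
      expect_true(all(tm$pairs$M >= -1e-12 & tm$pairs$K >= -1e-12))
    }
  }
})

test_that("run_em converges with a non-decreasing likelihood trace", {
  # saturated case: every protein carries exactly its own exclusive pair
  corpus <- annotation_corpus(
    list(p1 = "d1", p2 = "d2", p3 = "d3"),
    list(p1 = "g1", p2 = "g2", p3 = "g3"))
  tm <- run_em(build_triplets(corpus), corpus)
  expect_true(all(tm$pairs$theta == 1))

  for (seed in c(71, 72, 73)) {
    corpus2 <- random_corpus(seed)
    tm2 <- run_em(build_triplets(corpus2), corpus2,
                  em_config(max_iterations = 40L))
    expect_true(all(diff(tm2$trace) >= -1e-9), info = seed)
  }
})

test_that("exclusive support wins the two-pair competition", {
  # pairs A=(d1,g1) and B=(d2,g1) compete on p1; A also has exclusive
  # support on p2, so A should end with the larger theta
  corpus <- annotation_corpus(
    list(p1 = c("d1", "d2"), p2 = "d1"),
    list(p1 = "g1", p2 = "g1"))
  tm <- run_em(build_triplets(corpus), corpus)
  th <- stats::setNames(tm$pairs$theta, tm$pairs$domain_id)
  expect_gt(th[["d1"]], th[["d2"]])
})

test_that("E scores match the independent pinned-EM oracle", {
  corpus <- three_pair_corpus()
  ts <- build_triplets(corpus)
  cfg <- em_config(max_iterations = 25L)
  tm <- run_em(ts, corpus, cfg)
  ev <- compute_e_scores(tm, ts, corpus, cfg)

  info <- oracle_em_setup(corpus)
  full_theta <- stats::setNames(tm$pairs$theta,
                                info$key(tm$pairs$domain_id, tm$pairs$go_id))
  for (i in seq_len(nrow(ev))) {
    want <- oracle_e_score(info, corpus, full_theta,
                           info$key(ev$domain_id[[i]], ev$go_id[[i]]),
                           iters = cfg$e_score_iterations)
    expect_equal(ev$e[[i]], want, tolerance = 1e-9,
                 info = paste(ev$domain_id[[i]], ev$go_id[[i]]))
  }
})

test_that("an unopposed pair is capped at the epsilon guard", {
  corpus <- annotation_corpus(list(p1 = "d1"), list(p1 = "g1"))
  ts <- build_triplets(corpus)
  cfg <- em_config()
  tm <- run_em(ts, corpus, cfg)
  ev <- compute_e_scores(tm, ts, corpus, cfg)
  expect_true(ev$capped[[1]])
  expect_equal(ev$e[[1]], log(tm$pairs$theta[[1]] / cfg$epsilon))
})

test_that("E is near zero when the null model explains the data equally well", {
  # two pairs always co-annotated on the same proteins: removing one leaves
  # the other to absorb the whole explanatory mass
  corpus <- annotation_corpus(
    list(p1 = c("d1", "d2"), p2 = c("d1", "d2")),
    list(p1 = "g1", p2 = "g1"))
  ts <- build_triplets(corpus)
  cfg <- em_config(max_iterations = 50L)
  tm <- run_em(ts, corpus, cfg)
  ev <- compute_e_scores(tm, ts, corpus, cfg)
  expect_true(all(abs(ev$e) < 0.05))
})
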