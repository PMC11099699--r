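# Independent oracles, deliberately coded with plain loops and none of the
# package's internals, so each test compares two separate routes to the same
# quantity.

# Reachability by repeated edge expansion over an edge table.
oracle_ancestors <- function(edges, term, relations = c("is_a", "part_of")) {
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  reached <- character(0)
  frontier <- term
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, reached)
    if (length(new) == 0L) break
    reached <- c(reached, new)
    frontier <- new
  }
  sort(reached)
}

# Brute-force mapping table: double loop over every domain x term pair,
# counting protein-set intersections explicitly.
oracle_mapping_table <- function(corpus, exclude_terms = character(0)) {
  shared <- intersect(names(corpus$protein_domains), names(corpus$protein_go))
  doms <- sort(unique(unlist(corpus$protein_domains, use.names = FALSE)))
  gos <- setdiff(sort(unique(unlist(corpus$protein_go, use.names = FALSE))),
                 exclude_terms)
  rows <- list()
  for (d in doms) {
    prot_d_all <- names(corpus$protein_domains)[vapply(
      corpus$protein_domains, function(x) d %in% x, logical(1))]
    for (g in gos) {
      prot_g_all <- names(corpus$protein_go)[vapply(
        corpus$protein_go, function(x) g %in% x, logical(1))]
      co <- intersect(intersect(prot_d_all, prot_g_all), shared)
      if (length(co) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        domain_id = d, go_id = g, n = length(co),
        n_domain = length(prot_d_all), n_go = length(prot_g_all),
        s = 2 * length(co) / (length(prot_d_all) + length(prot_g_all)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$domain_id, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Jaccard index of the two protein sets of a (domain, term) pair.
oracle_jaccard <- function(corpus, d, g) {
  set_d <- names(corpus$protein_domains)[vapply(
    corpus$protein_domains, function(x) d %in% x, logical(1))]
  set_g <- names(corpus$protein_go)[vapply(
    corpus$protein_go, function(x) g %in% x, logical(1))]
  length(intersect(set_d, set_g)) / length(union(set_d, set_g))
}

# Two-sample KS statistic as an explicit sup over pooled breakpoints.
oracle_ks_statistic <- function(a, b) {
  breaks <- sort(unique(c(a, b)))
  max(vapply(breaks, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# ---- Independent EM implementation -----------------------------------------
# Plain-loop EM over an explicit triplet list; no shared code with the
# package beyond the corpus accessors.

oracle_em_setup <- function(corpus) {
  shared <- intersect(names(corpus$protein_domains), names(corpus$protein_go))
  trips <- list()
  for (p in shared) {
    for (d in corpus$protein_domains[[p]]) {
      for (g in corpus$protein_go[[p]]) {
        trips[[length(trips) + 1L]] <- c(d = d, p = p, g = g)
      }
    }
  }
  pairs <- unique(t(vapply(trips, function(x) c(x[["d"]], x[["g"]]),
                           character(2))))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  key <- function(d, g) paste(d, g, sep = "\r")
  pair_keys <- key(pairs[, 1], pairs[, 2])
  n_all <- function(map, x) sum(vapply(map, function(v) x %in% v, logical(1)))
  info <- list(trips = trips, pairs = pairs, pair_keys = pair_keys,
               key = key, shared = shared)
  info$n <- vapply(pair_keys, function(k) {
    sum(vapply(trips, function(t) key(t[["d"]], t[["g"]]) == k, logical(1)))
  }, numeric(1))
  info$Z <- vapply(seq_len(nrow(pairs)), function(i) {
    (n_all(corpus$protein_domains, pairs[i, 1]) - info$n[[i]]) +
      (n_all(corpus$protein_go, pairs[i, 2]) - info$n[[i]])
  }, numeric(1))
  info
}

oracle_em_run <- function(info, iters, eps = 1e-12, pin = NULL) {
  theta <- info$n / (info$n + info$Z)
  names(theta) <- info$pair_keys
  if (!is.null(pin)) theta[[pin]] <- 0
  for (it in seq_len(iters)) {
    if (!is.null(pin)) theta[[pin]] <- 0
    # per-protein product over A(p)
    prods <- sapply(info$shared, function(p) {
      pr <- 1
      seen <- character(0)
      for (t in info$trips) {
        if (t[["p"]] != p) next
        k <- info$key(t[["d"]], t[["g"]])
        if (k %in% seen) next
        seen <- c(seen, k)
        pr <- pr * (1 - theta[[k]])
      }
      pr
    })
    M <- stats::setNames(rep(0, length(theta)), names(theta))
    for (t in info$trips) {
      k <- info$key(t[["d"]], t[["g"]])
      denom <- max(1 - prods[[t[["p"]]]], eps)
      u <- min(max(theta[[k]] / denom, 0), 1)
      M[[k]] <- M[[k]] + u
    }
    theta <- M / (info$n + info$Z)
    if (!is.null(pin)) theta[[pin]] <- 0
  }
  theta
}

# E score of one pair via the oracle EM: full-model theta given, null model
# rerun with the pair pinned to zero.
oracle_e_score <- function(info, corpus, full_theta, pin_key, iters = 10,
                           eps = 1e-12) {
  theta_bar <- oracle_em_run(info, iters, eps = eps, pin = pin_key)
  prod_over <- function(theta, p) {
    pr <- 1
    seen <- character(0)
    for (t in info$trips) {
      if (t[["p"]] != p) next
      k <- info$key(t[["d"]], t[["g"]])
      if (k %in% seen) next
      seen <- c(seen, k)
      pr <- pr * (1 - theta[[k]])
    }
    pr
  }
  co_prots <- unique(vapply(
    Filter(function(t) info$key(t[["d"]], t[["g"]]) == pin_key, info$trips),
    function(t) t[["p"]], character(1)))
  e <- 0
  for (p in co_prots) {
    num <- max(1 - prod_over(full_theta, p), eps)
    den <- max(1 - prod_over(theta_bar, p), eps)
    e <- e + log(num / den)
  }
  e
}

# Per-protein precision/recall by direct set arithmetic.
oracle_pr_rc <- function(pred_list, truth_list, tau, mode) {
  prots_pred_any <- names(pred_list)
  eval_prots <- if (mode == "full") names(truth_list)
                else intersect(names(truth_list), prots_pred_any)
  prec <- c(); rc <- c()
  for (p in names(truth_list)) {
    pl <- pred_list[[p]]
    pred <- if (is.null(pl)) character(0) else pl$go_id[pl$score >= tau]
    tp <- length(intersect(pred, truth_list[[p]]))
    if (length(pred) > 0L) prec <- c(prec, tp / length(pred))
    if (p %in% eval_prots)
      rc <- c(rc, tp / length(truth_list[[p]]))
  }
  list(precision = if (length(prec)) mean(prec) else NA_real_,
       recall = if (length(rc)) mean(rc) else 0)
}
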