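# Expectation maximization over co-annotation triplets: association
# probabilities theta per domain-GO pair, and the leave-one-out
# likelihood-ratio evidence score E.
#
# Model sketch: every (domain d, protein p, term g) co-annotation triplet
# carries a latent responsibility C_p in [0,1] saying whether the pair (d,g)
# explains its own co-occurrence on p. Per pair, M = sum C_p over co-annotated
# proteins, K = sum (1 - C_p), and Z counts proteins carrying exactly one of
# the two annotations; theta = M / (M + K + Z). The E-step shares each
# protein's explanatory mass among the competing pairs annotated on it:
# U(C_p) = theta_dg / (1 - prod_{(x,y) in A(p)} (1 - theta_xy)).

#' EM configuration
#'
#' @param alpha,beta Pseudocounts added to the likelihood exponents (default
#'   0; the likelihood uses exponents `M + alpha` and `K + Z + beta`).
#' @param max_iterations Iteration cap for [run_em()] (default 150).
#' @param rel_tolerance Relative log-likelihood improvement below which the
#'   run stops (default 1e-4).
#' @param epsilon Probability floor for logs and for the shared-mass
#'   denominators (default 1e-12).
#' @param e_score_iterations EM iterations per leave-one-out rerun when
#'   computing E scores (default 10).
#' @return List of class `em_config`.
#' @export
em_config <- function(alpha = 0, beta = 0, max_iterations = 150L,
                      rel_tolerance = 1e-4, epsilon = 1e-12,
                      e_score_iterations = 10L) {
  stopifnot(alpha >= 0, beta >= 0, is_count(max_iterations),
            rel_tolerance > 0, epsilon > 0, epsilon <= 1e-6,
            is_count(e_score_iterations))
  structure(list(alpha = alpha, beta = beta,
                 max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance, epsilon = epsilon,
                 e_score_iterations = as.integer(e_score_iterations)),
            class = "em_config")
}

#' Enumerate co-annotation triplets
#'
#' One triplet per (domain, protein, term) with the domain and term
#' co-annotated on that protein (shared proteins only; namespace roots
#' excluded when a dag is supplied). `A(p)` -- the set of co-annotated pairs
#' on protein p -- is exactly the set of pairs appearing in p's triplets.
#'
#' @param corpus An `annotation_corpus`.
#' @param restrict_to Optional `mapping_table`; only its (domain, GO) pairs
#'   generate triplets (used to run EM on an S-filtered subset).
#' @param dag Optional `ontology_dag` for root exclusion.
#' @return A `triplet_set`: list with `records` (data.frame domain_id,
#'   protein_id, go_id), `pairs` (unique pair data.frame), `pair_idx`,
#'   `protein_ids`, `protein_idx`.
#' @export
build_triplets <- function(corpus, restrict_to = NULL, dag = NULL) {
  records <- coannotation_records(corpus, dag)
  if (!is.null(restrict_to)) {
    allowed <- pair_key(restrict_to$domain_id, restrict_to$go_id)
    keep <- pair_key(records$domain_id, records$go_id) %in% allowed
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0L)
      stopf("restriction removes every co-annotation triplet")
    rownames(records) <- NULL
  }
  key <- pair_key(records$domain_id, records$go_id)
  pair_levels <- sort(unique(key))
  parts <- strsplit(pair_levels, "\r", fixed = TRUE)
  pairs <- data.frame(domain_id = vapply(parts, `[[`, "", 1L),
                      go_id = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  protein_ids <- sort(unique(records$protein_id))
  structure(list(
    records = records,
    pairs = pairs,
    pair_idx = match(key, pair_levels),
    protein_ids = protein_ids,
    protein_idx = match(records$protein_id, protein_ids)
  ), class = "triplet_set")
}

#' @export
print.triplet_set <- function(x, ...) {
  cat(sprintf("<triplet_set> %d triplets, %d pairs, %d proteins\n",
              nrow(x$records), nrow(x$pairs), length(x$protein_ids)))
  invisible(x)
}

#' Initialize the theta matrix
#'
#' All responsibilities start at 1, so M is the co-annotated protein count n,
#' K = 0, and Z counts proteins carrying the domain xor the term (over shared
#' proteins). The initial estimate `theta_init = M / (M + K + Z)` is then the
#' Jaccard index of the pair's two protein sets.
#'
#' @param triplets A `triplet_set`.
#' @param corpus The `annotation_corpus` the triplets came from (supplies the
#'   marginal protein sets for Z).
#' @return A `theta_matrix`: list with `pairs` (data.frame domain_id, go_id,
#'   n, Z, M, K, theta_init, theta) and an empty log-likelihood `trace`.
#' @export
initialize_theta <- function(triplets, corpus) {
  n <- as.integer(tabulate(triplets$pair_idx, nbins = nrow(triplets$pairs)))
  n_domain <- as.integer(corpus$domain_counts[triplets$pairs$domain_id])
  n_go <- as.integer(corpus$go_counts[triplets$pairs$go_id])
  Z <- (n_domain - n) + (n_go - n)
  theta_init <- n / (n + Z)
  pairs <- data.frame(triplets$pairs,
                      n = n, Z = as.integer(Z),
                      M = as.numeric(n), K = 0,
                      theta_init = theta_init, theta = theta_init,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, trace = numeric(0)), class = "theta_matrix")
}

#' Log-likelihood of a theta matrix
#'
#' `sum over pairs of (M + alpha) * log(theta) + (K + Z + beta) * log(1 -
#' theta)`, with both probabilities floored at `epsilon`.
#'
#' @param matrix A `theta_matrix`.
#' @param config An `em_config`.
#' @return A single numeric value.
#' @export
log_likelihood <- function(matrix, config = em_config()) {
  p <- matrix$pairs
  eps <- config$epsilon
  sum((p$M + config$alpha) * log(pmax(p$theta, eps)) +
      (p$K + p$Z + config$beta) * log(pmax(1 - p$theta, eps)))
}

#' One full EM iteration
#'
#' E-step: each triplet's responsibility becomes `U(C_p) = theta_dg /
#' (1 - prod_{(x,y) in A(p)} (1 - theta_xy))` with the denominator floored at
#' `epsilon`. M-step: M and K are recomputed from the responsibilities and
#' `theta = M / (M + K + Z)`. When `pinned_zero` names a pair, its theta is
#' forced to zero before the E-step (the leave-one-out null model used by the
#' E score). The log-likelihood after the update is appended to the trace.
#'
#' @param matrix A `theta_matrix`.
#' @param triplets The `triplet_set` it was built from.
#' @param config An `em_config`.
#' @param pinned_zero Optional `c(domain_id, go_id)` to pin at theta = 0.
#' @return The updated `theta_matrix`.
#' @export
em_iterate <- function(matrix, triplets, config = em_config(),
                       pinned_zero = NULL) {
  p <- matrix$pairs
  theta <- p$theta
  pin <- NULL
  if (!is.null(pinned_zero)) {
    pin <- which(p$domain_id == pinned_zero[[1L]] & p$go_id == pinned_zero[[2L]])
    if (length(pin) != 1L)
      stopf("pinned pair (%s, %s) not in the theta matrix",
            pinned_zero[[1L]], pinned_zero[[2L]])
    theta[pin] <- 0
  }
  eps <- config$epsilon
  t_tri <- theta[triplets$pair_idx]
  # per-protein log prod (1 - theta) over A(p)
  lp <- rowsum(log1p(-pmin(t_tri, 1 - eps)), triplets$protein_idx)
  denom <- 1 - exp(lp[triplets$protein_idx, 1L])
  u <- t_tri / pmax(denom, eps)
  n_floored <- sum(denom < eps & t_tri > 0)
  u <- pmin(pmax(u, 0), 1)
  M <- as.numeric(rowsum(u, triplets$pair_idx))
  K <- p$n - M
  theta_new <- M / (p$n + p$Z)
  if (!is.null(pin)) theta_new[pin] <- 0
  p$M <- M; p$K <- K; p$theta <- theta_new
  matrix$pairs <- p
  ll <- log_likelihood(matrix, config)
  if (!is.finite(ll)) stopf("non-finite log-likelihood during EM iteration")
  matrix$trace <- c(matrix$trace, ll)
  attr(matrix, "n_denominator_floors") <- n_floored
  matrix
}

#' Run EM to convergence
#'
#' Initializes theta from the triplets and iterates [em_iterate()] until the
#' relative log-likelihood improvement drops below `rel_tolerance` or
#' `max_iterations` is reached. The trace starts with the likelihood of the
#' initial matrix.
#'
#' @inheritParams em_iterate
#' @param corpus The `annotation_corpus` (for Z).
#' @return A converged `theta_matrix` with the full likelihood trace.
#' @export
run_em <- function(triplets, corpus, config = em_config(),
                   pinned_zero = NULL) {
  matrix <- initialize_theta(triplets, corpus)
  if (!is.null(pinned_zero)) {
    pin <- which(matrix$pairs$domain_id == pinned_zero[[1L]] &
                 matrix$pairs$go_id == pinned_zero[[2L]])
    if (length(pin) == 1L) matrix$pairs$theta[pin] <- 0
  }
  matrix$trace <- log_likelihood(matrix, config)
  for (i in seq_len(config$max_iterations)) {
    prev <- matrix$trace[[length(matrix$trace)]]
    matrix <- em_iterate(matrix, triplets, config, pinned_zero)
    cur <- matrix$trace[[length(matrix$trace)]]
    if (abs(cur - prev) / max(abs(prev), 1) < config$rel_tolerance) break
  }
  matrix
}

#' Leave-one-out likelihood-ratio evidence scores
#'
#' For each requested pair the EM is rerun for `e_score_iterations` with that
#' pair pinned at theta = 0, yielding the null matrix theta-bar in which only
#' competing pairs may explain the co-annotations. The evidence score is
#' `E = sum over co-annotated proteins p of log[(1 - prod_{A(p)} (1 - theta))
#' / (1 - prod_{A(p)} (1 - theta_bar))]`; denominators that underflow are
#' floored at `epsilon` and the pair recorded in `capped`.
#'
#' @param matrix The converged `theta_matrix` of the full model.
#' @param triplets The `triplet_set`.
#' @param corpus The `annotation_corpus`.
#' @param config An `em_config`.
#' @param pairs Optional data.frame (domain_id, go_id) restricting which pairs
#'   get an E score (the reruns are expensive); default: all pairs.
#' @return An `evidence_table`: data.frame (domain_id, go_id, e, capped).
#' @export
compute_e_scores <- function(matrix, triplets, corpus, config = em_config(),
                             pairs = NULL) {
  all_pairs <- matrix$pairs
  if (is.null(pairs)) pairs <- all_pairs[, c("domain_id", "go_id")]
  want_keys <- pair_key(pairs$domain_id, pairs$go_id)
  have_keys <- pair_key(all_pairs$domain_id, all_pairs$go_id)
  idx <- match(want_keys, have_keys)
  if (anyNA(idx)) stopf("requested pair absent from the theta matrix")
  eps <- config$epsilon

  # full-model per-protein explanatory mass: 1 - prod (1 - theta) over A(p)
  theta_tri <- all_pairs$theta[triplets$pair_idx]
  lp_full <- rowsum(log1p(-pmin(theta_tri, 1 - eps)), triplets$protein_idx)
  num_protein <- 1 - exp(lp_full[, 1L])

  init <- initialize_theta(triplets, corpus)
  e <- numeric(length(idx))
  capped <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    pin <- c(all_pairs$domain_id[[i]], all_pairs$go_id[[i]])
    null_matrix <- init
    null_matrix$pairs$theta[i] <- 0
    for (it in seq_len(config$e_score_iterations))
      null_matrix <- em_iterate(null_matrix, triplets, config, pinned_zero = pin)
    tb_tri <- null_matrix$pairs$theta[triplets$pair_idx]
    lp_null <- rowsum(log1p(-pmin(tb_tri, 1 - eps)), triplets$protein_idx)
    den_protein <- 1 - exp(lp_null[, 1L])
    prot_rows <- unique(triplets$protein_idx[triplets$pair_idx == i])
    num <- pmax(num_protein[prot_rows], eps)
    den <- den_protein[prot_rows]
    capped[[k]] <- any(den < eps)
    e[[k]] <- sum(log(num / pmax(den, eps)))
  }
  structure(data.frame(domain_id = all_pairs$domain_id[idx],
                       go_id = all_pairs$go_id[idx],
                       e = e, capped = capped, stringsAsFactors = FALSE),
            class = c("evidence_table", "data.frame"))
}

#' Merge EM output into a mapping table
#'
#' Joins theta (and optionally E) columns onto a mapping table by
#' (domain_id, go_id).
#'
#' @param table A `mapping_table`.
#' @param matrix A `theta_matrix`.
#' @param evidence Optional `evidence_table`.
#' @return The table with added columns `theta_init`, `theta` and, when
#'   available, `e`.
#' @export
augment_mappings <- function(table, matrix, evidence = NULL) {
  tk <- pair_key(table$domain_id, table$go_id)
  mk <- pair_key(matrix$pairs$domain_id, matrix$pairs$go_id)
  m <- match(tk, mk)
  table$theta_init <- matrix$pairs$theta_init[m]
  table$theta <- matrix$pairs$theta[m]
  if (!is.null(evidence)) {
    ek <- pair_key(evidence$domain_id, evidence$go_id)
    table$e <- evidence$e[match(tk, ek)]
  }
  table
}
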