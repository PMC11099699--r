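# CAFA-style protein-centric evaluation: precision/recall over score
# thresholds, Fmax, the information-theoretic Smin, and coverage, in full and
# partial modes.
#
# Precision and recall follow the standard CAFA protocol:
#   pr(tau) = mean over proteins with >= 1 prediction at tau of TP/(TP+FP)
#   rc(tau) = mean over evaluated proteins of TP/(TP+FN)
# where "evaluated" is every benchmark protein in full mode, and only proteins
# with at least one prediction (at any threshold) in partial mode.

#' Build a benchmark set
#'
#' @param truth Named list protein_id -> character vector of true GO ids
#'   (ancestor-closed; namespace roots are removed when a dag is given).
#' @param dag Optional `ontology_dag` used to strip namespace roots.
#' @param namespace Optional namespace label recorded for provenance.
#' @param knowledge_type Label, e.g. `"no-knowledge"`.
#' @return A `benchmark_set`.
#' @export
benchmark_set <- function(truth, dag = NULL, namespace = NA_character_,
                          knowledge_type = "no-knowledge") {
  if (!is.null(dag)) {
    roots <- unname(dag$roots)
    truth <- lapply(truth, function(x) setdiff(x, roots))
  }
  truth <- truth[lengths(truth) > 0L]
  if (length(truth) == 0L) stopf("benchmark has no protein with non-empty truth")
  structure(list(truth = truth, namespace = namespace,
                 knowledge_type = knowledge_type),
            class = "benchmark_set")
}

#' Split a benchmark by GO namespace
#'
#' @param bench A `benchmark_set`.
#' @param dag An `ontology_dag`.
#' @return Named list of `benchmark_set`s, one per namespace present.
#' @export
split_benchmark_by_namespace <- function(bench, dag) {
  ns_of <- dag$namespaces
  out <- list()
  for (nsname in unique(stats::na.omit(ns_of[unlist(bench$truth)]))) {
    truth_ns <- lapply(bench$truth, function(x) x[ns_of[x] %in% nsname])
    truth_ns <- truth_ns[lengths(truth_ns) > 0L]
    if (length(truth_ns))
      out[[nsname]] <- benchmark_set(truth_ns, namespace = nsname,
                                     knowledge_type = bench$knowledge_type)
  }
  out
}

#' Read a benchmark from a two-column TSV (protein_id, go_id)
#'
#' @param path TSV path with header `protein_id, go_id`.
#' @param dag Optional `ontology_dag`; truth sets are ancestor-closed against
#'   it and roots stripped.
#' @inheritParams benchmark_set
#' @export
read_benchmark <- function(path, dag = NULL, knowledge_type = "no-knowledge") {
  df <- read_tsv(path)
  missing <- setdiff(c("protein_id", "go_id"), names(df))
  if (length(missing))
    stopf("benchmark table is missing column(s): %s",
          paste(missing, collapse = ", "))
  truth <- lapply(split(df$go_id, df$protein_id), function(x) sort(unique(x)))
  if (!is.null(dag)) truth <- propagate_go_annotations(truth, dag)
  benchmark_set(truth, dag = dag, knowledge_type = knowledge_type)
}

# Internal: per-benchmark-protein prediction records restricted to benchmark
# proteins, as parallel lists of term/score vectors.
prediction_index <- function(preds, bench) {
  keep <- preds$protein_id %in% names(bench$truth)
  df <- preds[keep, , drop = FALSE]
  split_terms <- split(df$go_id, df$protein_id)
  split_scores <- split(df$score, df$protein_id)
  list(terms = split_terms, scores = split_scores)
}

#' Precision and recall at a score threshold
#'
#' @param preds A `prediction_set` (DAG-consistent, roots excluded).
#' @param bench A `benchmark_set`.
#' @param tau Score threshold; a prediction counts when `score >= tau`.
#' @param mode `"full"` (recall averaged over all benchmark proteins) or
#'   `"partial"` (averaged over proteins with any prediction).
#' @return List with `precision` (NA when no protein predicts at tau),
#'   `recall`, `m_tau` (proteins predicting at tau), `n_eval`.
#' @export
precision_recall_at_tau <- function(preds, bench, tau,
                                    mode = c("full", "partial")) {
  mode <- match.arg(mode)
  if (length(bench$truth) == 0L) stopf("empty benchmark")
  px <- prediction_index(preds, bench)
  n_eval <- if (mode == "full") length(bench$truth) else length(px$terms)
  if (n_eval == 0L) return(list(precision = NA_real_, recall = 0,
                                m_tau = 0L, n_eval = 0L))
  prec_terms <- 0; m_tau <- 0L; rc_sum <- 0
  for (p in names(px$terms)) {
    sel <- px$scores[[p]] >= tau
    if (!any(sel)) next
    pred <- px$terms[[p]][sel]
    truth <- bench$truth[[p]]
    tp <- sum(pred %in% truth)
    m_tau <- m_tau + 1L
    prec_terms <- prec_terms + tp / length(pred)
    rc_sum <- rc_sum + tp / length(truth)
  }
  list(precision = if (m_tau > 0L) prec_terms / m_tau else NA_real_,
       recall = rc_sum / n_eval, m_tau = m_tau, n_eval = n_eval)
}

#' Maximum protein-centric F-score over thresholds
#'
#' `F(tau) = 2 * pr * rc / (pr + rc)` computed at each threshold of the grid;
#' thresholds where no protein predicts are skipped (precision undefined).
#' Ties in F go to the smallest threshold.
#'
#' @inheritParams precision_recall_at_tau
#' @param tau_grid Thresholds to scan (default 0.01, 0.02, ..., 1).
#' @return List with `fmax`, `tau_at_fmax`, and `pr_curve` (data.frame tau,
#'   precision, recall, f, m_tau).
#' @export
fmax <- function(preds, bench, mode = c("full", "partial"),
                 tau_grid = seq(0.01, 1, by = 0.01)) {
  mode <- match.arg(mode)
  rows <- lapply(tau_grid, function(tau) {
    pr <- precision_recall_at_tau(preds, bench, tau, mode)
    f <- if (is.na(pr$precision)) NA_real_
         else if (pr$precision + pr$recall == 0) 0
         else 2 * pr$precision * pr$recall / (pr$precision + pr$recall)
    data.frame(tau = tau, precision = pr$precision, recall = pr$recall,
               f = f, m_tau = pr$m_tau)
  })
  curve <- do.call(rbind, rows)
  ok <- !is.na(curve$f)
  if (!any(ok)) return(list(fmax = 0, tau_at_fmax = NA_real_, pr_curve = curve))
  best <- which(ok)[which.max(curve$f[ok])]
  list(fmax = curve$f[[best]], tau_at_fmax = curve$tau[[best]],
       pr_curve = curve)
}

#' Minimum semantic distance over thresholds
#'
#' At each threshold, remaining uncertainty `ru` is the mean (over benchmark
#' proteins) total information content of true-but-unpredicted terms and
#' misinformation `mi` the mean IC of predicted-but-false terms;
#' `smin = min over tau of sqrt(ru^2 + mi^2)`.
#'
#' @inheritParams fmax
#' @param ic An `ic_table` covering all benchmark and predicted terms.
#' @return List with `smin`, `tau_at_smin`, and `curve` (tau, ru, mi).
#' @export
smin <- function(preds, bench, ic, tau_grid = seq(0.01, 1, by = 0.01)) {
  lookup <- attr(ic, "ic_lookup")
  px <- prediction_index(preds, bench)
  needed <- unique(c(unlist(bench$truth, use.names = FALSE),
                     unlist(px$terms, use.names = FALSE)))
  miss <- needed[!needed %in% names(lookup)]
  if (length(miss))
    stopf("no information content for term(s): %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  n <- length(bench$truth)
  rows <- lapply(tau_grid, function(tau) {
    ru_sum <- 0; mi_sum <- 0
    for (p in names(bench$truth)) {
      truth <- bench$truth[[p]]
      pred <- character(0)
      if (!is.null(px$terms[[p]])) {
        sel <- px$scores[[p]] >= tau
        pred <- px$terms[[p]][sel]
      }
      ru_sum <- ru_sum + sum(lookup[setdiff(truth, pred)])
      mi_sum <- mi_sum + sum(lookup[setdiff(pred, truth)])
    }
    data.frame(tau = tau, ru = ru_sum / n, mi = mi_sum / n)
  })
  curve <- do.call(rbind, rows)
  dist <- sqrt(curve$ru^2 + curve$mi^2)
  best <- which.min(dist)
  list(smin = dist[[best]], tau_at_smin = curve$tau[[best]], curve = curve)
}

#' Fraction of benchmark proteins receiving any prediction
#'
#' @inheritParams precision_recall_at_tau
#' @return A fraction in [0, 1].
#' @export
coverage <- function(preds, bench) {
  if (length(bench$truth) == 0L) stopf("empty benchmark")
  covered <- sum(names(bench$truth) %in% unique(preds$protein_id))
  covered / length(bench$truth)
}

#' Full protein-centric evaluation
#'
#' Convenience wrapper: strips namespace roots from predictions when a dag is
#' supplied, then computes Fmax, Smin (when an IC table is given), and
#' coverage.
#'
#' @inheritParams fmax
#' @param dag Optional `ontology_dag` (root exclusion).
#' @param ic Optional `ic_table`; Smin is skipped when absent.
#' @return An `evaluation_result` list: fmax, tau_at_fmax, smin, tau_at_smin,
#'   coverage, mode, namespace, pr_curve.
#' @export
evaluate_predictions <- function(preds, bench, dag = NULL, ic = NULL,
                                 mode = c("full", "partial"),
                                 tau_grid = seq(0.01, 1, by = 0.01)) {
  mode <- match.arg(mode)
  if (!is.null(dag)) {
    keep <- !preds$go_id %in% unname(dag$roots)
    preds <- new_prediction_set(preds[keep, , drop = FALSE],
                                mode = attr(preds, "mode"))
  }
  f <- fmax(preds, bench, mode, tau_grid)
  s <- if (!is.null(ic)) smin(preds, bench, ic, tau_grid)
       else list(smin = NA_real_, tau_at_smin = NA_real_)
  structure(list(fmax = f$fmax, tau_at_fmax = f$tau_at_fmax,
                 smin = s$smin, tau_at_smin = s$tau_at_smin,
                 coverage = coverage(preds, bench), mode = mode,
                 namespace = bench$namespace, pr_curve = f$pr_curve),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> mode=%s fmax=%.4f (tau=%.2f) smin=%s coverage=%.3f\n",
    x$mode, x$fmax, x$tau_at_fmax,
    if (is.na(x$smin)) "NA" else sprintf("%.4f", x$smin), x$coverage))
  invisible(x)
}
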