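# Protein function prediction: propagate accepted domain-GO mappings to the
# proteins carrying those domains, plus the naive frequency baseline and the
# hybrid max-merge of prediction sets.

#' Min-max scale scores into (floor, 1]
#'
#' `x -> floor + (1 - floor) * (x - min) / (max - min)`; a constant vector
#' maps to all ones. Rank order is preserved. Used to bring E scores into the
#' (0, 1] range the CAFA protocol requires.
#'
#' @param values Non-empty numeric vector.
#' @param floor Lower bound of the target range (default 0.01).
#' @return Numeric vector in `[floor, 1]`.
#' @export
minmax_scale <- function(values, floor = 0.01) {
  if (length(values) == 0L) stopf("cannot scale an empty vector")
  stopifnot(floor > 0, floor < 1)
  rng <- range(values)
  if (rng[[1L]] == rng[[2L]]) return(rep(1, length(values)))
  floor + (1 - floor) * (values - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
}

# Make a prediction set DAG-consistent: every predicted term's ancestors are
# predicted at least as confidently (max-style propagation). Roots excluded.
dag_consistent <- function(records, dag) {
  if (is.null(dag) || nrow(records) == 0L) return(records)
  roots <- unname(dag$roots)
  anc <- dag$ancestors[records$go_id]
  n_anc <- lengths(anc)
  expanded <- data.frame(
    protein_id = c(records$protein_id, rep(records$protein_id, n_anc)),
    go_id = c(records$go_id, unlist(anc, use.names = FALSE)),
    score = c(records$score, rep(records$score, n_anc)),
    stringsAsFactors = FALSE
  )
  expanded <- expanded[!expanded$go_id %in% roots, , drop = FALSE]
  key <- paste(expanded$protein_id, expanded$go_id, sep = "\r")
  best <- tapply(expanded$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[[`, "", 1L),
                    go_id = vapply(parts, `[[`, "", 2L),
                    score = as.numeric(best), stringsAsFactors = FALSE)
  out[order(out$protein_id, out$go_id), , drop = FALSE]
}

new_prediction_set <- function(records, mode, components = mode) {
  rownames(records) <- NULL
  structure(records, class = c("prediction_set", "data.frame"),
            mode = mode, components = components)
}

#' Predict protein functions from a mapping table
#'
#' Every protein carrying domain d receives term g for each accepted mapping
#' (d, g). In `"S"` mode the prediction score is the mapping's co-occurrence
#' similarity; in `"E"` mode the evidence scores are min-max scaled into
#' (0, 1] first; in `"reference"` mode (curated InterPro2GO-style input) all
#' scores are 1. When one protein reaches the same term through several
#' domains the maximum score is kept, and a DAG-consistency pass then raises
#' each ancestor's score to at least its children's (namespace roots are
#' excluded).
#'
#' @param mappings A `mapping_table`; `"E"` mode requires an `e` column.
#' @param protein_domains Named list protein_id -> domain ids (the targets).
#' @param dag Optional `ontology_dag` for ancestor propagation and root
#'   exclusion.
#' @param score_mode `"S"`, `"E"`, or `"reference"`.
#' @param floor Min-max floor for E mode (default 0.01).
#' @return A `prediction_set`: data.frame (protein_id, go_id, score), scores
#'   in (0, 1], unique per (protein, term).
#' @export
predict_functions <- function(mappings, protein_domains, dag = NULL,
                              score_mode = c("S", "E", "reference"),
                              floor = 0.01) {
  score_mode <- match.arg(score_mode)
  if (nrow(mappings) == 0L) stopf("empty mapping table")
  score <- switch(score_mode,
    S = mappings$s,
    E = {
      if (!"e" %in% names(mappings) || anyNA(mappings$e))
        stopf("E-mode prediction requires an 'e' column without missing values")
      minmax_scale(mappings$e, floor)
    },
    reference = rep(1, nrow(mappings))
  )
  by_domain <- split(seq_len(nrow(mappings)), mappings$domain_id)
  pieces <- lapply(names(protein_domains), function(p) {
    rows <- unlist(by_domain[protein_domains[[p]]], use.names = FALSE)
    if (length(rows) == 0L) return(NULL)
    data.frame(protein_id = p, go_id = mappings$go_id[rows],
               score = score[rows], stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, pieces)
  if (is.null(records) || nrow(records) == 0L)
    stopf("no target protein carries a mapped domain")
  key <- paste(records$protein_id, records$go_id, sep = "\r")
  best <- tapply(records$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  records <- data.frame(protein_id = vapply(parts, `[[`, "", 1L),
                        go_id = vapply(parts, `[[`, "", 2L),
                        score = as.numeric(best), stringsAsFactors = FALSE)
  records <- dag_consistent(records, dag)
  records <- records[order(records$protein_id, records$go_id), , drop = FALSE]
  new_prediction_set(records, mode = score_mode)
}

#' Naive frequency baseline
#'
#' Pairs every target protein with every GO term seen in the (propagated)
#' training annotations, scored by the term's annotation frequency -- the
#' fraction of training proteins annotated with it. Scores are identical
#' across targets.
#'
#' @param train_go Named list protein_id -> ancestor-closed GO ids.
#' @param targets Character vector of target protein ids.
#' @return A `prediction_set` with mode `"naive"`.
#' @export
naive_baseline <- function(train_go, targets) {
  if (length(train_go) == 0L) stopf("empty training annotation set")
  counts <- table(unlist(lapply(train_go, unique), use.names = FALSE))
  freq <- as.numeric(counts) / length(train_go)
  terms <- names(counts)
  records <- data.frame(
    protein_id = rep(targets, each = length(terms)),
    go_id = rep(terms, times = length(targets)),
    score = rep(freq, times = length(targets)),
    stringsAsFactors = FALSE
  )
  new_prediction_set(records, mode = "naive")
}

#' Merge prediction sets (hybrid max rule)
#'
#' Union of the records; a (protein, term) pair present in several sets keeps
#' its maximum score. Associative and commutative.
#'
#' @param sets List of two or more `prediction_set`s.
#' @return A `prediction_set` with mode `"hybrid"` and the input modes in its
#'   `components` attribute.
#' @export
merge_hybrid <- function(sets) {
  if (length(sets) < 2L) stopf("merge_hybrid needs at least two prediction sets")
  records <- do.call(rbind, lapply(sets, as.data.frame))
  key <- paste(records$protein_id, records$go_id, sep = "\r")
  best <- tapply(records$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[[`, "", 1L),
                    go_id = vapply(parts, `[[`, "", 2L),
                    score = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$go_id), , drop = FALSE]
  new_prediction_set(out, mode = "hybrid",
                     components = unlist(lapply(sets, attr, "mode")))
}

#' Write / read predictions in CAFA submission style
#'
#' Tab-separated `protein_id, go_id, score` lines, scores printed with six
#' decimals; no header.
#'
#' @param preds A `prediction_set`.
#' @param path File path.
#' @export
write_predictions <- function(preds, path) {
  lines <- sprintf("%s\t%s\t%.6f", preds$protein_id, preds$go_id, preds$score)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @param mode Mode label to attach on read (default `"S"`).
#' @export
read_predictions <- function(path, mode = "S") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "go_id", "score"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  new_prediction_set(df, mode = mode)
}
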