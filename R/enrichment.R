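# Enrichment of a curated reference set among top-ranked mappings: the
# ablation comparing co-occurrence S, theta_init, theta, and E as rankers.

#' Load a curated reference mapping set
#'
#' Two-column TSV (domain_id, go_id), InterPro2GO style.
#' @param path TSV path.
#' @param label Provenance label (defaults to the file name).
#' @return A `reference_set`: data.frame (domain_id, go_id) with a label
#'   attribute.
#' @export
read_reference_mappings <- function(path, label = basename(path)) {
  df <- read_tsv(path)
  need <- c("domain_id", "go_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("reference mapping table is missing column(s): %s",
          paste(missing, collapse = ", "))
  reference_set(df[, need], label = label)
}

#' @rdname read_reference_mappings
#' @param pairs data.frame with columns domain_id, go_id.
#' @export
reference_set <- function(pairs, label = "reference") {
  pairs <- unique(pairs[, c("domain_id", "go_id")])
  rownames(pairs) <- NULL
  structure(pairs, class = c("reference_set", "data.frame"), label = label)
}

#' Rank mappings by a score column
#'
#' Descending by score; ties broken by descending support n, then by
#' lexicographic (domain_id, go_id) so rankings are deterministic.
#'
#' @param table A `mapping_table` (possibly EM-augmented).
#' @param score_name One of `"s"`, `"theta_init"`, `"theta"`, `"e"`.
#' @return data.frame (domain_id, go_id, score, n) in rank order.
#' @export
rank_mappings <- function(table, score_name = c("s", "theta_init", "theta", "e")) {
  score_name <- match.arg(score_name)
  if (!score_name %in% names(table))
    stopf("score column '%s' not present in the mapping table", score_name)
  score <- table[[score_name]]
  if (anyNA(score)) stopf("score column '%s' has missing values", score_name)
  ord <- order(-score, -table$n, table$domain_id, table$go_id)
  out <- data.frame(domain_id = table$domain_id[ord], go_id = table$go_id[ord],
                    score = score[ord], n = table$n[ord],
                    stringsAsFactors = FALSE)
  attr(out, "score_name") <- score_name
  out
}

#' Observed/expected enrichment of a reference set in the top K
#'
#' For each rank cutoff K: `observed` is the number of reference pairs among
#' the top K, `expected` is `K` times the reference fraction across the whole
#' ranked list, and `ratio = observed / expected`. A ratio above 1 means the
#' ranking concentrates curated pairs near the top.
#'
#' @param ranked Output of [rank_mappings()].
#' @param reference A `reference_set`.
#' @param ks Integer rank cutoffs, each at most the list length.
#' @return An `enrichment_curve`: data.frame (k, observed, expected, ratio)
#'   with the score name as an attribute.
#' @export
enrichment_at_k <- function(ranked, reference, ks) {
  if (any(ks < 1) || any(ks > nrow(ranked)))
    stopf("every K must lie in [1, %d]", nrow(ranked))
  ref_keys <- pair_key(reference$domain_id, reference$go_id)
  in_ref <- pair_key(ranked$domain_id, ranked$go_id) %in% ref_keys
  total <- sum(in_ref)
  if (total == 0L)
    stopf("expected enrichment is zero: no reference pair appears in the ranked list")
  frac <- total / nrow(ranked)
  cum <- cumsum(in_ref)
  observed <- cum[ks]
  expected <- ks * frac
  structure(data.frame(k = as.integer(ks), observed = as.integer(observed),
                       expected = expected, ratio = observed / expected),
            class = c("enrichment_curve", "data.frame"),
            score_name = attr(ranked, "score_name"),
            reference_label = attr(reference, "label"))
}
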