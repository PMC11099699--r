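# Mapping core: initial domain-GO mapping table from co-annotation,
# co-occurrence similarity, randomized null, KS-based threshold selection,
# and the final reliability filter.

#' Dice-type co-occurrence similarity between a domain and a GO term
#'
#' `S = 2 * n_co / (n_domain + n_go)` where the counts are protein-set sizes:
#' `n_co` proteins carrying both the domain and the term, `n_domain` carrying
#' the domain, `n_go` carrying the term. S lies in (0, 1], reaching 1 exactly
#' when the two protein sets coincide.
#'
#' @param n_co,n_domain,n_go Non-negative integer vectors (recycled).
#' @return Numeric vector of similarities.
#' @export
cooccurrence_similarity <- function(n_co, n_domain, n_go) {
  if (any(n_co < 1) || any(n_co > pmin(n_domain, n_go)))
    stopf("require 1 <= n_co <= min(n_domain, n_go)")
  2 * n_co / (n_domain + n_go)
}

# Aggregate a (domain_id, protein_id, go_id) co-annotation record table into
# a unique-pair mapping table. Marginal protein counts (N_D, N_GO) come from
# the annotation corpus: shuffling the co-annotation records changes which
# pairs co-occur, never how many proteins carry a domain or a term.
mapping_from_records <- function(records, domain_counts, go_counts,
                                 provenance, corpus_digest = NA_character_) {
  key <- pair_key(records$domain_id, records$go_id)
  n <- tapply(records$protein_id, key, function(p) length(unique(p)))
  dom_n <- domain_counts
  go_n <- go_counts
  keys <- names(n)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  domain_id <- vapply(parts, `[[`, "", 1L)
  go_id <- vapply(parts, `[[`, "", 2L)
  tab <- data.frame(
    domain_id = domain_id,
    go_id = go_id,
    n = as.integer(n),
    n_domain = as.integer(dom_n[domain_id]),
    n_go = as.integer(go_n[go_id]),
    stringsAsFactors = FALSE
  )
  # formula applied directly: in a shuffled null table a pair's support may
  # exceed the corpus marginals, which the guarded scorer would reject
  tab$s <- 2 * tab$n / (tab$n_domain + tab$n_go)
  tab <- tab[order(tab$domain_id, tab$go_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("mapping_table", "data.frame"),
            provenance = provenance,
            corpus_digest = corpus_digest,
            records = records,
            domain_counts = domain_counts,
            go_counts = go_counts)
}

# Enumerate co-annotation records (one row per domain x protein x term) over
# the proteins shared by both annotation maps; namespace roots are excluded
# from the mapping vocabulary when a dag is supplied.
coannotation_records <- function(corpus, dag = NULL) {
  shared <- corpus$shared_proteins
  roots <- if (is.null(dag)) character(0) else unname(dag$roots)
  pieces <- lapply(shared, function(p) {
    doms <- corpus$protein_domains[[p]]
    gos <- setdiff(corpus$protein_go[[p]], roots)
    if (length(doms) == 0L || length(gos) == 0L) return(NULL)
    data.frame(domain_id = rep(doms, each = length(gos)),
               protein_id = p,
               go_id = rep(gos, times = length(doms)),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, pieces)
  if (is.null(records) || nrow(records) == 0L)
    stopf("no protein is co-annotated with both a domain and a GO term")
  rownames(records) <- NULL
  records
}

#' Build the initial domain-GO mapping table
#'
#' Every (domain, term) pair co-annotated on at least one shared protein
#' becomes one row, with support `n` (co-annotated proteins), the marginal
#' protein counts, and the co-occurrence similarity `s`.
#'
#' @param corpus An `annotation_corpus`.
#' @param dag Optional `ontology_dag`; when given, namespace roots are
#'   excluded from the mapping vocabulary (they co-occur with everything).
#' @return A `mapping_table` (data.frame with columns domain_id, go_id, n,
#'   n_domain, n_go, s) carrying the co-annotation records and provenance as
#'   attributes.
#' @export
build_initial_mappings <- function(corpus, dag = NULL) {
  if (length(corpus$shared_proteins) == 0L)
    stopf("no protein appears in both the domain and the GO annotation maps")
  records <- coannotation_records(corpus, dag)
  mapping_from_records(records, corpus$domain_counts, corpus$go_counts,
                       provenance = "original",
                       corpus_digest = object_digest(corpus[c(
                         "protein_domains", "protein_go")]))
}

#' Randomize a mapping table by shuffling its GO column
#'
#' Builds the null model used for threshold selection. By default the GO
#' column of the underlying co-annotation record list is permuted uniformly
#' at random and the pair table (n, marginals, S) is recomputed from the
#' shuffled records, which preserves both column marginal multisets at the
#' record level and yields a proper null for S. `unit = "pair"` instead
#' permutes the GO column of the unique-pair table itself, keeping each row's
#' original n.
#'
#' @param table A `mapping_table` with provenance `"original"`.
#' @param seed Integer seed; randomization has no hidden global state.
#' @param unit `"record"` (default) or `"pair"`.
#' @return A `mapping_table` with provenance `"randomized"`.
#' @export
randomize_mappings <- function(table, seed, unit = c("record", "pair")) {
  unit <- match.arg(unit)
  if (!identical(attr(table, "provenance"), "original"))
    stopf("randomize_mappings expects a table with provenance 'original'")
  if (unit == "record") {
    records <- attr(table, "records")
    if (is.null(records)) stopf("mapping table carries no co-annotation records")
    perm <- withr::with_seed(seed, sample.int(nrow(records)))
    shuffled <- records
    shuffled$go_id <- records$go_id[perm]
    mapping_from_records(shuffled, attr(table, "domain_counts"),
                         attr(table, "go_counts"),
                         provenance = "randomized",
                         corpus_digest = attr(table, "corpus_digest"))
  } else {
    perm <- withr::with_seed(seed, sample.int(nrow(table)))
    out <- as.data.frame(table)
    out$go_id <- out$go_id[perm]
    out <- out[order(out$domain_id, out$go_id), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("mapping_table", "data.frame"),
              provenance = "randomized",
              corpus_digest = attr(table, "corpus_digest"))
  }
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the two-sided statistic
#' `D = sup |ECDF_a - ECDF_b|` and its p-value. With tied values (common for
#' the discrete S distribution) the asymptotic approximation is used.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stopf("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                         alternative = "two.sided"))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Select (S, n) reliability thresholds by KS testing against the null
#'
#' For each candidate pair `(s_min, n_min)` both tables are filtered to rows
#' with `s >= s_min` and `n >= n_min` and the two filtered S distributions are
#' compared with a two-sample KS test. The selected thresholds are the minimal
#' candidate (ascending `n_min`, then ascending `s_min`) whose p-value falls
#' below `alpha`; if none does, the selection is empty and `no_separation` is
#' set.
#'
#' @param original,randomized `mapping_table`s to compare.
#' @param s_grid Candidate S lower bounds (default 0.1..0.6).
#' @param n_grid Candidate n lower bounds (default 1..5).
#' @param alpha Significance level (default 0.01).
#' @return A `threshold_selection`: list with `grid` (data.frame of candidate
#'   results), `selected` (list s_min/n_min or NULL), `alpha`,
#'   `no_separation`.
#' @export
select_thresholds <- function(original, randomized,
                              s_grid = seq(0.1, 0.6, by = 0.1),
                              n_grid = 1:5, alpha = 0.01) {
  if (length(s_grid) == 0L || length(n_grid) == 0L) stopf("empty grid")
  if (alpha <= 0 || alpha >= 1) {
    if (alpha != 1) stopf("alpha must lie in (0, 1]")
  }
  grid <- expand.grid(n_min = sort(n_grid), s_min = sort(s_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_min, grid$s_min), , drop = FALSE]
  rownames(grid) <- NULL
  grid$statistic <- NA_real_
  grid$p_value <- NA_real_
  grid$n_original <- NA_integer_
  grid$n_randomized <- NA_integer_
  grid$testable <- FALSE
  grid$pass <- FALSE
  for (i in seq_len(nrow(grid))) {
    so <- original$s[original$s >= grid$s_min[[i]] & original$n >= grid$n_min[[i]]]
    sr <- randomized$s[randomized$s >= grid$s_min[[i]] & randomized$n >= grid$n_min[[i]]]
    grid$n_original[[i]] <- length(so)
    grid$n_randomized[[i]] <- length(sr)
    if (length(so) == 0L || length(sr) == 0L) next
    ks <- ks_two_sample(so, sr)
    grid$statistic[[i]] <- ks$statistic
    grid$p_value[[i]] <- ks$p_value
    grid$testable[[i]] <- TRUE
    grid$pass[[i]] <- ks$p_value < alpha
  }
  sel_idx <- which(grid$pass)
  selected <- if (length(sel_idx)) {
    list(s_min = grid$s_min[[sel_idx[[1L]]]], n_min = grid$n_min[[sel_idx[[1L]]]])
  } else NULL
  structure(list(grid = grid, selected = selected, alpha = alpha,
                 no_separation = is.null(selected)),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  if (x$no_separation) {
    cat("<threshold_selection> no candidate pair separates original from null\n")
  } else {
    cat(sprintf("<threshold_selection> selected n >= %d, S >= %.2f (alpha = %g)\n",
                x$selected$n_min, x$selected$s_min, x$alpha))
  }
  invisible(x)
}

#' Filter a mapping table on reliability thresholds
#'
#' Retains rows with `n >= n_min` and `s > s_min` (strict on S, inclusive on
#' n, mirroring the "n >= 2 and S > 0.2" safety choice).
#'
#' @param table A `mapping_table` (or EM-augmented data.frame).
#' @param s_min Strict lower bound on S (default 0.2).
#' @param n_min Inclusive lower bound on n (default 2).
#' @return The filtered table; co-annotation records, if attached, are
#'   restricted to surviving pairs.
#' @export
filter_mappings <- function(table, s_min = 0.2, n_min = 2L) {
  keep <- table$s > s_min & table$n >= n_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  records <- attr(table, "records")
  if (!is.null(records)) {
    keys <- pair_key(out$domain_id, out$go_id)
    rec_keep <- pair_key(records$domain_id, records$go_id) %in% keys
    attr(out, "records") <- records[rec_keep, , drop = FALSE]
  }
  attr(out, "provenance") <- attr(table, "provenance")
  attr(out, "corpus_digest") <- attr(table, "corpus_digest")
  attr(out, "domain_counts") <- attr(table, "domain_counts")
  attr(out, "go_counts") <- attr(table, "go_counts")
  class(out) <- class(table)
  out
}

#' Write / read a mapping table as TSV
#'
#' Columns: domain_id, go_id, n, n_domain, n_go, s, plus theta/e columns when
#' present. The co-annotation record attribute is not serialized.
#' @param table A `mapping_table`.
#' @param path File path.
#' @export
write_mapping_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  df <- read_tsv(path)
  structure(df, class = c("mapping_table", "data.frame"),
            provenance = "original")
}
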