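# Annotation ingestion: protein->domain TSV, protein->GO GAF (or a simplified
# 3-column table), ancestor propagation, and corpus assembly.

#' Read protein-domain annotations from a TSV
#'
#' Expects a header with columns `protein_id`, `domain_id`, `entry_type`.
#' Rows whose entry type does not match `entry_type_filter` are dropped (the
#' InterPro convention of keeping only true "Domain" entries, excluding
#' families, sites etc.); duplicates collapse to set membership.
#'
#' @param path TSV path (optionally gzipped).
#' @param entry_type_filter Entry type to retain (default `"Domain"`).
#' @return Named list protein_id -> sorted character vector of domain ids.
#' @export
read_domain_annotations <- function(path, entry_type_filter = "Domain") {
  df <- read_tsv(path)
  need <- c("protein_id", "domain_id", "entry_type")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("domain annotation table is missing column(s): %s",
          paste(missing, collapse = ", "))
  df <- df[df$entry_type == entry_type_filter, , drop = FALSE]
  lapply(split(df$domain_id, df$protein_id), function(x) sort(unique(x)))
}

#' Read protein-GO annotations (GAF 2.x or simplified 3-column table)
#'
#' GAF lines are parsed by column position (2 = object id, 4 = qualifier,
#' 5 = GO id, 7 = evidence code); comment lines start with `!`. A tab-separated
#' table with a header `protein_id, go_id, evidence_code` is auto-detected and
#' accepted as a lightweight dialect. Rows are dropped when their evidence code
#' is excluded (default: IEA, the uncurated electronic annotations) or their
#' qualifier contains `NOT`. alt_ids are resolved; annotations to obsolete or
#' unknown terms are dropped with a counter.
#'
#' @param path GAF or TSV path (optionally gzipped).
#' @param dag An `ontology_dag` used to validate and resolve term ids.
#' @param excluded_evidence Character vector of evidence codes to drop.
#' @return Named list protein_id -> sorted character vector of GO ids, with
#'   attribute `counters` (named integer: excluded_evidence, not_qualifier,
#'   obsolete, unknown_term, malformed).
#' @export
read_go_annotations <- function(path, dag, excluded_evidence = "IEA") {
  lines <- read_text_lines(path)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(body) == 0L) stopf("no annotation rows in %s", path)

  counters <- c(excluded_evidence = 0L, not_qualifier = 0L, obsolete = 0L,
                unknown_term = 0L, malformed = 0L)
  first_fields <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  simple <- length(first_fields) <= 3L && first_fields[[1L]] == "protein_id"

  if (simple) {
    df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    protein <- df$protein_id
    go <- df$go_id
    evidence <- if ("evidence_code" %in% names(df)) df$evidence_code
                else rep("EXP", nrow(df))
    qualifier <- rep("", nrow(df))
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 15L
    counters[["malformed"]] <- sum(!ok)
    if (any(!ok)) warnf("skipped %d malformed GAF line(s)", sum(!ok))
    fields <- fields[ok]
    protein <- vapply(fields, `[[`, "", 2L)
    qualifier <- vapply(fields, `[[`, "", 4L)
    go <- vapply(fields, `[[`, "", 5L)
    evidence <- vapply(fields, `[[`, "", 7L)
  }

  drop_ev <- evidence %in% excluded_evidence
  drop_not <- grepl("(^|\\|)NOT($|\\|)", qualifier) | grepl("NOT\\|", qualifier)
  counters[["excluded_evidence"]] <- sum(drop_ev)
  counters[["not_qualifier"]] <- sum(drop_not & !drop_ev)
  keep <- !drop_ev & !drop_not
  protein <- protein[keep]; go <- go[keep]

  go <- resolve_term(dag, go)
  obs <- go %in% dag$obsolete
  unk <- !obs & !(go %in% dag$terms)
  counters[["obsolete"]] <- sum(obs)
  counters[["unknown_term"]] <- sum(unk)
  if (any(obs | unk))
    warnf("dropped %d annotation(s) to obsolete terms and %d to unknown terms",
          sum(obs), sum(unk))
  keep <- !obs & !unk
  protein <- protein[keep]; go <- go[keep]

  if (length(protein) == 0L)
    stopf("no GO annotations survive filtering in %s", path)
  out <- lapply(split(go, protein), function(x) sort(unique(x)))
  attr(out, "counters") <- counters
  out
}

#' Propagate GO annotations to ancestors
#'
#' Replaces each protein's term set with its union over all ancestors reached
#' via `is_a` and `part_of`. Idempotent: propagating a closed set returns it
#' unchanged.
#'
#' @param protein_go Named list protein_id -> character vector of GO ids.
#' @param dag An `ontology_dag`.
#' @return Named list with ancestor-closed term sets (sorted).
#' @export
propagate_go_annotations <- function(protein_go, dag) {
  lapply(protein_go, function(terms) {
    terms <- resolve_term(dag, terms)
    sort(unique(c(terms, unlist(dag$ancestors[terms], use.names = FALSE))))
  })
}

#' Assemble an annotation corpus
#'
#' Bundles the protein->domain and propagated protein->GO maps under a shared
#' protein-id key space. The mapping stage operates on proteins present in
#' both maps.
#'
#' @param protein_domains Named list protein_id -> domain ids.
#' @param protein_go Named list protein_id -> ancestor-closed GO ids.
#' @param evidence_filter Character vector recorded for provenance.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(protein_domains, protein_go,
                              evidence_filter = "IEA excluded") {
  shared <- intersect(names(protein_domains), names(protein_go))
  # Marginal protein counts per domain / per term over each full map: the
  # N_D and N_GO denominators of the co-occurrence score. Co-annotation
  # support is counted on the shared proteins, but a domain's protein count
  # includes proteins without any GO annotation (and vice versa).
  domain_counts <- table(unlist(lapply(protein_domains, unique),
                                use.names = FALSE))
  go_counts <- table(unlist(lapply(protein_go, unique), use.names = FALSE))
  structure(list(
    protein_domains = protein_domains,
    protein_go = protein_go,
    shared_proteins = sort(shared),
    domain_counts = domain_counts,
    go_counts = go_counts,
    evidence_filter = evidence_filter
  ), class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf(
    "<annotation_corpus> %d proteins with domains, %d with GO, %d shared\n",
    length(x$protein_domains), length(x$protein_go),
    length(x$shared_proteins)))
  invisible(x)
}
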