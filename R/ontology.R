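# Gene Ontology ingestion: OBO parsing, ancestor closure over is_a/part_of,
# and per-term information content for semantic-distance evaluation.

#' Parse a Gene Ontology OBO file
#'
#' Reads an OBO 1.2/1.4 flat file and returns the ontology as a directed
#' acyclic graph restricted to `is_a` and `part_of` relations. Other
#' relationship types (`regulates`, ...) are dropped. Obsolete terms are
#' recorded but carry no edges; `alt_id` aliases are resolved to their primary
#' identifiers on lookup.
#'
#' @param path Path to an OBO file (optionally gzip-compressed).
#' @return An object of class `ontology_dag` with elements:
#'   \describe{
#'     \item{terms}{character vector of non-obsolete primary term ids}
#'     \item{edges}{data.frame (child, parent, relation)}
#'     \item{namespaces}{named character, term -> namespace}
#'     \item{roots}{named character, namespace -> root term}
#'     \item{obsolete}{character vector of obsolete term ids}
#'     \item{alt_map}{named character, alt_id -> primary id}
#'     \item{ancestors}{named list, term -> ancestor set over both relations}
#'   }
#' @export
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'              "name: root", "namespace: molecular_function", "", "[Term]",
#'              "id: GO:0000002", "name: child",
#'              "namespace: molecular_function", "is_a: GO:0000001 ! root"),
#'            obo)
#' dag <- parse_obo(obo)
#' ancestors(dag, "GO:0000002")
parse_obo <- function(path) {
  lines <- read_text_lines(path)
  stanzas <- list()
  cur <- NULL
  cur_type <- ""
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      if (!is.null(cur) && cur_type == "Term") stanzas[[length(stanzas) + 1L]] <- cur
      cur_type <- sub("^\\[(.*)\\]$", "\\1", ln)
      cur <- list(.line = i)
      next
    }
    if (cur_type == "") next  # header lines
    colon <- regexpr(": ", ln, fixed = TRUE)
    if (colon < 0) colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) stopf("malformed OBO stanza line %d: %s", i, ln)
    key <- substr(ln, 1L, colon - 1L)
    val <- trimws(substr(ln, colon + attr(colon, "match.length"), nchar(ln)))
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    cur[[length(cur) + 1L]] <- c(key, val)
  }
  if (!is.null(cur) && cur_type == "Term") stanzas[[length(stanzas) + 1L]] <- cur

  if (length(stanzas) == 0L) stopf("no [Term] stanzas found in %s", path)

  term_ids <- character(0)
  namespaces <- character(0)
  obsolete <- character(0)
  alt_from <- character(0); alt_to <- character(0)
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)

  for (st in stanzas) {
    kv <- Filter(function(x) is.character(x) && length(x) == 2L, st)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    id <- vals[keys == "id"]
    if (length(id) != 1L)
      stopf("malformed OBO [Term] stanza near line %d: missing id", st$.line)
    is_obs <- any(keys == "is_obsolete" & vals == "true")
    if (is_obs) {
      obsolete <- c(obsolete, id)
      next
    }
    term_ids <- c(term_ids, id)
    ns <- vals[keys == "namespace"]
    namespaces[id] <- if (length(ns)) ns[[1L]] else NA_character_
    for (a in vals[keys == "alt_id"]) { alt_from <- c(alt_from, a); alt_to <- c(alt_to, id) }
    for (p in vals[keys == "is_a"]) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, p); e_rel <- c(e_rel, "is_a")
    }
    for (r in vals[keys == "relationship"]) {
      parts <- strsplit(r, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        e_child <- c(e_child, id); e_parent <- c(e_parent, parts[[2L]]); e_rel <- c(e_rel, "part_of")
      }
    }
  }

  if (anyDuplicated(term_ids))
    stopf("duplicate term id in OBO: %s", term_ids[duplicated(term_ids)][1L])
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)
  # drop edges to obsolete/unknown parents (e.g. pruned relationship targets)
  edges <- edges[edges$parent %in% term_ids & edges$child %in% term_ids, ,
                 drop = FALSE]

  dag <- structure(list(
    terms = term_ids,
    edges = edges,
    namespaces = namespaces,
    roots = character(0),
    obsolete = obsolete,
    alt_map = stats::setNames(alt_to, alt_from),
    ancestors = NULL
  ), class = "ontology_dag")

  dag$ancestors <- compute_ancestor_closure(dag, c("is_a", "part_of"))

  # roots: terms with no outgoing is_a/part_of edges
  root_ids <- setdiff(term_ids, unique(edges$child))
  ns_of_root <- namespaces[root_ids]
  if (anyDuplicated(ns_of_root[!is.na(ns_of_root)]))
    warnf("multiple root terms share a namespace; using the first per namespace")
  dag$roots <- stats::setNames(root_ids, ns_of_root)[!duplicated(ns_of_root)]

  # every non-root term must reach exactly one namespace root
  for (t in setdiff(term_ids, root_ids)) {
    hit <- intersect(dag$ancestors[[t]], root_ids)
    if (length(hit) != 1L)
      stopf("term %s reaches %d namespace roots (expected exactly 1)",
            t, length(hit))
  }
  dag
}

# Topological-order dynamic program; detects cycles (Kahn's algorithm).
compute_ancestor_closure <- function(dag, relations) {
  terms <- dag$terms
  edges <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  idx <- stats::setNames(seq_along(terms), terms)
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  # Kahn: repeatedly remove nodes all of whose parents are resolved
  anc <- stats::setNames(vector("list", length(terms)), terms)
  out_deg <- lengths(parents)
  children_of <- split(edges$child, factor(edges$parent, levels = terms))
  queue <- terms[out_deg == 0L]
  resolved <- character(0)
  n_done <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    ps <- parents[[t]]
    anc[[t]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    n_done <- n_done + 1L
    for (ch in children_of[[t]]) {
      out_deg[[idx[[ch]]]] <- out_deg[[idx[[ch]]]] - 1L
      if (out_deg[[idx[[ch]]]] == 0L) queue <- c(queue, ch)
    }
  }
  if (n_done < length(terms))
    stopf("ontology relation graph contains a cycle over is_a/part_of")
  anc
}

#' Resolve a possibly-aliased term id to its primary id
#'
#' @param dag An `ontology_dag`.
#' @param term Character vector of term ids (primary or alt_id).
#' @return Character vector of primary ids; unknown ids are returned unchanged.
#' @export
resolve_term <- function(dag, term) {
  hit <- match(term, names(dag$alt_map))
  term[!is.na(hit)] <- unname(dag$alt_map[hit[!is.na(hit)]])
  term
}

#' Ancestor set of a term
#'
#' All terms reachable from `term` by following the selected relation labels
#' child-to-parent, excluding `term` itself.
#'
#' @param dag An `ontology_dag`.
#' @param term A single term id (alt_ids are resolved).
#' @param relations Subset of `c("is_a", "part_of")`.
#' @return Character vector of ancestor term ids (sorted).
#' @export
ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  stopifnot(length(term) == 1L)
  term <- resolve_term(dag, term)
  if (term %in% dag$obsolete) stopf("term %s is obsolete", term)
  if (!term %in% dag$terms) stopf("unknown term: %s", term)
  if (setequal(relations, c("is_a", "part_of")) && !is.null(dag$ancestors))
    return(dag$ancestors[[term]])
  compute_ancestor_closure(dag, relations)[[term]]
}

#' Per-term information content from a propagated annotation corpus
#'
#' IC is the marginal-frequency definition computed per namespace:
#' `ic(t) = -log2(n_t / n_root)` where `n_t` counts proteins annotated with
#' `t` and `n_root` counts proteins annotated with t's namespace root.
#' Annotation sets must already be ancestor-closed, which makes IC monotone
#' non-decreasing from parent to child. Terms never observed in the corpus are
#' smoothed to the maximum observed IC of their namespace so rankings stay
#' finite.
#'
#' @param dag An `ontology_dag`.
#' @param protein_go Named list protein_id -> character vector of GO ids,
#'   ancestor-closed (e.g. output of [propagate_go_annotations()]).
#' @return An `ic_table`: data.frame (term, namespace, ic) with attributes
#'   `source_corpus_size` and `ic_lookup` (named numeric for O(1) access).
#' @export
compute_information_content <- function(dag, protein_go) {
  if (length(protein_go) == 0L) stopf("empty annotation corpus")
  all_terms <- unlist(protein_go, use.names = FALSE)
  counts <- table(all_terms)
  cnt <- stats::setNames(rep(0, length(dag$terms)), dag$terms)
  cnt[names(counts)] <- as.numeric(counts)

  ns <- dag$namespaces[dag$terms]
  ic <- rep(NA_real_, length(dag$terms))
  names(ic) <- dag$terms
  for (nsname in unique(ns[!is.na(ns)])) {
    in_ns <- !is.na(ns) & ns == nsname
    root <- dag$roots[[nsname]]
    root_cnt <- if (!is.null(root)) cnt[[root]] else max(cnt[in_ns], 0)
    if (root_cnt == 0) { ic[in_ns] <- 0; next }
    with_cnt <- in_ns & cnt > 0
    ic[with_cnt] <- -log2(cnt[with_cnt] / root_cnt)
    max_ic <- if (any(with_cnt)) max(ic[with_cnt]) else 0
    ic[in_ns & cnt == 0] <- max_ic
  }
  ic[is.na(ic)] <- 0

  out <- data.frame(term = dag$terms, namespace = unname(ns), ic = unname(ic),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ic_table", "data.frame"),
            source_corpus_size = length(protein_go),
            ic_lookup = ic,
            ic_definition = "marginal frequency, per namespace, bits")
}

#' Write an information-content table to TSV
#' @param ic_table An `ic_table` from [compute_information_content()].
#' @param path Output path.
#' @export
write_ic_table <- function(ic_table, path) write_tsv(ic_table, path)

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges, %d obsolete, namespaces: %s\n",
              length(x$terms), nrow(x$edges), length(x$obsolete),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}
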