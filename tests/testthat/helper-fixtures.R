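# Fixture builders shared across the suite. Everything is generated in code;
# no files ship with the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write an OBO file from a term table: data.frame(id, ns, parent, rel) where
# parent NA marks a root. Extra stanza lines can be injected per id.
write_test_obo <- function(df, path = tempfile(fileext = ".obo"),
                           extra = list()) {
  lines <- c("format-version: 1.2")
  for (i in seq_len(nrow(df))) {
    lines <- c(lines, "", "[Term]",
               paste0("id: ", df$id[[i]]),
               paste0("name: term ", df$id[[i]]),
               paste0("namespace: ", df$ns[[i]]))
    if (!is.na(df$parent[[i]])) {
      lines <- c(lines,
                 if (df$rel[[i]] == "is_a") paste0("is_a: ", df$parent[[i]])
                 else paste0("relationship: part_of ", df$parent[[i]]))
    }
    if (!is.null(extra[[df$id[[i]]]]))
      lines <- c(lines, extra[[df$id[[i]]]])
  }
  writeLines(lines, path)
  path
}

# 12-term ontology over all three namespaces with mixed is_a/part_of edges,
# including a diamond (t05 -> {t03, t04} -> t02 -> root).
toy_term_table <- function() {
  data.frame(
    id = sprintf("GO:%07d", 1:12),
    ns = c("molecular_function", "molecular_function", "molecular_function",
           "molecular_function", "molecular_function",
           "biological_process", "biological_process", "biological_process",
           "biological_process",
           "cellular_component", "cellular_component", "cellular_component"),
    parent = c(NA, "GO:0000001", "GO:0000002", "GO:0000002", NA,
               NA, "GO:0000006", "GO:0000007", "GO:0000008",
               NA, "GO:0000010", "GO:0000011"),
    rel = c(NA, "is_a", "is_a", "part_of", NA,
            NA, "is_a", "part_of", "is_a",
            NA, "is_a", "part_of"),
    stringsAsFactors = FALSE
  )
}

# The diamond: GO:0000005 is_a GO:0000003 and part_of GO:0000004.
toy_dag <- function() {
  df <- toy_term_table()
  path <- write_test_obo(df[-5, ], extra = list())
  lines <- readLines(path)
  lines <- c(lines, "", "[Term]", "id: GO:0000005", "name: diamond child",
             "namespace: molecular_function", "is_a: GO:0000003",
             "relationship: part_of GO:0000004",
             "alt_id: GO:0000105")
  writeLines(lines, path)
  parse_obo(path)
}

# A small corpus with arbitrary domain/term vocabularies and no ontology
# (dag-free operations only), deterministic under seed.
random_corpus <- function(seed, n_prot = 30L, n_dom = 5L, n_go = 8L,
                          max_dom = 3L, max_go = 4L) {
  withr::with_seed(seed, {
    doms <- sprintf("D%02d", seq_len(n_dom))
    gos <- sprintf("G%02d", seq_len(n_go))
    prots <- sprintf("p%03d", seq_len(n_prot))
    pd <- lapply(prots, function(p)
      sort(sample(doms, sample.int(min(max_dom, n_dom), 1L))))
    pg <- lapply(prots, function(p)
      sort(sample(gos, sample.int(min(max_go, n_go), 1L))))
    names(pd) <- prots
    names(pg) <- prots
    # a few proteins appear in only one of the maps
    drop_d <- sample(prots, 2L)
    drop_g <- sample(setdiff(prots, drop_d), 2L)
    annotation_corpus(pd[setdiff(prots, drop_d)], pg[setdiff(prots, drop_g)])
  })
}

# Corpus for the single-pair EM fixture: one co-annotated protein and
# z_domain / z_go proteins carrying only the domain / only the term.
single_pair_corpus <- function(z_domain, z_go) {
  pd <- c(list(p00 = "d1"),
          stats::setNames(rep(list("d1"), z_domain),
                          sprintf("pa%02d", seq_len(z_domain))))
  pg <- c(list(p00 = "g1"),
          stats::setNames(rep(list("g1"), z_go),
                          sprintf("pb%02d", seq_len(z_go))))
  annotation_corpus(pd[lengths(pd) > 0], pg[lengths(pg) > 0])
}

# Three co-annotated pairs competing on two proteins:
# p1 carries {d1, d2} x {g1}; p2 carries {d1} x {g1, g2}.
three_pair_corpus <- function() {
  annotation_corpus(
    list(p1 = c("d1", "d2"), p2 = "d1"),
    list(p1 = "g1", p2 = c("g1", "g2"))
  )
}

# Hand-rolled mapping table (no corpus behind it) for threshold/ranking tests.
fake_mapping_table <- function(s, n, domain_id = NULL, go_id = NULL) {
  k <- length(s)
  df <- data.frame(
    domain_id = if (is.null(domain_id)) sprintf("D%03d", seq_len(k)) else domain_id,
    go_id = if (is.null(go_id)) sprintf("G%03d", seq_len(k)) else go_id,
    n = as.integer(n), n_domain = pmax(as.integer(n), 5L),
    n_go = pmax(as.integer(n), 5L), s = s,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("mapping_table", "data.frame"),
            provenance = "original")
}
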