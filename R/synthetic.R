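# Synthetic benchmark generator: small annotation corpora with planted
# domain->GO associations, annotation noise and dropout, a curated-style
# reference set, and a held-out "no-knowledge" benchmark split -- so every
# pipeline stage is testable without downloads.
#
# DAG layout: three namespace roots. Planted terms sit directly under their
# root; each namespace also carries one common background term fed by the
# noise process, a chain reaching dag_depth below the first planted term, and
# unannotated filler terms. Two deliberate consequences of this construction:
#   * a planted term's only ancestor is its (mapping-excluded) root, so the
#     planted co-occurrence signal is not aliased into intermediate ancestors
#     -- a planted leaf at the bottom of a private chain would hand its
#     perfect co-occurrence signal verbatim to every chain ancestor, and a
#     shared mid-level parent of few planted terms would inherit enough of it
#     to hover at the reliability threshold;
#   * noise lands on a small set of frequent background terms (as in real
#     corpora, where broad terms absorb most spurious annotation mass), so a
#     noise term's marginal protein count is large and a handful of
#     coincidental hits on one domain's proteins cannot lift the Dice
#     co-occurrence score S = 2n/(n_domain + n_go) above the threshold.

#' Synthetic corpus configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 500 proteins, 50 domains, 100 terms, 30 planted associations,
#' 20% annotation noise, 10% dropout.
#'
#' @param n_proteins,n_domains,n_terms Entity counts (`n_terms` includes the
#'   three namespace roots).
#' @param dag_depth Guaranteed chain depth under each root (default 4).
#' @param planted Number of true domain->GO associations, injective in both
#'   coordinates.
#' @param domains_per_protein Integer range `c(min, max)` of distinct domains
#'   drawn per protein. The default 1..1 guarantees that no two planted
#'   associations share proteins, so each planted pair's co-occurrence signal
#'   is attributable to that pair alone; widen the range to study competing
#'   multi-domain explanations.
#' @param noise_rate Probability a protein gains one random spurious GO term.
#' @param dropout_rate Probability a planted term is omitted from an eligible
#'   protein.
#' @param benchmark_fraction Fraction of proteins held out as no-knowledge
#'   benchmark targets (GO withheld from training; default 0.2).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 500L, n_domains = 50L,
                             n_terms = 100L, dag_depth = 4L, planted = 30L,
                             domains_per_protein = c(1L, 1L),
                             noise_rate = 0.2, dropout_rate = 0.1,
                             benchmark_fraction = 0.2, seed = 1L) {
  stopifnot(is_count(n_proteins), is_count(n_domains), is_count(n_terms),
            is_count(dag_depth), is_count(planted),
            length(domains_per_protein) == 2L,
            noise_rate >= 0, noise_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            benchmark_fraction >= 0, benchmark_fraction < 1)
  if (domains_per_protein[[1L]] < 1L)
    stopf("domains_per_protein must be at least 1, otherwise planted pairs are unobservable")
  if (planted > n_domains)
    stopf("planted associations must be injective in domains (planted <= n_domains)")
  per_ns <- ceiling(planted / 3) + 1L + max(0L, dag_depth - 1L)
  if (n_terms < 3L + 3L * per_ns)
    stopf("n_terms too small: need >= %d for %d planted pairs and depth-%d chains",
          3L + 3L * per_ns, planted, dag_depth)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_domains = as.integer(n_domains),
                 n_terms = as.integer(n_terms),
                 dag_depth = as.integer(dag_depth),
                 planted = as.integer(planted),
                 domains_per_protein = as.integer(domains_per_protein),
                 noise_rate = noise_rate, dropout_rate = dropout_rate,
                 benchmark_fraction = benchmark_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# OBO text for a generated ontology.
synthetic_obo_lines <- function(terms, names, namespaces, parents, relations) {
  out <- c("format-version: 1.2", "ontology: synthetic-go")
  for (i in seq_along(terms)) {
    out <- c(out, "", "[Term]",
             paste0("id: ", terms[[i]]),
             paste0("name: ", names[[i]]),
             paste0("namespace: ", namespaces[[i]]))
    if (!is.na(parents[[i]])) {
      out <- c(out, if (relations[[i]] == "is_a")
        paste0("is_a: ", parents[[i]])
      else paste0("relationship: part_of ", parents[[i]]))
    }
  }
  out
}

#' Generate a synthetic corpus with planted associations
#'
#' Builds a three-namespace ontology, assigns each protein a random domain
#' set, annotates proteins carrying a planted domain with the planted term
#' (subject to dropout), sprinkles random noise terms, ancestor-closes all GO
#' sets, and splits off a no-knowledge benchmark whose GO annotations are
#' withheld from the training corpus.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_truth` list: `config`, `dag`, `corpus` (training),
#'   `benchmark` (a `benchmark_set`), `reference` (planted pairs as a
#'   `reference_set`), `planted_pairs`, `protein_domains`, `direct_go`
#'   (un-propagated training annotations), `benchmark_direct_go`,
#'   `obo_lines`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    ns_names <- c("molecular_function", "biological_process",
                  "cellular_component")
    terms <- sprintf("GO:%07d", seq_len(config$n_terms))
    roots <- terms[1:3]
    term_name <- c(paste0(ns_names, " root"),
                   sprintf("synthetic term %d", seq_len(config$n_terms - 3L)))
    namespaces <- character(config$n_terms)
    namespaces[1:3] <- ns_names
    parents <- rep(NA_character_, config$n_terms)
    relations <- rep(NA_character_, config$n_terms)

    nonroot <- split(terms[-(1:3)],
                     rep_len(1:3, config$n_terms - 3L))
    namespaces[match(unlist(nonroot), terms)] <-
      rep(ns_names, times = lengths(nonroot))

    quota <- diff(floor(config$planted * 0:3 / 3))
    planted_terms <- character(0)
    background_terms <- character(0)
    for (k in 1:3) {
      pool <- nonroot[[k]]
      pl <- pool[seq_len(quota[[k]])]
      planted_terms <- c(planted_terms, pl)
      parents[match(pl, terms)] <- roots[[k]]
      relations[match(pl, terms)] <-
        ifelse(stats::runif(length(pl)) < 0.2, "part_of", "is_a")
      rest <- pool[-seq_len(quota[[k]])]
      bg <- rest[[1L]]
      background_terms <- c(background_terms, bg)
      parents[match(bg, terms)] <- roots[[k]]
      relations[match(bg, terms)] <- "is_a"
      rest <- rest[-1L]
      # chain below the first planted term so the deepest leaf sits at
      # dag_depth: root -> planted -> c1 -> c2 -> ...
      n_chain <- max(0L, config$dag_depth - 1L)
      chain <- rest[seq_len(min(n_chain, length(rest)))]
      prev <- pl[[1L]]
      for (t in chain) {
        parents[match(t, terms)] <- prev
        relations[match(t, terms)] <- if (stats::runif(1) < 0.2) "part_of" else "is_a"
        prev <- t
      }
      # unannotated filler terms pad the namespace under its root
      for (t in setdiff(rest, chain)) {
        parents[match(t, terms)] <- roots[[k]]
        relations[match(t, terms)] <- if (stats::runif(1) < 0.2) "part_of" else "is_a"
      }
    }

    obo_lines <- synthetic_obo_lines(terms, term_name, namespaces, parents,
                                     relations)
    obo_path <- tempfile(fileext = ".obo")
    writeLines(obo_lines, obo_path)
    dag <- parse_obo(obo_path)
    unlink(obo_path)

    domains <- sprintf("IPR%06d", seq_len(config$n_domains))
    planted_domains <- sample(domains, config$planted)
    planted_pairs <- data.frame(domain_id = planted_domains,
                                go_id = planted_terms,
                                stringsAsFactors = FALSE)

    proteins <- sprintf("P%05d", seq_len(config$n_proteins))
    k_dom <- sample(seq(config$domains_per_protein[[1L]],
                        config$domains_per_protein[[2L]]),
                    config$n_proteins, replace = TRUE)
    # Balanced domain assignment: domains are drawn with probability favoring
    # the least-used ones, keeping the per-domain protein counts near-equal.
    # The generator is a controlled test bed, so the marginals are controlled
    # rather than skewed as in real databases: equal-size domain protein sets
    # keep the co-occurrence score of chance overlaps well below that of the
    # planted associations.
    usage <- stats::setNames(rep(0L, config$n_domains), domains)
    protein_domains <- vector("list", config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      w <- max(usage) - usage + 1L
      picked <- sample(domains, k_dom[[i]], prob = w)
      usage[picked] <- usage[picked] + 1L
      protein_domains[[i]] <- sort(picked)
    }
    names(protein_domains) <- proteins

    # Noise draws come from the common background vocabulary (one frequent
    # term per namespace), mirroring the skew of real corpora where broad
    # terms absorb most spurious annotation mass.
    noise_pool <- background_terms
    direct_go <- stats::setNames(vector("list", config$n_proteins), proteins)
    planted_of_domain <- split(planted_pairs$go_id, planted_pairs$domain_id)
    for (p in proteins) {
      gos <- character(0)
      for (d in protein_domains[[p]]) {
        g <- planted_of_domain[[d]]
        if (!is.null(g) && stats::runif(1) >= config$dropout_rate)
          gos <- c(gos, g)
      }
      if (stats::runif(1) < config$noise_rate)
        gos <- c(gos, sample(noise_pool, 1L))
      direct_go[[p]] <- sort(unique(gos))
    }
    direct_go <- direct_go[lengths(direct_go) > 0L]
    protein_go <- propagate_go_annotations(direct_go, dag)

    n_bench <- floor(config$benchmark_fraction * length(protein_go))
    bench_proteins <- sort(sample(names(protein_go), n_bench))
    train_go <- protein_go[setdiff(names(protein_go), bench_proteins)]
    truth <- protein_go[bench_proteins]

    corpus <- annotation_corpus(protein_domains, train_go,
                                evidence_filter = "synthetic (EXP only)")
    benchmark <- if (n_bench > 0L)
      benchmark_set(truth, dag = dag, knowledge_type = "no-knowledge")
    else NULL

    structure(list(
      config = config,
      dag = dag,
      corpus = corpus,
      benchmark = benchmark,
      reference = reference_set(planted_pairs, label = "planted"),
      planted_pairs = planted_pairs,
      protein_domains = protein_domains,
      direct_go = direct_go[setdiff(names(direct_go), bench_proteins)],
      benchmark_direct_go = direct_go[intersect(names(direct_go),
                                                bench_proteins)],
      obo_lines = obo_lines
    ), class = "synthetic_truth")
  })
}

gaf_aspect <- function(dag, go_id) {
  c(molecular_function = "F", biological_process = "P",
    cellular_component = "C")[dag$namespaces[go_id]]
}

#' Write a synthetic corpus as a file bundle
#'
#' Writes `go.obo`, `annotations.gaf` (training annotations, evidence EXP),
#' `domains.tsv`, `reference.tsv`, `benchmark.tsv`, and `manifest.json`
#' recording the generating configuration, its digest, and per-file md5sums.
#'
#' @param truth A `synthetic_truth` from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory %s", dir)
  writeLines(truth$obo_lines, file.path(dir, "go.obo"))

  gaf <- c("!gaf-version: 2.2")
  for (p in names(truth$direct_go)) {
    for (g in truth$direct_go[[p]]) {
      gaf <- c(gaf, paste(c("SYN", p, p, "", g, "SYN_REF:0000001", "EXP", "",
                            gaf_aspect(truth$dag, g), "", "", "protein",
                            "taxon:0", "20160901", "SYN", "", ""),
                          collapse = "\t"))
    }
  }
  writeLines(gaf, file.path(dir, "annotations.gaf"))

  dom_rows <- data.frame(
    protein_id = rep(names(truth$protein_domains),
                     lengths(truth$protein_domains)),
    domain_id = unlist(truth$protein_domains, use.names = FALSE),
    entry_type = "Domain", stringsAsFactors = FALSE)
  write_tsv(dom_rows, file.path(dir, "domains.tsv"))

  write_tsv(as.data.frame(truth$reference), file.path(dir, "reference.tsv"))

  files <- c("go.obo", "annotations.gaf", "domains.tsv", "reference.tsv")
  if (!is.null(truth$benchmark)) {
    bench_rows <- data.frame(
      protein_id = rep(names(truth$benchmark$truth),
                       lengths(truth$benchmark$truth)),
      go_id = unlist(truth$benchmark$truth, use.names = FALSE),
      stringsAsFactors = FALSE)
    write_tsv(bench_rows, file.path(dir, "benchmark.tsv"))
    files <- c(files, "benchmark.tsv")
  }
  manifest <- list(
    generator = "domap::generate_synthetic",
    config = unclass(truth$config),
    config_digest = object_digest(unclass(truth$config)),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture bundle back into corpus objects
#'
#' Inverse of [write_fixture_bundle()]: parses the ontology, loads and
#' propagates the annotations, and rebuilds the corpus, reference, and
#' benchmark.
#'
#' @param dir Bundle directory.
#' @return List with `dag`, `corpus`, `reference`, `benchmark`.
#' @export
read_fixture_bundle <- function(dir) {
  dag <- parse_obo(file.path(dir, "go.obo"))
  protein_domains <- read_domain_annotations(file.path(dir, "domains.tsv"))
  raw_go <- read_go_annotations(file.path(dir, "annotations.gaf"), dag)
  protein_go <- propagate_go_annotations(raw_go, dag)
  corpus <- annotation_corpus(protein_domains, protein_go)
  reference <- if (file.exists(file.path(dir, "reference.tsv")))
    read_reference_mappings(file.path(dir, "reference.tsv")) else NULL
  benchmark <- if (file.exists(file.path(dir, "benchmark.tsv")))
    read_benchmark(file.path(dir, "benchmark.tsv"), dag = dag) else NULL
  list(dag = dag, corpus = corpus, reference = reference,
       benchmark = benchmark)
}
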