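# Pipeline driver: map -> randomize -> thresholds -> filter -> (EM + E) ->
# predict -> evaluate, with every stage output written to disk and a manifest
# recording the configuration and per-file digests.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline stages. `bundle_dir` must contain
#' `go.obo`, `annotations.gaf`, `domains.tsv` and may contain `reference.tsv`
#' and `benchmark.tsv` (the layout written by [write_fixture_bundle()]).
#'
#' @param bundle_dir Input directory.
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed for the randomized null.
#' @param s_min,n_min Final reliability filter (defaults 0.2 / 2, the safety
#'   choice above the minimal KS-selected pair).
#' @param s_grid,n_grid,alpha Threshold-selection grid and significance level.
#' @param with_em Run the EM stage and E scores (default TRUE).
#' @param em_s_min S cutoff restricting which pairs enter the EM triplet pool
#'   (default 0.1).
#' @param em Settings from [em_config()].
#' @param prediction_floor Min-max floor for E-mode prediction scores.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bundle_dir, out_dir, seed = 1L,
                            s_min = 0.2, n_min = 2L,
                            s_grid = seq(0.1, 0.6, by = 0.1), n_grid = 1:5,
                            alpha = 0.01, with_em = TRUE, em_s_min = 0.1,
                            em = em_config(), prediction_floor = 0.01) {
  structure(list(bundle_dir = bundle_dir, out_dir = out_dir,
                 seed = as.integer(seed), s_min = s_min,
                 n_min = as.integer(n_min), s_grid = s_grid, n_grid = n_grid,
                 alpha = alpha, with_em = with_em, em_s_min = em_s_min,
                 em = unclass(em), prediction_floor = prediction_floor),
            class = "pipeline_config")
}

#' Run the full mapping-to-evaluation pipeline
#'
#' Executes every stage on a file bundle and writes the artifacts listed in
#' the returned manifest: `mappings.tsv`, `randomized.tsv`,
#' `threshold_grid.tsv`, `filtered.tsv`, optionally `em.tsv` and
#' `em_trace.tsv`, one `predictions_<mode>.tsv` per prediction mode, and
#' `evaluation.json` when a benchmark is present. `manifest.json` records the
#' configuration, its digest, and md5sums of every stage output, so two runs
#' with identical configuration and seed produce byte-identical artifacts.
#'
#' @param config A `pipeline_config`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stopf("cannot create output directory %s", out)
  emcfg <- do.call(em_config, config$em)

  bundle <- read_fixture_bundle(config$bundle_dir)
  dag <- bundle$dag
  corpus <- bundle$corpus

  artifacts <- character(0)
  put <- function(name) artifacts <<- c(artifacts, name)

  mappings <- build_initial_mappings(corpus, dag = dag)
  write_mapping_table(mappings, file.path(out, "mappings.tsv")); put("mappings.tsv")

  randomized <- randomize_mappings(mappings, seed = config$seed)
  write_mapping_table(randomized, file.path(out, "randomized.tsv")); put("randomized.tsv")

  selection <- select_thresholds(mappings, randomized,
                                 s_grid = config$s_grid,
                                 n_grid = config$n_grid, alpha = config$alpha)
  write_tsv(selection$grid, file.path(out, "threshold_grid.tsv")); put("threshold_grid.tsv")

  filtered <- filter_mappings(mappings, s_min = config$s_min,
                              n_min = config$n_min)
  if (nrow(filtered) == 0L) stopf("no mapping survives the reliability filter")

  theta <- NULL; evidence <- NULL
  if (config$with_em) {
    em_pool <- mappings[mappings$s >= config$em_s_min, , drop = FALSE]
    triplets <- build_triplets(corpus, restrict_to = em_pool, dag = dag)
    theta <- run_em(triplets, corpus, emcfg)
    evidence <- compute_e_scores(theta, triplets, corpus, emcfg,
                                 pairs = filtered[, c("domain_id", "go_id")])
    filtered <- augment_mappings(filtered, theta, evidence)
    write_tsv(as.data.frame(filtered), file.path(out, "em.tsv")); put("em.tsv")
    write_tsv(data.frame(iteration = seq_along(theta$trace) - 1L,
                         log_likelihood = theta$trace),
              file.path(out, "em_trace.tsv")); put("em_trace.tsv")
  }
  write_mapping_table(filtered, file.path(out, "filtered.tsv")); put("filtered.tsv")

  targets <- names(corpus$protein_domains)
  pred_sets <- list(S = predict_functions(filtered, corpus$protein_domains,
                                          dag = dag, score_mode = "S"))
  if (config$with_em)
    pred_sets$E <- predict_functions(filtered, corpus$protein_domains,
                                     dag = dag, score_mode = "E",
                                     floor = config$prediction_floor)
  pred_sets$naive <- naive_baseline(corpus$protein_go, targets)
  pred_sets$hybrid <- merge_hybrid(list(pred_sets$S, pred_sets$naive))
  for (mode in names(pred_sets)) {
    fn <- sprintf("predictions_%s.tsv", mode)
    write_predictions(pred_sets[[mode]], file.path(out, fn)); put(fn)
  }

  evaluation <- NULL
  if (!is.null(bundle$benchmark)) {
    ic <- compute_information_content(dag, corpus$protein_go)
    evaluation <- lapply(pred_sets, function(ps) {
      lapply(c(full = "full", partial = "partial"), function(m) {
        r <- evaluate_predictions(ps, bundle$benchmark, dag = dag, ic = ic,
                                  mode = m)
        r$pr_curve <- NULL
        unclass(r)
      })
    })
    jsonlite::write_json(evaluation, file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put("evaluation.json")
  }

  manifest <- list(
    config = unclass(config),
    config_digest = object_digest(unclass(config)),
    threshold_selection = if (selection$no_separation) "none"
                          else selection$selected,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, artifacts))), artifacts))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
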