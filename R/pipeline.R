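#' Platform presets
#'
#' QC threshold and connection radius per imaging platform, in the
#' platform's native coordinate units: CosMx SMI `d = 12` pixels (about
#' 2.16 um at 0.18 um/pixel) with `alpha = 50`; MERFISH `d = 2` um with
#' `alpha = 100`; Xenium `d = 3` um with `alpha = 50`.
#'
#' @param platform `"cosmx"`, `"merfish"` or `"xenium"`.
#' @return List with `d`, `alpha`, `unit_scale` (micrometers per unit).
#' @export
platform_preset <- function(platform = c("cosmx", "merfish", "xenium")) {
  platform <- match.arg(platform)
  switch(platform,
         cosmx   = list(d = 12, alpha = 50L, unit_scale = 0.18),
         merfish = list(d = 2,  alpha = 100L, unit_scale = 1),
         xenium  = list(d = 3,  alpha = 50L, unit_scale = 1))
}

#' Pipeline configuration
#'
#' Bundles QC, graph, encoder, training and augmentation settings, with a
#' platform preset filling `d` and `alpha` and every field overridable.
#' One root seed propagates to graph partitioning and training.
#'
#' @param platform Optional platform preset name (see [platform_preset()]).
#' @param qc A [qc_config()]; default derived from the platform.
#' @param graph A [graph_config()]; default derived from the platform.
#' @param encoder An [encoder_config()].
#' @param train A [train_config()].
#' @param policy Augmentation policy (see [augment_policy()]).
#' @param gumbel_temperature Gumbel-Softmax temperature.
#' @param seed Root seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(platform = NULL, qc = NULL, graph = NULL,
                            encoder = encoder_config(),
                            train = train_config(), policy = "all",
                            gumbel_temperature = 1, seed = 0L) {
  preset <- if (is.null(platform)) NULL else platform_preset(platform)
  if (is.null(qc)) qc <- qc_config(alpha = if (is.null(preset)) 50L else preset$alpha)
  if (is.null(graph)) {
    graph <- graph_config(d = if (is.null(preset)) 2 else preset$d, seed = seed)
  }
  train$seed <- as.integer(seed)
  structure(list(platform = platform, qc = qc, graph = graph,
                 encoder = encoder, train = train, policy = policy,
                 gumbel_temperature = gumbel_temperature,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' `read_config(write_config(cfg, path))` reproduces an equal object.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()`: `path`, invisibly; `read_config()`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  ser <- list(platform = config$platform,
              qc = unclass(config$qc),
              graph = unclass(config$graph),
              encoder = unclass(config$encoder),
              train = unclass(config$train),
              policy = config$policy,
              gumbel_temperature = config$gumbel_temperature,
              seed = config$seed)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    platform = y$platform,
    qc = do.call(qc_config, y$qc),
    graph = do.call(graph_config, y$graph),
    encoder = do.call(encoder_config, y$encoder),
    train = do.call(train_config, y$train),
    policy = unlist(y$policy),
    gumbel_temperature = y$gumbel_temperature,
    seed = y$seed)
}

#' Run the full annotation pipeline
#'
#' Orchestrates QC, vocabulary construction (over reference and query
#' jointly), graph building with Louvain partitioning, semi-supervised
#' training, query annotation and, when query truth is supplied,
#' evaluation. Every stage reports its input/output counts; a manifest
#' with the seed, configuration and stage counts is attached to the result
#' (and written to `out_dir` with the predictions, loss history, gene
#' importance tables and GSEA-preranked exports when `out_dir` is given).
#'
#' @param config A [pipeline_config()].
#' @param reference Reference transcript `data.frame`.
#' @param labels Reference label `data.frame` (`cell_id`, `cell_type`).
#' @param query Query transcript `data.frame`.
#' @param query_labels Optional query truth for evaluation.
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Stage-by-stage logging.
#' @return List: `predictions` (annotation result), `model`, `metrics`
#'   (NULL without truth), `importance`, `manifest`.
#' @export
run_pipeline <- function(config, reference, labels, query,
                         query_labels = NULL, out_dir = NULL,
                         verbose = TRUE) {
  stage <- function(...) if (verbose) message("[pipeline] ", sprintf(...))
  ref_qc <- apply_qc(reference, config$qc, verbose = verbose)
  qry_qc <- apply_qc(query, config$qc, verbose = verbose)
  vocab <- build_vocabulary(rbind(ref_qc[, c("cell_id", "gene", "x", "y")],
                                  qry_qc[, c("cell_id", "gene", "x", "y")]))
  stage("vocabulary: %d gene symbols", vocab$d)
  ref_graphs <- build_cell_graphs(ref_qc, config$graph, vocab,
                                  labels = labels, verbose = verbose)
  qry_graphs <- build_cell_graphs(qry_qc, config$graph, vocab,
                                  verbose = verbose)
  stage("training on %d reference + %d query cells",
        length(ref_graphs), length(qry_graphs))
  model <- fit_gcl(ref_graphs, qry_graphs, vocab,
                   encoder = config$encoder, train = config$train,
                   policy = config$policy,
                   gumbel_temperature = config$gumbel_temperature,
                   verbose = verbose)
  predictions <- annotate_cells(model, qry_graphs)
  metrics <- NULL
  if (!is.null(query_labels)) {
    truth <- stats::setNames(query_labels$cell_type, query_labels$cell_id)
    metrics <- evaluate_annotation(truth[predictions$cell_id],
                                   predictions$predicted_type)
    stage("query accuracy %.3f, macro-F1 %.3f", metrics$accuracy,
          metrics$f1_macro)
  }
  importance <- gene_importance(model, qry_graphs, predictions$predicted_type)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("spatialGCL")),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))),
    qc_log_reference = attr(ref_qc, "qc_log"),
    qc_log_query = attr(qry_qc, "qc_log"),
    n_reference_graphs = length(ref_graphs),
    n_query_graphs = length(qry_graphs),
    classes = model$classes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(model$loss_history, file.path(out_dir, "loss_history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(importance, file.path(out_dir, "gene_importance.csv"),
                     row.names = FALSE, quote = FALSE)
    for (ct in model$classes) {
      if (ct %in% importance$cell_type) {
        write_rnk(importance, ct,
                  file.path(out_dir, paste0("importance_", gsub("\\W+", "_", ct), ".rnk")))
      }
    }
    save_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(metrics)) {
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  list(predictions = predictions, model = model, metrics = metrics,
       importance = importance, manifest = manifest)
}
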