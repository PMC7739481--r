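#' Run the full disease-prioritization pipeline from input files
#'
#' Executes similarity -> graph assembly -> GCN encoding -> boosting ->
#' evaluation, writing every intermediate artifact to `config$output_dir`.
#' The run can be stopped early with `stage`.
#'
#' Configuration fields (defaults in parentheses): `gene_network`,
#' `disease_genes`, `disease_proteins`, `labels` — input file paths;
#' `similarity_mode` ("corrected"); `edge_threshold` (0); `min_diseases` (1);
#' `gcn` — list(hidden_dim = 16, epochs = 200, learning_rate = 0.05,
#' self_loops = TRUE); `boost` — list of [boost_config()] arguments;
#' `evaluation` — list(encoder = "gcn"); `seed` (1); `output_dir`.
#'
#' @param config named list (see Details), e.g. from
#'   [read_pipeline_config()].
#' @param stage run up to this stage: `"similarity"`, `"graph"`, `"gcn"`,
#'   `"boost"` or `"evaluate"` (default: all).
#' @param quiet suppress progress messages.
#' @return for a full run, the [run_loocv()] `eval_report` (invisibly the
#'   written artifacts are in `config$output_dir`); for earlier stages, the
#'   last computed object.
#' @export
run_pipeline <- function(config, stage = c("evaluate", "similarity", "graph",
                                           "gcn", "boost"),
                         quiet = FALSE) {
  stage <- match.arg(stage)
  req <- c("gene_network", "disease_genes", "disease_proteins", "labels",
           "output_dir")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f))
    stop("pipeline config is missing: ", paste(missing_f, collapse = ", "))
  for (f in req[1:4])
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message("[ptsarank] ", sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("similarity: reading inputs and computing the disease similarity matrix")
  sim <- run_stage("similarity", {
    network <- read_edge_list(config$gene_network)
    gmap <- read_disease_gene_map(config$disease_genes)
    similarity_matrix(gmap, network,
                      mode = config$similarity_mode %||% "corrected")
  })
  write_matrix_tsv(sim, file.path(out_dir, "similarity.tsv"), "disease")
  if (stage == "similarity") return(invisible(sim))

  say("graph: protein features, frequency filter, graph assembly")
  graph <- run_stage("graph", {
    pmap <- read_disease_protein_map(config$disease_proteins,
                                     diseases = rownames(sim))
    sel <- select_frequent_proteins(pmap,
                                    as.integer(config$min_diseases %||% 1L))
    X <- encode_protein_features(pmap, sel)
    labels <- read_labels(config$labels, rownames(sim))
    build_disease_graph(sim, X, labels,
                        edge_threshold = config$edge_threshold %||% 0)
  })
  write_matrix_tsv(graph$adjacency, file.path(out_dir, "adjacency.tsv"),
                   "disease")
  write_feature_triplets(graph$features,
                         file.path(out_dir, "features.tsv"))
  utils::write.table(
    data.frame(disease = graph$node_ids, label = graph$labels),
    file.path(out_dir, "nodes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (stage == "graph") return(invisible(graph))

  gcn_args <- config$gcn %||% list()
  say("gcn: training the graph convolutional encoder")
  model <- run_stage("gcn", {
    gcn_args$graph <- graph
    if (is.null(gcn_args$seed)) gcn_args$seed <- seed
    do.call(gcn_fit, gcn_args)
  })
  emb <- embed_nodes(graph, model)
  write_matrix_tsv(emb, file.path(out_dir, "embeddings.tsv"), "disease")
  write_gcn_model(model, file.path(out_dir, "gcn_model.json"))
  if (stage == "gcn") return(invisible(model))

  boost_cfg <- do.call(boost_config, as.list(config$boost %||% list()))
  say("boost: fitting the gradient-boosted classifier")
  fit <- run_stage("boost", {
    gcn_args$graph <- NULL
    gcn_boost(graph, encoder = config$evaluation$encoder %||% "gcn",
              gcn = gcn_args, boost = boost_cfg, seed = seed)
  })
  write_boosted_model(fit$boosted_model,
                      file.path(out_dir, "boosted_model.json"))
  sc <- predict(fit, graph)
  utils::write.table(
    data.frame(disease = names(sc), score = unname(sc)),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (stage == "boost") return(invisible(fit))

  say("evaluate: leave-one-positive-out cross-validation")
  report <- run_stage("evaluate", {
    run_loocv(graph, encoder = config$evaluation$encoder %||% "gcn",
              gcn = gcn_args, boost = boost_cfg, seed = seed)
  })
  utils::write.table(
    data.frame(disease = names(report$scores),
               score = unname(report$scores),
               label = graph$labels[names(report$scores)]),
    file.path(out_dir, "heldout_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(roc_auc = report$roc_auc, pr_auc = report$pr_auc,
         encoder = report$encoder, seed = report$seed,
         n_folds = report$folds$n_folds,
         config = config[setdiff(names(config), "output_dir")]),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
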