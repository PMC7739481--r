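#' Fit the GCN-encoded gradient-boosting classifier on a disease graph
#'
#' The package's headline model.  A two-layer graph convolutional network is
#' trained on the labeled nodes of the disease graph (semi-supervised,
#' transductive), its hidden-layer activations become the node
#' representation, and a from-scratch second-order gradient-boosted tree
#' ensemble is fitted on the labeled nodes' representations.  The `"raw"`
#' encoder skips the GCN and boosts directly on the binary protein features;
#' `"concat"` uses both side by side, so each disease carries its protein
#' profile and its similarity-graph context.
#'
#' @param graph a [build_disease_graph()] object; nodes with NA labels are
#'   excluded from all training losses but still receive representations.
#' @param encoder `"gcn"`, `"raw"` or `"concat"`.
#' @param gcn list of arguments forwarded to [gcn_fit()] (hidden_dim, epochs,
#'   learning_rate, self_loops).
#' @param boost a [boost_config()].
#' @param seed integer seed for GCN weight initialization.
#' @return object of class `gcn_boost` with components `gcn_model` (NULL for
#'   the raw encoder), `boosted_model`, `encoder`, `representation` (the
#'   full node-by-feature matrix actually boosted on) and `graph_nodes`.
#' @seealso [run_loocv()], [rank_candidates()]
#' @export
gcn_boost <- function(graph, encoder = c("gcn", "raw", "concat"),
                      gcn = list(), boost = boost_config(), seed = 1L) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(graph, "disease_graph"))
  gm <- NULL
  if (encoder %in% c("gcn", "concat")) {
    gcn$graph <- graph
    if (is.null(gcn$seed)) gcn$seed <- seed
    gm <- do.call(gcn_fit, gcn)
    emb <- embed_nodes(graph, gm)
    rep_mat <- if (encoder == "concat") cbind(graph$features, emb) else emb
  } else {
    rep_mat <- graph$features
  }
  lab <- !is.na(graph$labels)
  bm <- xgb_fit(rep_mat[lab, , drop = FALSE], graph$labels[lab], boost)
  structure(list(gcn_model = gm, boosted_model = bm, encoder = encoder,
                 representation = rep_mat, graph_nodes = graph$node_ids,
                 seed = as.integer(seed)),
            class = "gcn_boost")
}

representation_for <- function(object, graph) {
  switch(object$encoder,
         raw = graph$features,
         gcn = embed_nodes(graph, object$gcn_model),
         concat = cbind(graph$features, embed_nodes(graph, object$gcn_model)))
}

#' @export
#' @rdname gcn_boost
#' @param object,x a fitted `gcn_boost` model.
#' @param newdata a `disease_graph` to score (defaults to the training
#'   graph's stored representation).
#' @param ... unused.
predict.gcn_boost <- function(object, newdata = NULL, ...) {
  rep_mat <- if (is.null(newdata)) object$representation
             else representation_for(object, newdata)
  stats::setNames(predict_proba(object$boosted_model, rep_mat),
                  rownames(rep_mat))
}

#' @export
#' @rdname gcn_boost
print.gcn_boost <- function(x, ...) {
  cat(sprintf("GCN-boosted disease classifier (%s encoder, %d nodes)\n",
              x$encoder, length(x$graph_nodes)))
  if (!is.null(x$gcn_model))
    cat(sprintf("  GCN: %d-dim embedding, %d epochs, final loss %.4f\n",
                x$gcn_model$hidden_dim, x$gcn_model$epochs,
                utils::tail(x$gcn_model$loss_trace, 1)))
  cat(sprintf("  boosting: %d trees, depth <= %d, final train loss %.4f\n",
              length(x$boosted_model$trees), x$boosted_model$config$max_depth,
              utils::tail(x$boosted_model$train_loss, 1)))
  invisible(x)
}

#' @export
#' @rdname gcn_boost
summary.gcn_boost <- function(object, ...) {
  p <- predict(object)
  cat("Fitted scores over all nodes:\n")
  print(summary(p))
  invisible(p)
}
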