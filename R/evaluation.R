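#' Leave-one-positive-out fold plan
#'
#' One fold per known positive disease.  The unknown (label 0) diseases are
#' shuffled by `seed` and partitioned into as many near-equal groups as there
#' are positives (sizes differing by at most one); fold t's test set is
#' positive t plus group t, and every disease appears in exactly one test
#' fold.
#'
#' @param labels named 0/1 vector over all diseases.
#' @param seed integer shuffle seed.
#' @return object of class `fold_plan`: list with `n_folds`, `test_positive`
#'   (character vector), `test_unknowns` (list of character vectors), `seed`.
#' @export
make_loocv_folds <- function(labels, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)), !is.null(names(labels)))
  pos <- names(labels)[labels == 1]
  unk <- names(labels)[labels == 0]
  if (length(pos) < 2) stop("need at least 2 positive diseases")
  set.seed(seed)
  unk <- sample(unk)
  groups <- split(unk, rep_len(seq_along(pos), length(unk)))
  structure(list(n_folds = length(pos), test_positive = pos,
                 test_unknowns = unname(groups[as.character(seq_along(pos))]),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' ROC-AUC by the rank (Wilcoxon) formula
#'
#' Probability that a uniformly random positive outranks a uniformly random
#' negative, with ties counted one half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes are required to compute ROC-AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-curve / average-precision convention: sum over positives, in
#' descending score order, of precision at each positive's position; no
#' linear interpolation.  Ties in score are broken by placing positives last
#' within a tie group (pessimistic, deterministic).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector; at least one positive required.
#' @return AUPR in \(0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (sum(labels == 1) == 0) stop("at least one positive is required")
  o <- order(-scores, labels)          # ties: negatives first
  y <- labels[o]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Run the leave-one-positive-out evaluation of the full pipeline
#'
#' For each fold the test nodes' labels are masked (set NA), the GCN is
#' trained on the remaining labeled nodes, all nodes are embedded, the
#' boosting classifier is fitted on the training nodes' representations, and
#' the held-out test nodes are scored.  Held-out scores are pooled across
#' folds and both ranking metrics are computed on the pool.
#'
#' @param graph a [build_disease_graph()] object with 0/1 labels.
#' @param encoder `"gcn"` (hidden embeddings), `"raw"` (protein features
#'   straight to boosting) or `"concat"` (features and embeddings side by
#'   side).
#' @param gcn list of arguments forwarded to [gcn_fit()].
#' @param boost a [boost_config()].
#' @param seed integer; drives the fold shuffle and per-fold model seeds.
#' @return object of class `eval_report`: `scores` (named, pooled held-out),
#'   `roc_auc`, `pr_auc`, `folds` (the plan), `encoder`, `seed`, `config`.
#' @export
run_loocv <- function(graph, encoder = c("gcn", "raw", "concat"),
                      gcn = list(), boost = boost_config(), seed = 1L) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(graph, "disease_graph"), all(graph$labels %in% c(0, 1)))
  plan <- make_loocv_folds(graph$labels, seed)
  scores <- stats::setNames(rep(NA_real_, length(graph$node_ids)),
                            graph$node_ids)
  for (t in seq_len(plan$n_folds)) {
    test_ids <- c(plan$test_positive[t], plan$test_unknowns[[t]])
    fold_graph <- graph
    fold_graph$labels[test_ids] <- NA
    fit <- gcn_boost(fold_graph, encoder = encoder, gcn = gcn, boost = boost,
                     seed = seed + t)
    scores[test_ids] <- predict(fit, fold_graph)[test_ids]
  }
  structure(list(scores = scores,
                 roc_auc = roc_auc(scores, graph$labels),
                 pr_auc = pr_auc(scores, graph$labels),
                 folds = plan, encoder = encoder, seed = as.integer(seed),
                 config = list(gcn = gcn, boost = unclass(boost))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Leave-one-positive-out evaluation (%s encoder, %d folds, seed %d)\n",
              x$encoder, x$folds$n_folds, x$seed))
  cat(sprintf("  pooled ROC-AUC %.4f, AUPR %.4f over %d held-out scores\n",
              x$roc_auc, x$pr_auc, length(x$scores)))
  invisible(x)
}

#' Rank unlabeled diseases as PTSA candidates
#'
#' Case-study mode: the model is fitted on all positives plus `n_negatives`
#' randomly sampled unknown diseases treated as negatives; every unlabeled
#' disease is then scored and returned in descending score order with a
#' decision column.
#'
#' @inheritParams run_loocv
#' @param n_negatives number of unknown diseases sampled as negatives.
#' @param threshold scores above this are called positive (default 0.5).
#' @return data.frame with columns `disease`, `score`, `predicted_positive`,
#'   sorted by descending score; the sampled negatives are recorded in
#'   attribute `sampled_negatives`.
#' @export
rank_candidates <- function(graph, encoder = c("gcn", "raw", "concat"),
                            gcn = list(), boost = boost_config(),
                            n_negatives = 100L, threshold = 0.5, seed = 1L) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(graph, "disease_graph"))
  unk <- graph$node_ids[graph$labels == 0 & !is.na(graph$labels)]
  if (length(unk) < n_negatives)
    stop("only ", length(unk), " unknown diseases available, need ",
         n_negatives)
  set.seed(seed)
  neg <- sample(unk, n_negatives)
  train_graph <- graph
  train_graph$labels[] <- NA
  pos <- graph$node_ids[graph$labels == 1 & !is.na(graph$labels)]
  train_graph$labels[pos] <- 1
  train_graph$labels[neg] <- 0
  fit <- gcn_boost(train_graph, encoder = encoder, gcn = gcn, boost = boost,
                   seed = seed)
  sc <- predict(fit, train_graph)[unk]
  out <- data.frame(disease = unk, score = unname(sc),
                    predicted_positive = unname(sc > threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$disease), ]
  rownames(out) <- NULL
  attr(out, "sampled_negatives") <- neg
  out
}
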