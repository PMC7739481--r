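#' Binary disease-by-protein annotation map
#'
#' @param incidence binary integer matrix, rows = diseases, columns =
#'   proteins, with dimnames; strictly 0/1.
#' @return an object of class `disease_protein_map` with fields `incidence`
#'   and `proteins`.
#' @export
disease_protein_map <- function(incidence) {
  stopifnot(is.matrix(incidence), !is.null(rownames(incidence)),
            !is.null(colnames(incidence)),
            all(incidence %in% c(0L, 1L)),
            !anyDuplicated(colnames(incidence)),
            !anyDuplicated(rownames(incidence)))
  storage.mode(incidence) <- "integer"
  structure(list(incidence = incidence, proteins = colnames(incidence)),
            class = "disease_protein_map")
}

#' @export
print.disease_protein_map <- function(x, ...) {
  cat(sprintf("Disease-protein map: %d diseases x %d proteins, %d associations\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' Select proteins associated with at least `min_diseases` diseases
#'
#' The frequency filter that keeps only the most common proteins as features
#' (in the original data, proteins associated with >= 100 diseases).  The
#' returned order is deterministic: descending disease count, then ascending
#' protein identifier.
#'
#' @param dmap a [disease_protein_map()].
#' @param min_diseases minimum number of associated diseases (>= 1).
#' @return character vector of selected protein IDs.
#' @export
select_frequent_proteins <- function(dmap, min_diseases = 100L) {
  stopifnot(inherits(dmap, "disease_protein_map"), min_diseases >= 1)
  counts <- colSums(dmap$incidence)
  keep <- counts >= min_diseases
  if (!any(keep))
    stop("no features survive filter: no protein is associated with >= ",
         min_diseases, " diseases")
  sel <- names(counts)[keep]
  sel[order(-counts[keep], sel)]
}

#' Encode diseases as binary protein-feature vectors
#'
#' One row per disease, one column per selected protein; entry 1 iff the
#' association exists in the map.  Column order follows `selected`.
#'
#' @param dmap a [disease_protein_map()].
#' @param selected character vector of protein IDs, a subset of the map's
#'   protein universe.
#' @return binary integer matrix (diseases x selected proteins).
#' @export
encode_protein_features <- function(dmap, selected) {
  stopifnot(inherits(dmap, "disease_protein_map"))
  unknown <- setdiff(selected, dmap$proteins)
  if (length(unknown))
    stop("unknown selected protein(s): ", paste(unknown, collapse = ", "))
  dmap$incidence[, selected, drop = FALSE]
}

#' Assemble the labeled disease graph
#'
#' Nodes are diseases in sorted disease-ID order; the adjacency is the
#' similarity matrix with entries below `edge_threshold` zeroed and a zero
#' diagonal (self-loops are a property of the GCN propagation operator, not
#' of the stored adjacency).  Node features are the binary protein encoding
#' and labels are 1 (known positive), 0 (unknown) or NA (masked).
#'
#' @param sim_matrix symmetric disease similarity matrix with dimnames.
#' @param features binary feature matrix, rows named by disease.
#' @param labels named vector in \{1, 0, NA\} covering all diseases.
#' @param edge_threshold similarities strictly below this are zeroed
#'   (default 0: dense weighted graph).
#' @return an object of class `disease_graph` with fields `node_ids`,
#'   `adjacency`, `features`, `labels`.
#' @export
build_disease_graph <- function(sim_matrix, features, labels,
                                edge_threshold = 0) {
  stopifnot(is.matrix(sim_matrix), nrow(sim_matrix) == ncol(sim_matrix))
  ids <- sort(rownames(sim_matrix))
  if (!setequal(ids, rownames(features)) || !setequal(ids, names(labels)))
    stop("disease IDs of similarity matrix, features and labels disagree")
  A <- sim_matrix[ids, ids]
  A[A < edge_threshold] <- 0
  diag(A) <- 0
  X <- features[ids, , drop = FALSE]
  y <- labels[ids]
  structure(list(node_ids = ids, adjacency = A,
                 features = X, labels = y),
            class = "disease_graph")
}

#' @export
print.disease_graph <- function(x, ...) {
  n_lab <- sum(!is.na(x$labels))
  cat(sprintf("Disease graph: %d nodes, %d weighted edges, %d features/node\n",
              length(x$node_ids), sum(x$adjacency[upper.tri(x$adjacency)] > 0),
              ncol(x$features)))
  cat(sprintf("  labels: %d positive, %d unknown, %d masked\n",
              sum(x$labels == 1, na.rm = TRUE),
              sum(x$labels == 0, na.rm = TRUE), sum(is.na(x$labels))))
  invisible(x)
}

#' Build the disease graph directly from a scenario
#'
#' Convenience wrapper running similarity -> feature selection -> encoding ->
#' graph assembly with the module defaults.
#'
#' The default `edge_threshold = NULL` keeps only the top third of
#' off-diagonal similarities (threshold at their 2/3 quantile).  Real
#' gene-derived disease similarity matrices are effectively sparse -- the
#' bulk of pairs have near-zero similarity -- and a dense synthetic matrix
#' over-smooths the GCN propagation operator: with near-uniform positive
#' weights the kernel averages almost globally and node representations
#' collapse.  The quantile rule reproduces realistic sparsity at any
#' scenario scale; pass an explicit numeric threshold (0 for dense) to
#' override.
#'
#' @param scenario a `ptsa_scenario` from [simulate_scenario()].
#' @param min_diseases protein frequency filter threshold; proteins associated
#'   with fewer diseases are dropped (default 1 keeps the full universe,
#'   appropriate at synthetic scale).
#' @param edge_threshold numeric threshold for [build_disease_graph()], or
#'   NULL for the 2/3-quantile rule (see Details).
#' @param mode LLS normalization mode.
#' @return a `disease_graph`.
#' @export
scenario_graph <- function(scenario, min_diseases = 1L, edge_threshold = NULL,
                           mode = "corrected") {
  sim <- similarity_matrix(scenario$gene_map, scenario$network, mode)
  if (is.null(edge_threshold))
    edge_threshold <- stats::quantile(sim[upper.tri(sim)], 2 / 3, names = FALSE)
  sel <- select_frequent_proteins(scenario$protein_map, min_diseases)
  X <- encode_protein_features(scenario$protein_map, sel)
  build_disease_graph(sim, X, scenario$labels, edge_threshold)
}
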