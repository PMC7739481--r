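# Shared fixtures and independent oracles, all generated in code.

# Tiny hand-auditable network: LLS range pinned to [0, 10] by the x-y / x-z
# edges so other weights normalize to weight/10 in corrected mode.
pinned_network <- function(extra = NULL) {
  edges <- data.frame(
    gene1 = c("x", "x"), gene2 = c("y", "z"), lls = c(0, 10),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) edges <- rbind(edges, extra)
  gene_network(edges)
}

small_scenario <- function(seed = 7, signal_strength = 0.9, n_diseases = 30,
                           n_positives = 6, ...) {
  simulate_scenario(sim_config(
    n_genes = 80, n_diseases = n_diseases, n_positives = n_positives,
    n_proteins = 40, edge_density = 0.08, positive_gene_pool = 12,
    genes_per_disease = c(4, 8), signal_strength = signal_strength,
    seed = seed, ...
  ))
}

# Naive double-loop disease-pair similarity: enumerates every F term.
bma_oracle <- function(G1, G2, network, mode = "corrected") {
  f <- function(g, G) max(vapply(G, function(gj)
    gene_pair_similarity(g, gj, network, mode), numeric(1)))
  (sum(vapply(G1, f, numeric(1), G = G2)) +
     sum(vapply(G2, f, numeric(1), G = G1))) / (length(G1) + length(G2))
}

# Brute-force best split: enumerate every feature and every midpoint.
best_split_oracle <- function(x, g, h, lambda, gamma, min_child_hessian = 0) {
  best <- -Inf
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (thr in (v[-1] + v[-length(v)]) / 2) {
      left <- x[, j] <= thr
      HL <- sum(h[left]); HR <- sum(h[!left])
      if (HL < min_child_hessian || HR < min_child_hessian) next
      gain <- split_gain(sum(g[left]), HL, sum(g[!left]), HR, lambda, gamma)
      if (gain > best) best <- gain
    }
  }
  best
}

root_gain <- function(tree) tree$gain

# O(n^2) pairwise ROC-AUC oracle with half-credit ties.
roc_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Direct average-precision summation oracle (ties: negatives ranked first).
pr_auc_oracle <- function(scores, labels) {
  o <- order(-scores, labels)
  y <- labels[o]
  hits <- 0; ap <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      hits <- hits + 1
      ap <- ap + hits / i
    }
  }
  ap / sum(y)
}

table3_counts <- function() {
  matrix(c(9, 54, 28, 8,
           172, 130, 152, 177,
           11, 8, 12, 7),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("low", "moderate", "high"),
                         paste0("stage", 1:4)))
}
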