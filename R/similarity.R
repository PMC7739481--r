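#' Weighted gene functional network
#'
#' Container for an undirected simple gene graph whose edges carry raw
#' log-likelihood scores (LLS).  The global LLS minimum and maximum are cached
#' at construction and used by [normalize_lls()] for every query.  Edge lookup
#' is symmetric: querying (a, b) and (b, a) returns the same weight.
#'
#' @param edges data.frame with columns `gene1`, `gene2`, `lls`; self-edges
#'   are rejected, duplicated pairs must agree on the weight.
#' @param gene_ids optional character vector of the gene universe; defaults to
#'   the genes appearing in `edges`.
#' @return an object of class `gene_network` with fields `gene_ids`, `edges`,
#'   `lls_min`, `lls_max` and an internal hashed edge index.
#' @export
gene_network <- function(edges, gene_ids = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("gene1", "gene2", "lls") %in% names(edges)))
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  edges$lls <- as.numeric(edges$lls)
  if (any(edges$gene1 == edges$gene2)) stop("self-edges are not allowed")
  key <- edge_key(edges$gene1, edges$gene2)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    agg <- tapply(edges$lls[dup], key[dup], function(w) length(unique(w)))
    if (any(agg > 1)) stop("duplicate edges with conflicting weights")
    keep <- !duplicated(key)
    edges <- edges[keep, ]; key <- key[keep]
  }
  if (is.null(gene_ids))
    gene_ids <- sort(unique(c(edges$gene1, edges$gene2)))
  else
    stopifnot(all(c(edges$gene1, edges$gene2) %in% gene_ids))
  lookup <- stats::setNames(edges$lls, key)
  structure(list(gene_ids = gene_ids, edges = edges,
                 lls_min = if (nrow(edges)) min(edges$lls) else NA_real_,
                 lls_max = if (nrow(edges)) max(edges$lls) else NA_real_,
                 lookup = lookup),
            class = "gene_network")
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene functional network: %d genes, %d edges, LLS in [%g, %g]\n",
              length(x$gene_ids), nrow(x$edges), x$lls_min, x$lls_max))
  invisible(x)
}

#' Normalize a log-likelihood score
#'
#' The default `"corrected"` mode is the standard min-max normalization
#' `(lls - lls_min) / (lls_max - lls_min)`, mapping the network's global LLS
#' range onto \[0, 1\].  `"as_printed"` evaluates the alternative form
#' `(lls - lls_min) / (lls_max - lls)`, which is non-monotone in `lls` and
#' singular at `lls = lls_max`; it is retained only for fidelity audits and
#' raises an explicit error at the singular point.
#'
#' @param lls numeric vector of raw scores within `[lls_min, lls_max]`.
#' @param lls_min,lls_max global network extremes, `lls_min < lls_max`.
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return normalized scores; in \[0, 1\] for `"corrected"`.
#' @export
normalize_lls <- function(lls, lls_min, lls_max,
                          mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (lls_min >= lls_max) stop("lls_min must be strictly below lls_max")
  if (any(lls < lls_min | lls > lls_max))
    stop("lls outside the [lls_min, lls_max] range")
  if (mode == "corrected") {
    (lls - lls_min) / (lls_max - lls_min)
  } else {
    if (any(lls == lls_max))
      stop("as-printed normalization is singular at lls = lls_max ",
           "(denominator lls_max - lls vanishes)")
    (lls - lls_min) / (lls_max - lls)
  }
}

#' Functional similarity of two genes
#'
#' 1 if the genes are identical; the normalized LLS of their edge if it is in
#' the network; 0 otherwise.  Genes absent from the network are allowed and
#' fall through to the identity / zero branches.
#'
#' @param g_i,g_j gene identifiers.
#' @param network a [gene_network()].
#' @param mode normalization mode, see [normalize_lls()].
#' @return a single similarity value.
#' @export
gene_pair_similarity <- function(g_i, g_j, network,
                                 mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (g_i == g_j) return(1)
  w <- unname(network$lookup[edge_key(g_i, g_j)])
  if (is.na(w)) return(0)
  normalize_lls(w, network$lls_min, network$lls_max, mode)
}

#' Association between a gene and a gene set
#'
#' Best-match score: the maximum of [gene_pair_similarity()] between `g` and
#' every member of `G`.
#'
#' @param g a gene identifier.
#' @param G non-empty character vector of gene identifiers.
#' @inheritParams gene_pair_similarity
#' @return value in \[0, 1\] (corrected mode).
#' @export
gene_to_set_association <- function(g, G, network,
                                    mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (length(G) == 0) stop("gene set is empty")
  max(vapply(G, function(gj) gene_pair_similarity(g, gj, network, mode),
             numeric(1)))
}

#' Best-match-average similarity of two diseases
#'
#' Treats the diseases as gene sets G1 and G2 and returns
#' `(sum_{g in G1} F(G2, g) + sum_{g in G2} F(G1, g)) / (|G1| + |G2|)`
#' where `F` is [gene_to_set_association()].  Symmetric, equal to 1 for
#' identical sets, and 0 for disjoint sets with no cross edges.
#'
#' @param G1,G2 non-empty character vectors of gene identifiers.
#' @inheritParams gene_pair_similarity
#' @return similarity in \[0, 1\] (corrected mode).
#' @export
disease_pair_similarity <- function(G1, G2, network,
                                    mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (length(G1) == 0 || length(G2) == 0) stop("disease gene set is empty")
  s1 <- sum(vapply(G1, gene_to_set_association, numeric(1),
                   G = G2, network = network, mode = mode))
  s2 <- sum(vapply(G2, gene_to_set_association, numeric(1),
                   G = G1, network = network, mode = mode))
  (s1 + s2) / (length(G1) + length(G2))
}

# Dense gene-gene similarity over a restricted universe, used by the
# vectorized matrix path.  Rows/cols named by `genes`.
gene_sim_submatrix <- function(genes, network, mode) {
  n <- length(genes)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  diag(S) <- 1
  e <- network$edges
  keep <- e$gene1 %in% genes & e$gene2 %in% genes
  if (any(keep)) {
    e <- e[keep, ]
    w <- normalize_lls(e$lls, network$lls_min, network$lls_max, mode)
    i <- match(e$gene1, genes); j <- match(e$gene2, genes)
    S[cbind(i, j)] <- w
    S[cbind(j, i)] <- w
  }
  S
}

#' Disease similarity matrix
#'
#' Computes all pairwise [disease_pair_similarity()] values over a disease
#' gene map through a vectorized path (one dense gene-similarity lookup over
#' the genes in use, then row/column maxima per disease pair).
#'
#' @param dmap a `disease_gene_map`: named list of non-empty gene-ID vectors.
#' @inheritParams gene_pair_similarity
#' @return symmetric numeric matrix with unit diagonal, dimnames = disease IDs.
#' @export
similarity_matrix <- function(dmap, network,
                              mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(length(dmap) >= 1)
  if (any(lengths(dmap) == 0)) stop("every disease needs a non-empty gene set")
  d_ids <- names(dmap)
  genes <- sort(unique(unlist(dmap, use.names = FALSE)))
  S <- gene_sim_submatrix(genes, network, mode)
  idx <- lapply(dmap, match, table = genes)
  n <- length(dmap)
  M <- diag(1, n)
  dimnames(M) <- list(d_ids, d_ids)
  if (n == 1) return(M)
  for (a in seq_len(n - 1)) {
    ia <- idx[[a]]
    for (b in (a + 1):n) {
      ib <- idx[[b]]
      sub <- S[ia, ib, drop = FALSE]
      v <- (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
        (length(ia) + length(ib))
      M[a, b] <- v; M[b, a] <- v
    }
  }
  M
}
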