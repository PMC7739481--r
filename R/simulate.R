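#' Simulation configuration for a planted PTSA scenario
#'
#' Describes a synthetic study: a weighted gene functional network, per-disease
#' gene sets with elevated gene sharing among planted positive (PTSA-causing)
#' diseases, and a binary disease-by-protein annotation matrix in which a
#' fraction of proteins is label-informative.  The generators below consume
#' this object and are fully deterministic given `seed`.
#'
#' `signal_strength` scales both class-signal channels: the fraction of a
#' positive disease's gene set drawn from the shared `positive_gene_pool`, and
#' the gap between the presence probability of an informative protein in
#' positive versus negative diseases.  At `signal_strength = 0` positives and
#' negatives are exchangeable.
#'
#' @param n_genes number of genes in the network (>= 2).
#' @param n_diseases number of diseases.
#' @param n_positives number of planted positive diseases (<= `n_diseases`).
#' @param n_proteins number of proteins in the annotation universe.
#' @param edge_density fraction in (0, 1] of all gene pairs that get an edge.
#' @param lls_range length-2 numeric, min < max; edge log-likelihood scores
#'   are drawn uniformly in this interval.
#' @param positive_gene_pool size of the shared gene pool that positive
#'   diseases preferentially draw from (<= `n_genes`).
#' @param signal_strength fraction in \[0, 1\]; see Details.
#' @param genes_per_disease length-2 integer (low, high); each disease's gene
#'   set size is drawn uniformly in this range.
#' @param informative_fraction fraction of proteins whose presence probability
#'   depends on the disease label.
#' @param p_pos,p_neg presence probability of an informative protein in a
#'   positive / negative disease at full signal; the realized positive-class
#'   probability is `p_neg + signal_strength * (p_pos - p_neg)`.
#' @param seed integer master seed; per-generator substreams are derived from
#'   it so adding a generator never perturbs earlier outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400L, n_diseases = 100L, n_positives = 10L,
                       n_proteins = 200L, edge_density = 0.05,
                       lls_range = c(1, 6), positive_gene_pool = 30L,
                       signal_strength = 0.9,
                       genes_per_disease = c(8L, 15L),
                       informative_fraction = 0.15,
                       p_pos = 0.6, p_neg = 0.2, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
    n_positives = as.integer(n_positives), n_proteins = as.integer(n_proteins),
    edge_density = edge_density, lls_range = as.numeric(lls_range),
    positive_gene_pool = as.integer(positive_gene_pool),
    signal_strength = signal_strength,
    genes_per_disease = as.integer(genes_per_disease),
    informative_fraction = informative_fraction,
    p_pos = p_pos, p_neg = p_neg, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_genes >= 2, n_diseases >= 1, n_proteins >= 1,
      n_positives >= 0, n_positives <= n_diseases,
      positive_gene_pool >= 1, positive_gene_pool <= n_genes,
      edge_density > 0, edge_density <= 1,
      length(lls_range) == 2, lls_range[1] < lls_range[2],
      signal_strength >= 0, signal_strength <= 1,
      length(genes_per_disease) == 2,
      genes_per_disease[1] >= 1,
      genes_per_disease[1] <= genes_per_disease[2],
      informative_fraction >= 0, informative_fraction <= 1,
      p_pos >= 0, p_pos <= 1, p_neg >= 0, p_neg <= 1
    )
  })
  if (cfg$genes_per_disease[2] > cfg$n_genes)
    stop("genes_per_disease upper bound exceeds n_genes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Planted PTSA scenario configuration\n")
  cat(sprintf("  genes: %d (edge density %.3f, LLS in [%g, %g])\n",
              x$n_genes, x$edge_density, x$lls_range[1], x$lls_range[2]))
  cat(sprintf("  diseases: %d (%d positive), proteins: %d\n",
              x$n_diseases, x$n_positives, x$n_proteins))
  cat(sprintf("  signal strength: %.2f, seed: %d\n",
              x$signal_strength, x$seed))
  invisible(x)
}

# Per-generator substreams from one master seed.  Drawing a fixed block of
# sub-seeds up front means adding a later generator never shifts earlier ones.
substream_seeds <- function(seed, n = 8L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

disease_ids <- function(n) sprintf("D%04d", seq_len(n))
gene_ids_for <- function(n) sprintf("g%04d", seq_len(n))
protein_ids_for <- function(n) sprintf("P%04d", seq_len(n))

#' Simulate a weighted gene functional network
#'
#' Draws an undirected simple graph on `config$n_genes` genes with
#' `round(edge_density * n_genes * (n_genes - 1) / 2)` edges chosen uniformly
#' among all pairs, each carrying a log-likelihood score (LLS) drawn uniformly
#' within `config$lls_range`.
#'
#' @param config a [sim_config()].
#' @return a [gene_network()] object.
#' @export
simulate_gene_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 2) stop("need at least 2 genes")
  seed <- substream_seeds(config$seed)[1]
  set.seed(seed)
  n <- config$n_genes
  ids <- gene_ids_for(n)
  n_pairs <- n * (n - 1) / 2
  n_edges <- max(1L, round(config$edge_density * n_pairs))
  pick <- sort(sample.int(n_pairs, n_edges))
  idx <- pair_index_decode(pick, n)
  lls <- stats::runif(n_edges, config$lls_range[1], config$lls_range[2])
  gene_network(
    edges = data.frame(gene1 = ids[idx$i], gene2 = ids[idx$j], lls = lls,
                       stringsAsFactors = FALSE),
    gene_ids = ids
  )
}

# Decode 1-based linear indices over lexicographic (i < j) pairs of 1..n.
pair_index_decode <- function(k, n) {
  # number of pairs with first element <= i is C(n,2) - C(n-i,2)
  i <- findInterval(k - 1L, cumsum((n - 1L):1L), left.open = FALSE) + 1L
  prior <- c(0, cumsum((n - 1L):1L))[i]
  j <- i + (k - prior)
  list(i = i, j = j)
}

#' Simulate disease gene sets with planted positive-class overlap
#'
#' Each disease receives a gene set whose size is uniform within
#' `config$genes_per_disease`.  Positive diseases draw a `signal_strength`
#' fraction of their set from the shared positive gene pool (the first
#' `positive_gene_pool` genes); the remainder, and all genes of negative
#' diseases, are drawn uniformly from the whole gene universe.
#'
#' @param config a [sim_config()].
#' @param network the [gene_network()] from [simulate_gene_network()]
#'   (supplies the gene universe).
#' @return a named list of class `disease_gene_map` mapping disease IDs to
#'   character vectors of gene IDs, with attribute `positives` naming the
#'   planted positive diseases.
#' @export
simulate_disease_gene_map <- function(config, network) {
  stopifnot(inherits(config, "sim_config"), inherits(network, "gene_network"))
  if (config$genes_per_disease[2] > length(network$gene_ids))
    stop("genes_per_disease upper bound exceeds number of network genes")
  seed <- substream_seeds(config$seed)[2]
  set.seed(seed)
  genes <- network$gene_ids
  pool <- genes[seq_len(config$positive_gene_pool)]
  d_ids <- disease_ids(config$n_diseases)
  positives <- d_ids[seq_len(config$n_positives)]
  lo <- config$genes_per_disease[1]; hi <- config$genes_per_disease[2]
  out <- vector("list", config$n_diseases)
  names(out) <- d_ids
  for (d in seq_len(config$n_diseases)) {
    k <- if (lo == hi) lo else sample(lo:hi, 1L)
    if (d <= config$n_positives) {
      k_pool <- min(round(config$signal_strength * k), length(pool))
      from_pool <- if (k_pool > 0) sample(pool, k_pool) else character()
      rest <- setdiff(genes, from_pool)
      from_rest <- if (k - k_pool > 0) sample(rest, k - k_pool) else character()
      out[[d]] <- c(from_pool, from_rest)
    } else {
      out[[d]] <- sample(genes, k)
    }
  }
  structure(out, class = "disease_gene_map", positives = positives)
}

#' Simulate a binary disease-by-protein annotation map
#'
#' Every protein is present in a disease independently with probability
#' `p_neg`, except that the first `round(informative_fraction * n_proteins)`
#' proteins are label-informative: in positive diseases their presence
#' probability is raised to `p_neg + signal_strength * (p_pos - p_neg)`.
#' At `signal_strength = 0` label-conditional frequencies are equal in
#' expectation.
#'
#' @param config a [sim_config()].
#' @return a [disease_protein_map()] with attribute `informative` naming the
#'   informative proteins.
#' @export
simulate_disease_protein_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- substream_seeds(config$seed)[3]
  set.seed(seed)
  d_ids <- disease_ids(config$n_diseases)
  p_ids <- protein_ids_for(config$n_proteins)
  n_inf <- round(config$informative_fraction * config$n_proteins)
  p_eff <- config$p_neg + config$signal_strength * (config$p_pos - config$p_neg)
  prob <- matrix(config$p_neg, config$n_diseases, config$n_proteins)
  if (n_inf > 0 && config$n_positives > 0)
    prob[seq_len(config$n_positives), seq_len(n_inf)] <- p_eff
  inc <- matrix(as.integer(stats::runif(length(prob)) < prob),
                config$n_diseases, config$n_proteins,
                dimnames = list(d_ids, p_ids))
  structure(
    disease_protein_map(inc),
    informative = p_ids[seq_len(n_inf)]
  )
}

#' Simulate a full planted scenario
#'
#' Composes the network, gene-map and protein-map generators under one master
#' seed and returns the labels marking the planted positives.
#'
#' @param config a [sim_config()].
#' @return a list of class `ptsa_scenario` with elements `network`,
#'   `gene_map`, `protein_map`, `labels` (named 0/1 integer vector) and
#'   `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  network <- simulate_gene_network(config)
  gene_map <- simulate_disease_gene_map(config, network)
  protein_map <- simulate_disease_protein_map(config)
  d_ids <- disease_ids(config$n_diseases)
  labels <- stats::setNames(integer(config$n_diseases), d_ids)
  labels[attr(gene_map, "positives")] <- 1L
  structure(list(network = network, gene_map = gene_map,
                 protein_map = protein_map, labels = labels, config = config),
            class = "ptsa_scenario")
}

#' @export
print.ptsa_scenario <- function(x, ...) {
  cat(sprintf("Planted PTSA scenario: %d diseases (%d positive), %d genes, %d proteins\n",
              x$config$n_diseases, sum(x$labels == 1L),
              x$config$n_genes, x$config$n_proteins))
  cat(sprintf("  gene network: %d edges; signal strength %.2f; seed %d\n",
              nrow(x$network$edges), x$config$signal_strength, x$config$seed))
  invisible(x)
}

#' Write a scenario to the pipeline's plain-text input formats
#'
#' Emits the four files the pipeline readers consume: `gene_network.tsv`
#' (gene1, gene2, lls), `disease_genes.tsv` (disease, gene),
#' `disease_proteins.tsv` (disease, protein) and `labels.txt` (one positive
#' disease ID per line).
#'
#' @param scenario a `ptsa_scenario`.
#' @param dir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "ptsa_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gene_network.tsv", "disease_genes.tsv",
                            "disease_proteins.tsv", "labels.txt"))
  utils::write.table(scenario$network$edges, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dg <- data.frame(
    disease = rep(names(scenario$gene_map),
                  lengths(scenario$gene_map)),
    gene = unlist(scenario$gene_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(dg, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  inc <- scenario$protein_map$incidence
  idx <- which(inc == 1L, arr.ind = TRUE)
  dp <- data.frame(disease = rownames(inc)[idx[, 1]],
                   protein = colnames(inc)[idx[, 2]],
                   stringsAsFactors = FALSE)
  dp <- dp[order(dp$disease, dp$protein), ]
  utils::write.table(dp, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(names(scenario$labels)[scenario$labels == 1L], paths[4])
  invisible(paths)
}
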