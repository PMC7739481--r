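#' Read a weighted gene-network edge list
#'
#' Three-column TSV (`gene1 TAB gene2 TAB lls`), header optional.  Edges are
#' undirected and deduplicated; duplicate pairs with conflicting weights are
#' an error that reports the offending line numbers.
#'
#' @param path TSV file.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_flex(path, c("gene1", "gene2", "lls"))
  df$lls <- suppressWarnings(as.numeric(df$lls))
  bad <- which(is.na(df$lls) | df$gene1 == "" | df$gene2 == "")
  if (length(bad))
    stop("malformed edge line(s): ", paste(bad + 1L, collapse = ", "))
  key <- edge_key(df$gene1, df$gene2)
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    for (k in dup_keys) {
      lines <- which(key == k)
      if (length(unique(df$lls[lines])) > 1)
        stop("conflicting duplicate edge weights at lines ",
             paste(lines + 1L, collapse = ", "))
    }
  }
  gene_network(df)
}

# Tolerant TSV reader: uses the header if it matches the expected names,
# otherwise treats the first line as data.
read_tsv_flex <- function(path, col_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- identical(tolower(strsplit(first, "\t")[[1]])[1],
                          col_names[1])
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) != length(col_names))
    stop("expected ", length(col_names), " columns in ", path)
  names(df) <- col_names
  for (j in seq_along(col_names))
    if (is.character(df[[j]]) || is.factor(df[[j]]))
      df[[j]] <- as.character(df[[j]])
  df
}

#' Read a disease-gene association table
#'
#' Two-column TSV (`disease TAB gene`).
#'
#' @param path TSV file.
#' @return a `disease_gene_map` (named list of gene-ID vectors).
#' @export
read_disease_gene_map <- function(path) {
  df <- read_tsv_flex(path, c("disease", "gene"))
  out <- split(df$gene, df$disease)
  out <- lapply(out, unique)
  structure(out[order(names(out))], class = "disease_gene_map")
}

#' Read a disease-protein association table
#'
#' Two-column TSV (`disease TAB protein`), densified to a binary incidence
#' matrix.
#'
#' @param path TSV file.
#' @param diseases optional disease universe (rows); defaults to the
#'   diseases present in the file.
#' @return a [disease_protein_map()].
#' @export
read_disease_protein_map <- function(path, diseases = NULL) {
  df <- read_tsv_flex(path, c("disease", "protein"))
  if (is.null(diseases)) diseases <- sort(unique(df$disease))
  proteins <- sort(unique(df$protein))
  inc <- matrix(0L, length(diseases), length(proteins),
                dimnames = list(diseases, proteins))
  inc[cbind(match(df$disease, diseases), match(df$protein, proteins))] <- 1L
  disease_protein_map(inc)
}

#' Read the positive-disease label list
#'
#' One disease ID per line; every other disease in `diseases` is labeled 0.
#'
#' @param path text file of positive disease IDs.
#' @param diseases full disease universe.
#' @return named 0/1 integer vector.
#' @export
read_labels <- function(path, diseases) {
  pos <- readLines(path)
  pos <- pos[nzchar(pos)]
  unknown <- setdiff(pos, diseases)
  if (length(unknown))
    stop("labels reference unknown disease(s): ",
         paste(unknown, collapse = ", "))
  labels <- stats::setNames(integer(length(diseases)), diseases)
  labels[pos] <- 1L
  labels
}

#' Write a matrix as TSV with ID headers
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_name name of the leading ID column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with a leading ID column.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a binary feature matrix as sparse triplets
#'
#' TSV with columns `disease`, `protein`, `value` listing the nonzero
#' entries, preceded by no header magic: fully plain text.
#'
#' @param X binary matrix with dimnames.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_feature_triplets <- function(X, path) {
  idx <- which(X != 0, arr.ind = TRUE)
  df <- data.frame(disease = rownames(X)[idx[, 1]],
                   protein = colnames(X)[idx[, 2]],
                   value = X[idx], stringsAsFactors = FALSE)
  df <- df[order(df$disease, df$protein), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a GCN model to JSON
#'
#' Weight matrices with shapes, activation names, self-loop flag and seed in a
#' self-describing container.
#'
#' @param model a `gcn_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gcn_model <- function(model, path) {
  payload <- list(
    format = "ptsarank-gcn-model",
    hidden_dim = model$hidden_dim,
    self_loops = model$self_loops,
    activation = model$activation,
    seed = model$seed,
    layer_weights = lapply(model$layer_weights, function(W)
      list(shape = dim(W), values = as.vector(W)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json")
}
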