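#' Degree matrix of an adjacency
#'
#' Diagonal matrix of row sums of the (possibly self-looped) adjacency.
#'
#' @param A square non-negative matrix.
#' @return diagonal matrix of the same dimension.
#' @export
degree_matrix <- function(A) {
  check_adjacency(A, symmetric = FALSE)
  diag(rowSums(A), nrow(A))
}

#' Combinatorial graph Laplacian L = D - A
#'
#' @param A square non-negative matrix.
#' @return the Laplacian; its rows sum to zero.
#' @export
laplacian <- function(A) {
  check_adjacency(A, symmetric = FALSE)
  degree_matrix(A) - A
}

check_adjacency <- function(A, symmetric = TRUE) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("adjacency entries must be non-negative")
  if (symmetric && !isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  invisible(A)
}

#' Symmetrically normalized graph operators
#'
#' Returns both the normalized Laplacian
#' `L_sym = I - D^(-1/2) A D^(-1/2)` and the propagation kernel
#' `D^(-1/2) A D^(-1/2)` used by the GCN forward pass.  Degree-0 nodes follow
#' the zero convention: their rows and columns are zero in the kernel and
#' their `L_sym` diagonal entry is 0 (not 1).
#'
#' @param A square symmetric non-negative adjacency.
#' @param self_loops if TRUE, `A + I` is normalized instead of `A`, so each
#'   node's own features participate in propagation.
#' @return list with elements `kernel` and `l_sym`.
#' @export
sym_normalized_operator <- function(A, self_loops = FALSE) {
  check_adjacency(A, symmetric = TRUE)
  if (self_loops) A <- A + diag(1, nrow(A))
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  K <- A * outer(inv_sqrt, inv_sqrt)
  l_sym <- -K
  diag(l_sym) <- ifelse(d > 0, 1, 0) - diag(K)
  # diag of L_sym = 1 - K_ii for connected nodes, 0 for isolated ones
  list(kernel = K, l_sym = l_sym)
}

#' Chebyshev polynomial sequence T_0..T_K at a point
#'
#' Recurrence `T_k(x) = 2 x T_{k-1}(x) - T_{k-2}(x)` with `T_0 = 1`,
#' `T_1 = x`.
#'
#' @param x evaluation point.
#' @param K highest order (>= 0).
#' @return numeric vector of length K + 1.
#' @export
chebyshev_polynomials <- function(x, K) {
  stopifnot(K >= 0)
  out <- numeric(K + 1)
  out[1] <- 1
  if (K >= 1) out[2] <- x
  if (K >= 2) for (k in 3:(K + 1)) out[k] <- 2 * x * out[k - 1] - out[k - 2]
  out
}

#' First-order spectral graph filter
#'
#' The first-order (K = 1, lambda_max = 2) linear approximation of a spectral
#' graph convolution: `theta0 * x - theta1 * D^(-1/2) A D^(-1/2) x`.  The
#' single-parameter collapse `theta1 = -theta0` gives
#' `theta0 * (I + kernel) x`, the renormalized form GCN layers build on.
#'
#' @param x node signal (vector or matrix with one column per signal).
#' @param A adjacency matrix.
#' @param theta0,theta1 filter coefficients.
#' @param self_loops forwarded to [sym_normalized_operator()].
#' @return filtered signal, same shape as `x`.
#' @export
first_order_filter <- function(x, A, theta0, theta1, self_loops = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(A)) stop("signal length does not match node count")
  K <- sym_normalized_operator(A, self_loops)$kernel
  drop(theta0 * x - theta1 * (K %*% x))
}

activation_fun <- function(name) {
  switch(name,
         relu = function(z) pmax(z, 0),
         identity = function(z) z,
         stop("unknown activation: ", name))
}

#' One GCN layer forward pass
#'
#' `H_next = sigma(kernel %*% H %*% W[[layer_index]])` with the model's
#' cached propagation operator and per-layer activation.
#'
#' @param H input activations (nodes x in-dim).
#' @param model a [gcn_fit()] model.
#' @param layer_index 1-based layer number.
#' @return activations of the next layer.
#' @export
gcn_layer_forward <- function(H, model, layer_index) {
  W <- model$layer_weights[[layer_index]]
  if (ncol(H) != nrow(W))
    stop("input width ", ncol(H), " does not match layer in-dim ", nrow(W))
  sigma <- activation_fun(model$activation[layer_index])
  sigma(model$propagation_operator %*% H %*% W)
}

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Fit a two-layer graph convolutional network on a labeled disease graph
#'
#' Semi-supervised node classification in the transductive setting:
#' propagation uses the whole graph, the cross-entropy loss is averaged over
#' labeled nodes only (labels 1/0; NA nodes are masked out).  Layers follow
#' `H^(l+1) = sigma(D^(-1/2) Â D^(-1/2) H^(l) W^(l))` with no bias terms,
#' ReLU on the hidden layer and a 2-way softmax output, trained by full-batch
#' gradient descent.
#'
#' @param graph a [build_disease_graph()] object with >= 1 positive and >= 1
#'   negative (non-NA) label.
#' @param hidden_dim width of the hidden embedding layer.
#' @param epochs number of full-batch gradient steps.
#' @param learning_rate gradient-descent step size.
#' @param self_loops add `A + I` before normalization (default TRUE); turning
#'   it off reproduces the literal propagation rule, which discards each
#'   node's own features.
#' @param seed integer seed for weight initialization.
#' @return object of class `gcn_model` with fields `layer_weights`,
#'   `activation`, `propagation_operator`, `loss_trace`, `hidden_dim`,
#'   `self_loops`, `seed`, `node_ids`.
#' @export
gcn_fit <- function(graph, hidden_dim = 64L, epochs = 200L,
                    learning_rate = 0.2, self_loops = TRUE, seed = 1L) {
  stopifnot(inherits(graph, "disease_graph"))
  y <- graph$labels
  lab <- which(!is.na(y))
  if (length(lab) == 0) stop("no labeled nodes")
  if (sum(y[lab] == 1) == 0 || sum(y[lab] == 0) == 0)
    stop("need at least one positive and one negative labeled node")
  X <- graph$features
  storage.mode(X) <- "double"
  K <- sym_normalized_operator(graph$adjacency, self_loops)$kernel
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  W1 <- glorot_init(p, hidden_dim)
  W2 <- glorot_init(hidden_dim, 2L)
  Y <- cbind(1 - y[lab], y[lab])          # columns: class 0, class 1
  KX <- K %*% X                            # constant across epochs
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    A1 <- KX %*% W1
    H1 <- pmax(A1, 0)
    Z <- K %*% H1 %*% W2
    P <- softmax_rows(Z)
    loss_trace[ep] <- -mean(log(pmax(P[cbind(lab, y[lab] + 1L)], 1e-12)))
    dZ <- matrix(0, n, 2)
    dZ[lab, ] <- (P[lab, , drop = FALSE] - Y) / length(lab)
    KdZ <- K %*% dZ
    dW2 <- crossprod(H1, KdZ)
    dH1 <- KdZ %*% t(W2)
    dA1 <- dH1 * (A1 > 0)
    dW1 <- crossprod(KX, dA1)
    W1 <- W1 - learning_rate * dW1
    W2 <- W2 - learning_rate * dW2
  }
  structure(list(layer_weights = list(W1, W2),
                 activation = c("relu", "identity"),
                 propagation_operator = K,
                 hidden_dim = as.integer(hidden_dim),
                 self_loops = self_loops,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 loss_trace = loss_trace, seed = as.integer(seed),
                 node_ids = graph$node_ids),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("Two-layer GCN: %d nodes, %d -> %d -> 2, self-loops %s\n",
              length(x$node_ids), nrow(x$layer_weights[[1]]),
              x$hidden_dim, x$self_loops))
  cat(sprintf("  %d epochs @ lr %g; training loss %.4f -> %.4f\n",
              x$epochs, x$learning_rate,
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Node embeddings from a trained GCN
#'
#' Hidden-layer activations per node (nodes x hidden_dim), the encoded
#' disease representation handed to the boosting classifier.
#'
#' @param graph the disease graph the model was trained on (features are
#'   re-propagated, so the call is idempotent).
#' @param model a fitted `gcn_model`.
#' @return numeric matrix, rows named by node ID.
#' @export
embed_nodes <- function(graph, model) {
  if (!inherits(model, "gcn_model")) stop("model is not a trained gcn_model")
  X <- graph$features
  storage.mode(X) <- "double"
  H1 <- gcn_layer_forward(X, model, 1L)
  rownames(H1) <- graph$node_ids
  H1
}

#' @export
predict.gcn_model <- function(object, graph, ...) {
  H1 <- embed_nodes(graph, object)
  Z <- gcn_layer_forward(H1, object, 2L)
  P <- softmax_rows(Z)
  stats::setNames(P[, 2], graph$node_ids)
}
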