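test_that("degree matrix and Laplacian follow their definitions", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(degree_matrix(A), diag(1, 2))
  expect_equal(laplacian(A), matrix(c(1, -1, -1, 1), 2))
  expect_equal(unname(rowSums(laplacian(A))), c(0, 0))
  expect_equal(degree_matrix(matrix(0, 3, 3)), diag(0, 3))
  W <- matrix(runif(16), 4); W <- W + t(W); diag(W) <- 0
  expect_equal(diag(degree_matrix(W)), rowSums(W))
  expect_equal(laplacian(W), t(laplacian(W)))
  expect_error(degree_matrix(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("symmetric normalization follows the zero-degree convention", {
  A <- matrix(c(0, 1, 1, 0), 2)
  op <- sym_normalized_operator(A)
  expect_equal(op$l_sym, matrix(c(1, -1, -1, 1), 2))
  expect_equal(op$kernel, matrix(c(0, 1, 1, 0), 2))

  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1  # node 3 isolated
  op3 <- sym_normalized_operator(A3)
  expect_equal(op3$l_sym[3, 3], 0)
  expect_true(all(op3$kernel[3, ] == 0) && all(op3$kernel[, 3] == 0))

  op1 <- sym_normalized_operator(matrix(0, 1, 1), self_loops = TRUE)
  expect_equal(op1$kernel, matrix(1))

  expect_error(sym_normalized_operator(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("normalized operators have the expected spectra", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    A <- matrix(stats::runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    A[A < 0.5] <- 0
    op <- sym_normalized_operator(A, self_loops = FALSE)
    ev <- eigen(op$l_sym, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
    opl <- sym_normalized_operator(A, self_loops = TRUE)
    expect_equal(opl$kernel, t(opl$kernel))
    expect_lte(max(abs(eigen(opl$kernel, only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("Chebyshev recurrence matches the cosine closed form", {
  expect_equal(chebyshev_polynomials(0.31, 0), 1)
  expect_equal(chebyshev_polynomials(0.5, 2)[3], -0.5)
  expect_equal(chebyshev_polynomials(1, 10), rep(1, 11))
  theta <- 0.77
  expect_equal(chebyshev_polynomials(cos(theta), 10), cos((0:10) * theta),
               tolerance = 1e-12)
})

test_that("first-order filter matches dense assembly and collapses correctly", {
  set.seed(7)
  n <- 5
  A <- matrix(stats::runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
  x <- stats::rnorm(n)
  K <- sym_normalized_operator(A)$kernel
  expect_equal(first_order_filter(x, A, 1, 0), x)
  expect_equal(first_order_filter(x, A, 0, -1), drop(K %*% x))
  th <- c(0.8, -0.3)
  expect_equal(first_order_filter(x, A, th[1], th[2]),
               drop(th[1] * x - th[2] * K %*% x), tolerance = 1e-12)
  # single-parameter renormalized collapse: theta1 = -theta0
  expect_equal(first_order_filter(x, A, 0.4, -0.4),
               drop(0.4 * (diag(n) + K) %*% x), tolerance = 1e-12)
})

test_that("a GCN layer equals explicit matrix assembly", {
  # identity pass-through: single self-looped node, identity weights
  m1 <- structure(list(layer_weights = list(diag(3)),
                       activation = "identity",
                       propagation_operator = matrix(1)),
                  class = "gcn_model")
  H <- matrix(rnorm(3), 1)
  expect_equal(gcn_layer_forward(H, m1, 1), H)

  set.seed(13)
  n <- 6; p <- 4; hdim <- 3
  A <- matrix(stats::runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
  K <- sym_normalized_operator(A, self_loops = TRUE)$kernel
  W <- matrix(stats::rnorm(p * hdim), p)
  m <- structure(list(layer_weights = list(W), activation = "relu",
                      propagation_operator = K),
                 class = "gcn_model")
  H0 <- matrix(stats::rnorm(n * p), n)
  expect_equal(gcn_layer_forward(H0, m, 1), pmax(K %*% H0 %*% W, 0),
               tolerance = 1e-12)
  expect_equal(gcn_layer_forward(matrix(0, n, p), m, 1), matrix(0, n, hdim))
  expect_error(gcn_layer_forward(matrix(0, n, p + 1), m, 1), "in-dim")
})

test_that("GCN training reduces loss, is reproducible and monotone", {
  scen <- small_scenario(seed = 7, signal_strength = 1)
  g <- scenario_graph(scen)
  m <- gcn_fit(g, hidden_dim = 8, epochs = 150, seed = 7)
  expect_lt(m$loss_trace[150], m$loss_trace[1])
  expect_true(all(diff(m$loss_trace) <= 1e-9))
  m2 <- gcn_fit(g, hidden_dim = 8, epochs = 150, seed = 7)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_identical(m$layer_weights, m2$layer_weights)

  g_unlab <- g; g_unlab$labels[] <- NA
  expect_error(gcn_fit(g_unlab), "no labeled nodes")
})

test_that("uninformative graph plateaus at the class-prior entropy", {
  n <- 20
  ids <- sprintf("D%02d", 1:n)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  X <- matrix(1, n, 3, dimnames = list(ids, paste0("p", 1:3)))
  y <- stats::setNames(c(rep(1L, 5), rep(0L, 15)), ids)
  g <- structure(list(node_ids = ids, adjacency = A, features = X, labels = y),
                 class = "disease_graph")
  m <- gcn_fit(g, hidden_dim = 4, epochs = 3000, learning_rate = 0.5, seed = 2)
  prior <- 0.25
  floor_loss <- -(prior * log(prior) + (1 - prior) * log(1 - prior))
  expect_equal(m$loss_trace[3000], floor_loss, tolerance = 1e-3)
})

test_that("embeddings separate planted classes and are idempotent", {
  scen <- small_scenario(seed = 7, signal_strength = 1)
  g <- scenario_graph(scen)
  m <- gcn_fit(g, hidden_dim = 8, epochs = 300, seed = 7)
  E <- embed_nodes(g, m)
  expect_equal(nrow(E), length(g$node_ids))
  expect_identical(E, embed_nodes(g, m))

  pos <- g$labels == 1
  centroid_p <- colMeans(E[pos, , drop = FALSE])
  centroid_n <- colMeans(E[!pos, , drop = FALSE])
  inter <- sqrt(sum((centroid_p - centroid_n)^2))
  intra <- mean(c(
    apply(E[pos, , drop = FALSE], 1, function(r) sqrt(sum((r - centroid_p)^2))),
    apply(E[!pos, , drop = FALSE], 1, function(r) sqrt(sum((r - centroid_n)^2)))
  ))
  expect_gt(inter, 0)
  expect_gt(inter / intra, 0.5)
  dists <- as.matrix(stats::dist(E))
  expect_gt(mean(dists[pos, !pos]), mean(dists[pos, pos]))

  expect_error(embed_nodes(g, list()), "not a trained")
})
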