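test_that("logistic gradients match closed form and finite differences", {
  expect_equal(logistic_gradients(0, 1), list(g = -0.5, h = 0.25))
  expect_equal(logistic_gradients(0, 0), list(g = 0.5, h = 0.25))
  loss <- function(F, y) -(y * log(1 / (1 + exp(-F))) +
                             (1 - y) * log(1 - 1 / (1 + exp(-F))))
  eps <- 1e-5
  for (F in c(-1, 1)) for (y in c(0, 1)) {
    num_g <- (loss(F + eps, y) - loss(F - eps, y)) / (2 * eps)
    expect_equal(logistic_gradients(F, y)$g, num_g, tolerance = 1e-6)
  }
})

test_that("leaf weight is the shrunk Newton step", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(0, 5, 2), 0)
  lambdas <- c(0, 0.5, 1, 10, 1e3, 1e9)
  w <- abs(leaf_weight(rep(2, 6), rep(3, 6), lambdas))
  expect_true(all(diff(w) < 0))
  expect_lt(w[6], 1e-8)
  expect_error(leaf_weight(1, -2, 1), "positive")
})

test_that("structure score and split gain agree with direct summation", {
  expect_equal(structure_score(list(c(0, 1)), lambda = 1, gamma = 0.7), 0.7)
  expect_equal(structure_score(list(c(1, 1), c(-1, 1)), 1, 0), -0.5)
  set.seed(1)
  stats_list <- replicate(6, c(stats::rnorm(1), stats::runif(1, 0.1, 2)),
                          simplify = FALSE)
  lam <- 0.8; gam <- 0.3
  manual <- -0.5 * sum(vapply(stats_list, function(s)
    s[1]^2 / (s[2] + lam), numeric(1))) + gam * length(stats_list)
  expect_equal(structure_score(stats_list, lam, gam), manual)

  expect_equal(split_gain(1, 1, -1, 1, 0, 0), 1)
  expect_lt(split_gain(1, 1, -1, 1, 0, gamma = 5), 0)
  # Cauchy-Schwarz: gain >= 0 at lambda = gamma = 0
  set.seed(2)
  for (i in 1:200) {
    GL <- stats::rnorm(1); GR <- stats::rnorm(1)
    HL <- stats::runif(1, 0.01, 3); HR <- stats::runif(1, 0.01, 3)
    expect_gte(split_gain(GL, HL, GR, HR, 0, 0), -1e-12)
  }
})

test_that("accepting a split changes the structure score by the gain term", {
  set.seed(3)
  for (i in 1:50) {
    GL <- stats::rnorm(1); GR <- stats::rnorm(1)
    HL <- stats::runif(1, 0.1, 2); HR <- stats::runif(1, 0.1, 2)
    lam <- stats::runif(1, 0, 2); gam <- stats::runif(1, 0, 1)
    parent <- structure_score(list(c(GL + GR, HL + HR)), lam, gam)
    children <- structure_score(list(c(GL, HL), c(GR, HR)), lam, gam)
    bracket <- split_gain(GL, HL, GR, HR, lam, 0)
    expect_equal(parent - children, bracket - gam, tolerance = 1e-10)
  }
})

test_that("tree growth is exact greedy", {
  # all labels identical: no split, single leaf with the Newton step
  g <- rep(-0.5, 4); h <- rep(0.25, 4)
  cfg <- boost_config(max_depth = 3, lambda = 1, gamma = 0)
  tr <- build_tree(matrix(stats::runif(8), 4), g, h, cfg)
  expect_null(tr$split_feature)
  expect_equal(tr$leaf_weight, -sum(g) / (sum(h) + 1))

  # 1-D toy: best depth-1 split falls between 2 and 3
  x <- matrix(1:4, ncol = 1)
  g2 <- c(0.5, 0.5, -0.5, -0.5); h2 <- rep(0.25, 4)
  cfg1 <- boost_config(max_depth = 1, lambda = 1, gamma = 0,
                       min_child_hessian = 0)
  tr2 <- build_tree(x, g2, h2, cfg1)
  expect_equal(tr2$split_feature, 1)
  expect_gt(tr2$split_threshold, 2)
  expect_lt(tr2$split_threshold, 3)

  # fitted root gain equals the brute-force enumeration maximum
  set.seed(8)
  for (rep in 1:5) {
    n <- 30; p <- 5
    xr <- matrix(stats::rnorm(n * p), n)
    gr <- stats::rnorm(n); hr <- stats::runif(n, 0.05, 1)
    cfgr <- boost_config(max_depth = 1, lambda = 0.5, gamma = 0.05,
                         min_child_hessian = 1e-3)
    fitted <- build_tree(xr, gr, hr, cfgr)
    oracle <- best_split_oracle(xr, gr, hr, 0.5, 0.05, 1e-3)
    if (oracle > 0) expect_equal(root_gain(fitted), oracle, tolerance = 1e-10)
    else expect_null(fitted$split_feature)
  }
})

test_that("every internal node of a deep tree is brute-force optimal", {
  set.seed(12)
  n <- 40
  x <- matrix(stats::rnorm(n * 4), n)
  y <- as.numeric(x[, 1] + 0.5 * x[, 2] + stats::rnorm(n, sd = 0.3) > 0)
  gh <- logistic_gradients(rep(0, n), y)
  cfg <- boost_config(max_depth = 3, lambda = 1, gamma = 0,
                      min_child_hessian = 1e-3)
  tr <- build_tree(x, gh$g, gh$h, cfg)
  # walk the tree, re-deriving each node's sample set from the splits
  check_node <- function(node, idx) {
    if (is.null(node$split_feature)) return(invisible())
    oracle <- best_split_oracle(x[idx, , drop = FALSE], gh$g[idx], gh$h[idx],
                                cfg$lambda, cfg$gamma, cfg$min_child_hessian)
    expect_equal(node$gain, oracle, tolerance = 1e-10)
    left <- idx[x[idx, node$split_feature] <= node$split_threshold]
    right <- setdiff(idx, left)
    check_node(node$left, left)
    check_node(node$right, right)
  }
  check_node(tr, seq_len(n))
})

test_that("boosted fit drives training loss down and separates separable data", {
  set.seed(5)
  n <- 60
  x <- cbind(stats::rnorm(n), stats::rnorm(n))
  y <- as.numeric(x[, 1] + x[, 2] > 0)
  fit <- xgb_fit(x, y, boost_config(n_rounds = 20, learning_rate = 0.5,
                                    lambda = 0.1))
  expect_equal(as.numeric(predict(fit, x) > 0.5), y)  # accuracy 1.0
  fit2 <- xgb_fit(x, y, boost_config(n_rounds = 30, learning_rate = 0.1))
  expect_true(all(diff(fit2$train_loss) <= 1e-9))
  expect_error(xgb_fit(x, rep(1, n), boost_config()), "both classes")
})

test_that("first-round leaves are computed at margin zero", {
  set.seed(6)
  x <- matrix(stats::rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  cfg <- boost_config(n_rounds = 1, learning_rate = 1)
  fit <- xgb_fit(x, y, cfg)
  gh <- logistic_gradients(rep(0, 10), y)   # margins start at zero
  manual <- build_tree(x, gh$g, gh$h, cfg)
  expect_equal(fit$trees[[1]], manual)
  expect_equal(predict_margin(fit, x),
               vapply(seq_len(10), function(i) {
                 node <- manual
                 while (is.null(node$leaf_weight)) {
                   node <- if (x[i, node$split_feature] <= node$split_threshold)
                     node$left else node$right
                 }
                 node$leaf_weight
               }, numeric(1)))
})

test_that("prediction is the sigmoid of accumulated margins", {
  empty <- structure(list(base_score = 0, trees = list(),
                          config = boost_config(), n_features = 3),
                     class = "boosted_model")
  x <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(predict_proba(empty, x), rep(0.5, 4))
  expect_error(predict_proba(empty, matrix(0, 2, 5)), "width")

  set.seed(9)
  y <- c(0, 1, 1, 0)
  fit <- xgb_fit(x, y, boost_config(n_rounds = 7, learning_rate = 0.3))
  manual <- rep(0, 4)
  for (tr in fit$trees)
    manual <- manual + 0.3 * vapply(seq_len(4), function(i) {
      node <- tr
      while (is.null(node$leaf_weight)) {
        node <- if (x[i, node$split_feature] <= node$split_threshold)
          node$left else node$right
      }
      node$leaf_weight
    }, numeric(1))
  expect_equal(predict_margin(fit, x), manual, tolerance = 1e-12)
  expect_equal(predict_proba(fit, x), 1 / (1 + exp(-manual)))

  xi <- x; storage.mode(xi) <- "double"
  expect_identical(predict_proba(fit, xi), predict_proba(fit, x))
})

test_that("reference GBDT initial score and leaf values follow the formulas", {
  expect_equal(gbdt_init_score(c(-1, 1, -1, 1)), 0)
  y <- c(rep(1, 3), -1)  # ybar = 0.5
  expect_equal(gbdt_init_score(y), 0.5 * log(3))
  expect_equal(gbdt_init_score(y), -gbdt_init_score(-y))
  expect_error(gbdt_init_score(rep(1, 5)), "identical")

  expect_equal(gbdt_leaf_value(0.5), 0.5 / (0.5 * 1.5))
  expect_error(gbdt_leaf_value(c(0, 0)), "degenerate")
  set.seed(10)
  r <- stats::runif(20, -1, 1)
  expect_equal(sign(gbdt_leaf_value(r)), sign(sum(r)))
})

test_that("predictions agree with the reference xgboost library", {
  skip_if_not_installed("xgboost")
  set.seed(14)
  n <- 80
  x <- matrix(stats::rnorm(n * 3), n)
  y <- as.numeric(x[, 1] - x[, 2] + stats::rnorm(n, sd = 0.5) > 0)
  cfg <- boost_config(n_rounds = 10, max_depth = 3, learning_rate = 0.3,
                      lambda = 1, gamma = 0, min_child_hessian = 1e-3)
  ours <- predict_proba(xgb_fit(x, y, cfg), x)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                  lambda = 1, gamma = 0, min_child_weight = 1e-3,
                  base_score = 0.5, tree_method = "exact", nthread = 1),
    data = dtrain, nrounds = 10, verbose = 0)
  theirs <- predict(ref, dtrain)
  expect_gt(stats::cor(ours, theirs), 0.999)
  expect_lt(max(abs(ours - theirs)), 0.02)
})
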