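#' Boosting hyperparameters
#'
#' @param n_rounds number of boosting rounds (trees).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param learning_rate shrinkage applied to each tree's contribution,
#'   in (0, 1].
#' @param lambda L2 penalty on leaf weights (>= 0).
#' @param gamma per-leaf complexity penalty subtracted from every split gain
#'   (>= 0).
#' @param min_child_hessian minimum hessian sum allowed in a child (>= 0).
#' @param seed integer, recorded for provenance (the exact-greedy fit is
#'   deterministic).
#' @return object of class `boost_config`.
#' @export
boost_config <- function(n_rounds = 50L, max_depth = 3L, learning_rate = 0.1,
                         lambda = 1, gamma = 0, min_child_hessian = 1e-3,
                         seed = 1L) {
  stopifnot(n_rounds >= 1, max_depth >= 0,
            learning_rate > 0, learning_rate <= 1,
            lambda >= 0, gamma >= 0, min_child_hessian >= 0)
  structure(list(n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, lambda = lambda,
                 gamma = gamma, min_child_hessian = min_child_hessian,
                 seed = as.integer(seed)),
            class = "boost_config")
}

#' Gradient and hessian of the binary logistic loss
#'
#' For margin F and label y in \{0, 1\}: `p = 1/(1 + exp(-F))`, gradient
#' `g = p - y`, hessian `h = p (1 - p)`.  Vectorized.
#'
#' @param margin numeric vector of raw margins.
#' @param label numeric vector of 0/1 labels.
#' @return list with components `g` and `h`.
#' @export
logistic_gradients <- function(margin, label) {
  stopifnot(all(is.finite(margin)), all(label %in% c(0, 1)))
  p <- 1 / (1 + exp(-margin))
  list(g = p - label, h = p * (1 - p))
}

#' Optimal leaf weight -G / (H + lambda)
#'
#' @param G leaf gradient sum.
#' @param H leaf hessian sum; `H + lambda` must be positive.
#' @param lambda L2 penalty.
#' @return the Newton-step leaf weight.
#' @export
leaf_weight <- function(G, H, lambda) {
  if (any(H + lambda <= 0)) stop("H + lambda must be positive")
  -G / (H + lambda)
}

#' Structure score of a fixed tree shape
#'
#' `-1/2 * sum_j G_j^2 / (H_j + lambda) + gamma * T` over the leaves, with
#' T = number of leaves.  Lower is better.
#'
#' @param leaf_stats list of length-2 numeric vectors `c(G, H)`, one per leaf.
#' @param lambda,gamma regularization parameters.
#' @return the structure score.
#' @export
structure_score <- function(leaf_stats, lambda, gamma) {
  G <- vapply(leaf_stats, `[`, numeric(1), 1)
  H <- vapply(leaf_stats, `[`, numeric(1), 2)
  if (any(H + lambda <= 0)) stop("H + lambda must be positive for every leaf")
  -0.5 * sum(G^2 / (H + lambda)) + gamma * length(leaf_stats)
}

#' Gain of splitting one leaf into left/right children
#'
#' `1/2 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda))
#'  - gamma`.  Non-negative for lambda = gamma = 0.
#'
#' @param GL,HL,GR,HR gradient/hessian sums of the two children.
#' @param lambda,gamma regularization parameters.
#' @return the split gain.
#' @export
split_gain <- function(GL, HL, GR, HR, lambda, gamma) {
  if (any(HL + lambda <= 0) || any(HR + lambda <= 0))
    stop("child hessian sum plus lambda must be positive")
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

# Best split for one node by exact greedy enumeration: every feature, every
# midpoint between consecutive distinct sorted values.  Vectorized per
# feature via cumulative gradient/hessian sums.  Ties break to the lowest
# feature index, then the lowest threshold.
best_split <- function(x, g, h, config) {
  n <- length(g)
  Gt <- sum(g); Ht <- sum(h)
  best <- list(gain = -Inf, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    o <- order(xj)
    xs <- xj[o]
    distinct <- which(diff(xs) > 0)          # split after these positions
    if (!length(distinct)) next
    cg <- cumsum(g[o]); ch <- cumsum(h[o])
    GL <- cg[distinct]; HL <- ch[distinct]
    GR <- Gt - GL; HR <- Ht - HL
    ok <- HL >= config$min_child_hessian & HR >= config$min_child_hessian
    if (!any(ok)) next
    gains <- 0.5 * (GL^2 / (HL + config$lambda) + GR^2 / (HR + config$lambda) -
                      Gt^2 / (Ht + config$lambda)) - config$gamma
    gains[!ok] <- -Inf
    k <- which.max(gains)                     # first max -> lowest threshold
    if (gains[k] > best$gain + 1e-15 ||
        (abs(gains[k] - best$gain) <= 1e-15 && is.na(best$feature))) {
      best <- list(gain = gains[k], feature = j,
                   threshold = (xs[distinct[k]] + xs[distinct[k] + 1]) / 2)
    }
  }
  best
}

#' Grow one regression tree by exact greedy second-order splitting
#'
#' At each node every feature and every midpoint between consecutive distinct
#' sorted values is scored with [split_gain()]; the maximum-gain split is
#' taken.  Growth stops at `max_depth`, on non-positive gain, or when a child
#' hessian sum would fall below `min_child_hessian`.  Leaves receive
#' [leaf_weight()] values.
#'
#' @param x numeric feature matrix (samples x features).
#' @param g,h per-sample gradients and hessians.
#' @param config a [boost_config()].
#' @return nested-list tree: internal nodes carry `split_feature`,
#'   `split_threshold`, `left`, `right`; leaves carry `leaf_weight`; every
#'   node carries `stats = c(G, H)`.
#' @export
build_tree <- function(x, g, h, config) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1, length(g) == nrow(x), length(h) == nrow(x),
            all(is.finite(g)), all(is.finite(h)))
  grow <- function(idx, depth) {
    G <- sum(g[idx]); H <- sum(h[idx])
    node <- list(stats = c(G = G, H = H))
    if (depth < config$max_depth && length(idx) >= 2) {
      sp <- best_split(x[idx, , drop = FALSE], g[idx], h[idx], config)
      if (is.finite(sp$gain) && sp$gain > 0) {
        go_left <- x[idx, sp$feature] <= sp$threshold
        node$split_feature <- sp$feature
        node$split_threshold <- sp$threshold
        node$gain <- sp$gain
        node$left <- grow(idx[go_left], depth + 1L)
        node$right <- grow(idx[!go_left], depth + 1L)
        return(node)
      }
    }
    node$leaf_weight <- leaf_weight(G, H, config$lambda)
    node
  }
  grow(seq_len(nrow(x)), 0L)
}

tree_predict <- function(tree, x) {
  out <- numeric(nrow(x))
  descend <- function(node, idx) {
    if (!is.null(node$leaf_weight)) {
      out[idx] <<- node$leaf_weight
      return(invisible())
    }
    go_left <- x[idx, node$split_feature] <= node$split_threshold
    descend(node$left, idx[go_left])
    descend(node$right, idx[!go_left])
  }
  if (nrow(x)) descend(tree, seq_len(nrow(x)))
  out
}

tree_leaves <- function(tree) {
  if (!is.null(tree$leaf_weight)) return(list(tree))
  c(tree_leaves(tree$left), tree_leaves(tree$right))
}

#' Fit a second-order gradient-boosted tree classifier
#'
#' Additive training: margins start at the base score 0, each round fits one
#' [build_tree()] to the current logistic gradients/hessians and margins are
#' updated with `learning_rate` shrinkage.  Deterministic given the config.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y 0/1 labels; both classes must be present.
#' @param config a [boost_config()].
#' @return object of class `boosted_model` with fields `base_score`, `trees`,
#'   `config`, `n_features`, `train_loss` (per-round logistic loss).
#' @export
xgb_fit <- function(x, y, config = boost_config()) {
  x <- as.matrix(x)
  stopifnot(inherits(config, "boost_config"),
            nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training labels")
  margin <- rep(0, nrow(x))                 # y-hat^0 = 0
  trees <- vector("list", config$n_rounds)
  train_loss <- numeric(config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    gh <- logistic_gradients(margin, y)
    trees[[t]] <- build_tree(x, gh$g, gh$h, config)
    margin <- margin + config$learning_rate * tree_predict(trees[[t]], x)
    p <- 1 / (1 + exp(-margin))
    train_loss[t] <- -mean(y * log(pmax(p, 1e-12)) +
                             (1 - y) * log(pmax(1 - p, 1e-12)))
  }
  structure(list(base_score = 0, trees = trees, config = config,
                 n_features = ncol(x), train_loss = train_loss),
            class = "boosted_model")
}

#' @export
print.boosted_model <- function(x, ...) {
  n_leaves <- vapply(x$trees, function(tr) length(tree_leaves(tr)), integer(1))
  cat(sprintf("Gradient-boosted trees: %d rounds, depth <= %d, lr %g, lambda %g, gamma %g\n",
              length(x$trees), x$config$max_depth, x$config$learning_rate,
              x$config$lambda, x$config$gamma))
  cat(sprintf("  %d features; mean leaves/tree %.1f; final train loss %.4f\n",
              x$n_features, mean(n_leaves),
              x$train_loss[length(x$train_loss)]))
  invisible(x)
}

#' Raw margin of a boosted model
#'
#' `base_score + learning_rate * sum_t tree_t(x)`.
#'
#' @param model a `boosted_model`.
#' @param x feature matrix with `model$n_features` columns.
#' @return numeric vector of margins.
#' @export
predict_margin <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("feature width ", ncol(x), " does not match model (",
         model$n_features, ")")
  m <- rep(model$base_score, nrow(x))
  for (tr in model$trees)
    m <- m + model$config$learning_rate * tree_predict(tr, x)
  m
}

#' Predicted positive-class probabilities
#'
#' Sigmoid of the accumulated margins.
#'
#' @inheritParams predict_margin
#' @return probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) {
  1 / (1 + exp(-predict_margin(model, x)))
}

#' @export
predict.boosted_model <- function(object, newdata,
                                  type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata)
  else predict_margin(object, newdata)
}

#' Initial score of the reference GBDT variant
#'
#' For labels in \{-1, 1\} with mean `ybar`:
#' `F_0 = 1/2 * log((1 + ybar) / (1 - ybar))`.
#'
#' @param y numeric vector of -1/1 labels.
#' @return the initial model score.
#' @export
gbdt_init_score <- function(y) {
  stopifnot(all(y %in% c(-1, 1)))
  ybar <- mean(y)
  if (abs(ybar) >= 1)
    stop("labels are all identical; the initial score diverges")
  0.5 * log((1 + ybar) / (1 - ybar))
}

#' Leaf value of the reference GBDT variant
#'
#' For pseudo-residuals r in a leaf region:
#' `sum(r) / sum(|r| * (2 - |r|))`.
#'
#' @param residuals non-empty numeric vector of pseudo-residuals.
#' @return the regression value of the leaf.
#' @export
gbdt_leaf_value <- function(residuals) {
  if (length(residuals) == 0) stop("leaf region is empty")
  denom <- sum(abs(residuals) * (2 - abs(residuals)))
  if (denom == 0) stop("degenerate leaf: residual denominator is zero")
  sum(residuals) / denom
}

#' Serialize a boosted model to JSON
#'
#' Writes the tree list (split feature/threshold/children/leaf weights), base
#' score and config to a self-describing JSON container.
#'
#' @param model a `boosted_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_boosted_model <- function(model, path) {
  payload <- list(
    format = "ptsarank-boosted-model",
    base_score = model$base_score,
    n_features = model$n_features,
    config = unclass(model$config),
    trees = lapply(model$trees, tree_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

tree_to_list <- function(node) {
  if (!is.null(node$leaf_weight))
    return(list(leaf_weight = node$leaf_weight,
                G = unname(node$stats[1]), H = unname(node$stats[2])))
  list(split_feature = node$split_feature,
       split_threshold = node$split_threshold,
       gain = node$gain,
       left = tree_to_list(node$left), right = tree_to_list(node$right))
}
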