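# Random-forest classifier over the 11-feature sway descriptors: bagged CART
# trees with Gini impurity and per-node feature subsampling (mtry). Class
# probabilities are ensemble vote fractions; predicting with the first
# `n_trees` trees of a larger forest is exactly an n_trees forest, which the
# leave-one-participant-out grid search exploits.

gini_best_split <- function(x, y, n_classes) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(x)
  counts <- matrix(0, n, n_classes)
  counts[cbind(seq_len(n), ys)] <- 1
  left <- apply(counts, 2, cumsum)            # class counts left of split i
  total <- left[n, ]
  cut_ok <- which(diff(xs) > 0)               # splits between distinct values
  if (!length(cut_ok)) return(NULL)
  nl <- cut_ok
  nr <- n - nl
  lcnt <- left[cut_ok, , drop = FALSE]
  rcnt <- matrix(total, length(cut_ok), n_classes, byrow = TRUE) - lcnt
  gini_l <- 1 - rowSums((lcnt / nl)^2)
  gini_r <- 1 - rowSums((rcnt / nr)^2)
  score <- (nl * gini_l + nr * gini_r) / n    # weighted child impurity
  k <- which.min(score)
  list(threshold = (xs[cut_ok[k]] + xs[cut_ok[k] + 1]) / 2,
       score = score[k])
}

grow_tree <- function(X, y, n_classes, mtry, min_node = 1L) {
  # arrays grown in a closure; nodes appended depth-first
  feat <- integer(); thr <- numeric(); left <- integer(); right <- integer()
  pred <- integer()
  new_node <- function() {
    feat[[length(feat) + 1L]] <<- NA_integer_
    thr[[length(thr) + 1L]] <<- NA_real_
    left[[length(left) + 1L]] <<- 0L
    right[[length(right) + 1L]] <<- 0L
    pred[[length(pred) + 1L]] <<- NA_integer_
    length(feat)
  }
  majority <- function(idx) {
    tab <- tabulate(y[idx], n_classes)
    which.max(tab)  # ties -> lowest class
  }
  build <- function(idx) {
    node <- new_node()
    ys <- y[idx]
    if (length(idx) <= min_node || all(ys == ys[1])) {
      pred[node] <<- majority(idx)
      return(node)
    }
    parent_gini <- 1 - sum((tabulate(ys, n_classes) / length(idx))^2)
    cand <- sample.int(ncol(X), mtry)
    best <- NULL
    for (f in cand) {
      sp <- gini_best_split(X[idx, f], ys, n_classes)
      if (!is.null(sp) && (is.null(best) || sp$score < best$score)) {
        best <- sp; best$feature <- f
      }
    }
    if (is.null(best) || best$score >= parent_gini - 1e-12) {
      pred[node] <<- majority(idx)
      return(node)
    }
    go_left <- X[idx, best$feature] <= best$threshold
    feat[node] <<- best$feature
    thr[node] <<- best$threshold
    left[node] <<- build(idx[go_left])
    right[node] <<- build(idx[!go_left])
    node
  }
  build(seq_len(nrow(X)))
  list(feature = feat, threshold = thr, left = left, right = right,
       pred = pred)
}

tree_predict <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  active <- which(is.na(tree$pred[node]))
  while (length(active)) {
    f <- tree$feature[node[active]]
    goes_left <- X[cbind(active, f)] <= tree$threshold[node[active]]
    node[active] <- ifelse(goes_left, tree$left[node[active]],
                           tree$right[node[active]])
    active <- active[is.na(tree$pred[node[active]])]
  }
  tree$pred[node]
}

#' Fit a random forest on feature vectors
#'
#' @param X numeric matrix, one row per example.
#' @param y integer class labels 1..n_classes.
#' @param n_trees ensemble size (the original protocol selected 1000 by
#'   leave-one-participant-out grid search; see [tune_rf()]).
#' @param mtry features sampled per node (default `floor(sqrt(ncol(X)))`).
#' @param n_classes number of classes (default 5).
#' @param seed seed controlling bootstrap and feature sampling.
#' @return object of class `sway_forest`.
#' @export
rf_fit <- function(X, y, n_trees = 1000L, mtry = NULL, n_classes = 5L,
                   seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_domain("need at least 2 training examples")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(nrow(X), replace = TRUE)
      grow_tree(X[boot, , drop = FALSE], y[boot], n_classes, mtry)
    })
  })
  structure(list(trees = trees, n_classes = as.integer(n_classes),
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "sway_forest")
}

#' Class-probability predictions from a forest (vote fractions)
#'
#' @param forest a `sway_forest`.
#' @param X numeric matrix with the training feature columns.
#' @param n_trees use only the first `n_trees` trees (default all), exactly
#'   equivalent to a forest of that size.
#' @return matrix `nrow(X) x n_classes` of vote fractions (rows sum to 1).
#' @export
rf_predict <- function(forest, X, n_trees = length(forest$trees)) {
  X <- as.matrix(X)
  if (ncol(X) != forest$n_features)
    stop_domain("feature count mismatch: forest expects %d, got %d",
                forest$n_features, ncol(X))
  votes <- matrix(0, nrow(X), forest$n_classes)
  for (tr in forest$trees[seq_len(n_trees)]) {
    p <- tree_predict(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1
  }
  votes / n_trees
}

#' Select the forest size by leave-one-participant-out cross-validation
#'
#' For each candidate tree count the held-out macro-AUROC is averaged across
#' folds that leave out one participant at a time; the argmax is returned,
#' with ties broken toward the smallest forest. One maximal forest per fold is
#' fitted and its leading sub-forests are evaluated, which is exactly
#' equivalent to fitting each grid value separately.
#'
#' @param X feature matrix (rows = repetitions).
#' @param y integer labels 1..5.
#' @param participants character/factor vector of participant IDs per row.
#' @param grid candidate tree counts (default `c(250, 500, 1000)`).
#' @param seed seed for the per-fold forests.
#' @return selected tree count; attribute `"cv"` holds the fold-averaged
#'   macro-AUROC per grid value.
#' @export
tune_rf <- function(X, y, participants, grid = c(250L, 500L, 1000L),
                    seed = 1L) {
  X <- as.matrix(X)
  pids <- unique(participants)
  if (length(pids) < 2) stop_domain("grid search needs >= 2 participants")
  grid <- sort(as.integer(grid))
  scores <- matrix(NA_real_, length(pids), length(grid))
  for (i in seq_along(pids)) {
    held <- participants == pids[i]
    if (length(unique(y[held])) < 2) next  # AUROC undefined on this fold
    forest <- rf_fit(X[!held, , drop = FALSE], y[!held],
                     n_trees = max(grid),
                     seed = derive_seed(seed, "fold", i))
    for (j in seq_along(grid)) {
      probs <- rf_predict(forest, X[held, , drop = FALSE], n_trees = grid[j])
      scores[i, j] <- macro_auroc(probs, y[held])
    }
  }
  if (all(is.na(scores)))
    stop_domain("macro-AUROC undefined on every fold (single-class folds)")
  mean_scores <- colMeans(scores, na.rm = TRUE)
  best <- grid[which.max(mean_scores)]  # which.max takes the first (smallest)
  attr(best, "cv") <- stats::setNames(mean_scores, grid)
  attr(best, "n_folds") <- length(pids)
  best
}
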