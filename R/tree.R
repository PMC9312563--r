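# CART-style recursive partitioning for two classes: exhaustive Gini
# split search, minsplit/minbucket stopping, and minimal cost-complexity
# pruning on resubstitution misclassification error (split retained only
# if it buys at least cp * root error per added leaf).

tree_grow <- function(X, y01, rows, minsplit, minbucket, counter) {
  n <- length(rows)
  n1 <- sum(y01[rows])
  node <- list(n = n, n1 = n1, prob = n1 / n, leaf = TRUE)
  if (n < minsplit || n1 == 0 || n1 == n) return(node)

  best <- list(gain = 1e-12, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    o <- order(x)
    xs <- x[o]; ys <- y01[rows][o]
    c1 <- cumsum(ys)
    i <- which(xs[-n] != xs[-1])          # candidate cut positions
    i <- i[i >= minbucket & (n - i) >= minbucket]
    if (!length(i)) next
    nl <- i; nr <- n - i
    child <- c1[i] * (nl - c1[i]) / nl +
      (n1 - c1[i]) * (nr - (n1 - c1[i])) / nr
    gain <- n1 * (n - n1) / n - child
    b <- which.max(gain)
    if (gain[b] > best$gain) {
      best <- list(gain = gain[b], feature = j,
                   threshold = (xs[i[b]] + xs[i[b] + 1]) / 2)
    }
  }
  if (is.na(best$feature)) return(node)

  counter$i <- counter$i + 1L
  sel <- X[rows, best$feature] <= best$threshold
  node$leaf <- FALSE
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$gain <- best$gain
  node$order <- counter$i
  node$left <- tree_grow(X, y01, rows[sel], minsplit, minbucket, counter)
  node$right <- tree_grow(X, y01, rows[!sel], minsplit, minbucket, counter)
  node
}

# resubstitution misclassification count of a node treated as a leaf
node_error <- function(node) min(node$n1, node$n - node$n1)

tree_prune <- function(node, cp_abs) {
  if (node$leaf) return(node)
  node$left <- tree_prune(node$left, cp_abs)
  node$right <- tree_prune(node$right, cp_abs)
  sub <- tree_leaf_stats(node)
  if (node_error(node) - sub$error < cp_abs * (sub$leaves - 1)) {
    node <- list(n = node$n, n1 = node$n1, prob = node$prob, leaf = TRUE)
  }
  node
}

tree_leaf_stats <- function(node) {
  if (node$leaf) return(list(error = node_error(node), leaves = 1L))
  l <- tree_leaf_stats(node$left); r <- tree_leaf_stats(node$right)
  list(error = l$error + r$error, leaves = l$leaves + r$leaves)
}

tree_collect_splits <- function(node, acc = NULL) {
  if (node$leaf) return(acc)
  dir <- if (node$right$prob >= node$left$prob) ">" else "<="
  acc <- rbind(acc, data.frame(feature = node$feature,
                               threshold = node$threshold,
                               direction = dir, gain = node$gain,
                               order = node$order, n = node$n,
                               stringsAsFactors = FALSE))
  acc <- tree_collect_splits(node$left, acc)
  tree_collect_splits(node$right, acc)
}

#' Fit a CART classification tree and summarize its splits
#'
#' Recursive partitioning with the Gini criterion and class-probability
#' leaves, intended for the two-class (NAFL vs NASH) reduction of the
#' eight machine-learning-featured metabolites. Splits are searched
#' exhaustively over (feature, threshold) pairs; the grown tree is pruned
#' by minimal cost-complexity with complexity parameter `cp` relative to
#' the root misclassification error. Feature importance is the total Gini
#' impurity decrease over retained primary splits, with ties in rank broken
#' by split order (earlier split wins the better rank).
#'
#' @param panel Numeric subjects x features matrix (typically the eight
#'   featured metabolites; fewer triggers a warning).
#' @param labels Two-class label per subject.
#' @param cp Complexity parameter (default 0.01).
#' @param minsplit Minimum node size eligible for splitting (default 20).
#' @param minbucket Minimum child size (default 7).
#' @return List of class `tree_summary`: `splits` (data.frame of feature,
#'   threshold, direction, gain, order), `importance` (named vector),
#'   `importance_rank` (named 1..k), `selected_features`, `positive`,
#'   `tree` (nested node structure).
#' @export
fit_classification_tree <- function(panel, labels, cp = 0.01,
                                    minsplit = 20L, minbucket = 7L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("single-class input")
  if (length(classes) > 2) stop("two classes required")
  if (ncol(panel) < 8) warning("fewer than 8 input features")
  pos <- disease_class(classes)
  y01 <- as.integer(labels == pos)

  counter <- new.env()
  counter$i <- 0L
  root <- tree_grow(panel, y01, seq_len(nrow(panel)), minsplit, minbucket,
                    counter)
  cp_abs <- cp * node_error(root)
  root <- tree_prune(root, cp_abs)

  splits <- tree_collect_splits(root)
  if (!is.null(splits)) {
    splits$feature <- colnames(panel)[splits$feature]
    splits <- splits[order(splits$order), ]
    rownames(splits) <- NULL
  }
  imp <- stats::setNames(numeric(ncol(panel)), colnames(panel))
  first_order <- stats::setNames(rep(Inf, ncol(panel)), colnames(panel))
  if (!is.null(splits)) {
    for (i in seq_len(nrow(splits))) {
      f <- splits$feature[i]
      imp[f] <- imp[f] + splits$gain[i]
      first_order[f] <- min(first_order[f], splits$order[i])
    }
  }
  selected <- names(imp)[imp > 0]
  ord <- order(-imp[selected], first_order[selected])
  selected <- selected[ord]
  rank <- stats::setNames(seq_along(selected), selected)

  structure(list(splits = splits, importance = imp[selected],
                 importance_rank = rank, selected_features = selected,
                 positive = pos, tree = root),
            class = "tree_summary")
}

#' Predict class-1 probabilities from a fitted classification tree
#'
#' @param tree A `tree_summary` from [fit_classification_tree()].
#' @param panel Numeric matrix with the same columns as used for fitting.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_tree_prob <- function(tree, panel) {
  stopifnot(inherits(tree, "tree_summary"))
  cols <- colnames(panel)
  one <- function(node, x) {
    while (!node$leaf) {
      j <- match(node$feature_name, cols)
      node <- if (x[j] <= node$threshold) node$left else node$right
    }
    node$prob
  }
  # attach feature names once (splits store indices of the fitting panel)
  attach_names <- function(node) {
    if (node$leaf) return(node)
    node$feature_name <- cols[node$feature]
    node$left <- attach_names(node$left)
    node$right <- attach_names(node$right)
    node
  }
  root <- attach_names(tree$tree)
  apply(panel, 1, function(x) one(root, x))
}
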