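# Axis-aligned classification tree grown by exhaustive split search under the
# Gini criterion. Deliberately small and fully deterministic (tie-breaks:
# lowest feature index, then lowest threshold) so runs are reproducible across
# platforms and the tree can be compared against brute-force enumeration on
# tiny datasets.

gini_impurity <- function(labels, levels) {
  p <- tabulate(match(labels, levels), length(levels)) / length(labels)
  1 - sum(p^2)
}

# candidate thresholds for one feature: midpoints of consecutive unique values
split_candidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

# best (feature, threshold) minimizing the weighted child Gini; NULL if no
# valid split exists. Tie-break: lowest feature index, then lowest threshold.
best_split <- function(X, labels, levels) {
  n <- nrow(X)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    for (thr in split_candidates(X[, j])) {
      left <- X[, j] <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      obj <- (nl * gini_impurity(labels[left], levels) +
              (n - nl) * gini_impurity(labels[!left], levels)) / n
      if (is.null(best) || obj < best$objective - 1e-12) {
        best <- list(feature = j, threshold = thr, objective = obj)
      }
    }
  }
  best
}

majority_label <- function(labels, levels) {
  counts <- tabulate(match(labels, levels), length(levels))
  levels[which.max(counts)]    # ties: first level
}

#' Train a Gini decision tree
#'
#' Grows an axis-aligned binary classification tree by exhaustive search over
#' all (feature, midpoint-threshold) splits, choosing the split that
#' minimizes the weighted Gini impurity of the children. Nodes are expanded
#' breadth-first while impure, up to `max_splits` splits. All tie-breaks are
#' deterministic: lowest feature index, then lowest threshold; leaf
#' predictions are the majority label with ties to the first factor level.
#'
#' @param X Feature matrix, one sample per row.
#' @param labels Class label per row (factor or character). A single-class
#'   input yields a single-leaf tree.
#' @param max_splits Maximum number of internal nodes (default `nrow(X)`,
#'   i.e. effectively unlimited at this scale).
#' @param max_depth Maximum depth of an internal node chain (default
#'   unlimited); `max_depth = 2` allows a root split plus one split per
#'   child.
#' @return Object of class `thz_tree`.
#' @export
train_decision_tree <- function(X, labels, max_splits = nrow(X),
                                max_depth = Inf) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  levels <- unique(labels)

  # breadth-first growth over a queue of open node paths
  tree <- list(idx = seq_len(nrow(X)))
  queue <- list(character(0))     # paths into the nested list, root = empty
  splits <- 0L
  get_node <- function(path) if (length(path)) tree[[path]] else tree
  set_node <- function(path, value) {
    if (length(path)) tree[[path]] <<- value else tree <<- value
  }
  while (length(queue) && splits < max_splits) {
    path <- queue[[1]]; queue <- queue[-1]
    if (length(path) >= max_depth) next   # depth = number of path steps
    node <- get_node(path)
    idx <- node$idx
    if (gini_impurity(labels[idx], levels) <= 0) next
    sp <- best_split(X[idx, , drop = FALSE], labels[idx], levels)
    if (is.null(sp)) next
    left <- idx[X[idx, sp$feature] <= sp$threshold]
    right <- setdiff(idx, left)
    set_node(path, list(leaf = FALSE, feature = sp$feature,
                        threshold = sp$threshold,
                        left = list(idx = left), right = list(idx = right)))
    splits <- splits + 1L
    queue <- c(queue, list(c(path, "left")), list(c(path, "right")))
  }
  tree <- finalize_node(tree, labels, levels)
  structure(list(root = tree, levels = levels, n_splits = splits),
            class = "thz_tree")
}

# convert any still-open node into a leaf with its majority prediction
finalize_node <- function(node, labels, levels) {
  if (is.null(node$leaf) || isTRUE(node$leaf)) {
    return(list(leaf = TRUE, prediction = majority_label(labels[node$idx], levels),
                n = length(node$idx)))
  }
  list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
       left = finalize_node(node$left, labels, levels),
       right = finalize_node(node$right, labels, levels))
}

predict_tree_row <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prediction
}

#' @export
predict.thz_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- vapply(seq_len(nrow(newdata)), function(i)
    predict_tree_row(object$root, newdata[i, ]), character(1))
  factor(out, levels = object$levels)
}

#' @export
print.thz_tree <- function(x, ...) {
  cat(sprintf("Gini decision tree: %d split(s), classes: %s\n",
              x$n_splits, paste(x$levels, collapse = ", ")))
  invisible(x)
}
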