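# Shared fixtures and independent oracles, built in code at test time.

# small labeled two-group Gaussian sample in m dimensions
tiny_labeled <- function(n1 = 8, n2 = 8, m = 2, sep = 4, seed = 11) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n1 * m), n1, m),
               matrix(rnorm(n2 * m, mean = sep), n2, m))
    list(X = X, labels = rep(c("a", "b"), c(n1, n2)))
  })
}

# naive mixture log-likelihood by direct summation (no log-domain tricks)
naive_loglik <- function(X, params) {
  s <- 0
  for (j in seq_len(nrow(X))) {
    pj <- 0
    for (k in seq_len(params$K)) {
      d <- X[j, ] - params$means[k, ]
      S <- params$covariances[[k]]
      pj <- pj + params$weights[k] *
        exp(-0.5 * drop(t(d) %*% solve(S) %*% d)) /
        sqrt((2 * pi)^params$m * det(S))
    }
    s <- s + log(pj)
  }
  s
}

# --- brute-force depth-<=2 axis-threshold tree oracle ------------------------
# Enumerates every root (feature, midpoint threshold); each child is either a
# majority leaf or split again by the best depth-1 rule. Objective: total
# weighted Gini impurity of the final leaves, matching the grown tree's
# criterion; ties resolved toward the lexicographically first (feature,
# threshold) combination, the same preference the greedy tree uses.

oracle_candidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

oracle_gini <- function(y, lev) {
  p <- tabulate(match(y, lev), length(lev)) / length(y)
  1 - sum(p^2)
}

oracle_majority <- function(y, lev) lev[which.max(tabulate(match(y, lev), length(lev)))]

# best depth-1 subtree for one node; returns total weighted impurity (counts)
# and the prediction function. An impure node is always split when a valid
# split exists (even at zero Gini gain), mirroring the grown tree's rule.
oracle_depth1 <- function(X, y, lev) {
  leaf <- list(cost = length(y) * oracle_gini(y, lev),
               predict = local({
                 p <- oracle_majority(y, lev)
                 function(x) p
               }))
  if (leaf$cost <= 0) return(leaf)
  best <- NULL
  for (j in seq_len(ncol(X))) for (thr in oracle_candidates(X[, j])) {
    left <- X[, j] <= thr
    if (!any(left) || all(left)) next
    cost <- sum(left) * oracle_gini(y[left], lev) +
      sum(!left) * oracle_gini(y[!left], lev)
    if (is.null(best) || cost < best$cost - 1e-12) {
      pl <- oracle_majority(y[left], lev); pr <- oracle_majority(y[!left], lev)
      best <- list(cost = cost,
                   predict = local({
                     j0 <- j; t0 <- thr; pl0 <- pl; pr0 <- pr
                     function(x) if (x[j0] <= t0) pl0 else pr0
                   }))
    }
  }
  if (is.null(best)) leaf else best
}

oracle_depth2_predict <- function(X, y) {
  lev <- unique(y)
  leaf <- list(cost = length(y) * oracle_gini(y, lev),
               predict = local({
                 p <- oracle_majority(y, lev)
                 function(x) p
               }))
  best <- if (leaf$cost <= 0) leaf else NULL
  if (is.null(best)) {
    for (j in seq_len(ncol(X))) for (thr in oracle_candidates(X[, j])) {
      left <- X[, j] <= thr
      if (!any(left) || all(left)) next
      bl <- oracle_depth1(X[left, , drop = FALSE], y[left], lev)
      br <- oracle_depth1(X[!left, , drop = FALSE], y[!left], lev)
      cost <- bl$cost + br$cost
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(cost = cost,
                     predict = local({
                       j0 <- j; t0 <- thr; fl <- bl$predict; fr <- br$predict
                       function(x) if (x[j0] <= t0) fl(x) else fr(x)
                     }))
      }
    }
    if (is.null(best)) best <- leaf
  }
  function(Xn) vapply(seq_len(nrow(Xn)), function(i) best$predict(Xn[i, ]), "")
}

# fixed fuzz corpus of tiny two-feature datasets (some with duplicated points)
tree_fuzz_corpus <- function(n_datasets = 40, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n_datasets), function(i) {
      n <- sample(4:8, 1)
      X <- matrix(round(rnorm(n * 2), 1), n, 2)   # rounding forces ties
      y <- sample(c("a", "b"), n, replace = TRUE)
      if (length(unique(y)) == 1) y[1] <- setdiff(c("a", "b"), y[1])
      list(X = X, y = y)
    })
  })
}

# fixed corpus of tiny two-cluster datasets: the regime the comparator sees
tree_cluster_corpus <- function(n_datasets = 40, seed = 7) {
  withr::with_seed(seed, {
    lapply(seq_len(n_datasets), function(i) {
      n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
      X <- rbind(matrix(rnorm(n1 * 2, 0, 0.8), n1, 2),
                 matrix(rnorm(n2 * 2, 2.5, 0.8), n2, 2))
      list(X = X, y = rep(c("a", "b"), c(n1, n2)))
    })
  })
}

# total weighted Gini impurity of the leaves a fitted tree induces
tree_leaf_cost <- function(tr, X, y) {
  lev <- unique(y)
  leaf_id <- function(node, x, id = "r") {
    while (!node$leaf) {
      if (x[node$feature] <= node$threshold) { node <- node$left; id <- paste0(id, "L") }
      else { node <- node$right; id <- paste0(id, "R") }
    }
    id
  }
  ids <- vapply(seq_len(nrow(X)), function(i) leaf_id(tr$root, X[i, ]), "")
  sum(tapply(seq_along(ids), ids,
             function(ix) length(ix) * oracle_gini(y[ix], lev)))
}

# minimal total leaf impurity over every depth-<=2 axis-threshold tree
oracle_depth2_cost <- function(X, y) {
  lev <- unique(y)
  if (oracle_gini(y, lev) <= 0) return(0)
  best <- Inf
  for (j in seq_len(ncol(X))) for (thr in oracle_candidates(X[, j])) {
    left <- X[, j] <= thr
    if (!any(left) || all(left)) next
    cost <- oracle_depth1(X[left, , drop = FALSE], y[left], lev)$cost +
      oracle_depth1(X[!left, , drop = FALSE], y[!left], lev)$cost
    best <- min(best, cost)
  }
  if (is.infinite(best)) length(y) * oracle_gini(y, lev) else best
}

# constant classifier used by the combination-harness tests
constant_classifier <- function(label, levels) {
  structure(list(label = label, levels = levels), class = "const_clf")
}

predict.const_clf <- function(object, newdata, ...) {
  factor(rep(object$label, nrow(as.matrix(newdata))), levels = object$levels)
}
registerS3method("predict", "const_clf", predict.const_clf)
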