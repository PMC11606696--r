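#' Multivariate normal density
#'
#' Evaluates \eqn{N(x; \mu, \Sigma) = (2\pi)^{-m/2} |\Sigma|^{-1/2}
#' \exp(-\frac{1}{2}(x-\mu)^T \Sigma^{-1} (x-\mu))} via the Cholesky
#' factorization, computed in the log domain internally for stability.
#'
#' @param x Length-m numeric vector (or n x m matrix of row vectors).
#' @param mu Length-m mean vector.
#' @param sigma m x m symmetric positive-definite covariance.
#' @param log If `TRUE` return the log density.
#' @return Density value(s).
#' @export
mvn_pdf <- function(x, mu, sigma, log = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  ld <- log_mvn_rows(x, mu, as.matrix(sigma), component = NA)
  if (log) ld else exp(ld)
}

# log N(x_j; mu, Sigma) for every row of X; `component` names the offender
# in the error raised on a failed Cholesky factorization
log_mvn_rows <- function(X, mu, Sigma, component) {
  R <- tryCatch(chol(Sigma), error = function(e)
    stop(sprintf("covariance of component %s is not positive definite",
                 as.character(component)), call. = FALSE))
  m <- length(mu)
  Z <- backsolve(R, t(sweep(X, 2, mu)), transpose = TRUE)
  -0.5 * m * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(Z^2)
}

# parameter container ---------------------------------------------------------

#' Construct a Gaussian mixture parameter set
#'
#' @param weights Mixing weights, summing to 1.
#' @param means K x m matrix of component means (rows).
#' @param covariances List of K symmetric positive-definite m x m matrices.
#' @param component_labels Optional character labels, one per component, fixing
#'   the component-to-class mapping.
#' @return Object of class `gmm_params` with fields `K`, `m`, `weights`,
#'   `means`, `covariances`, `component_labels`.
#' @export
gmm_params <- function(weights, means, covariances, component_labels = NULL) {
  means <- as.matrix(means)
  K <- length(weights)
  stopifnot(K >= 1, nrow(means) == K, length(covariances) == K)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (any(weights < 0)) stop("mixture weights must be non-negative", call. = FALSE)
  for (k in seq_len(K)) {
    if (!isTRUE(all.equal(dim(covariances[[k]]), c(ncol(means), ncol(means)))))
      stop("covariance dimensions inconsistent with means", call. = FALSE)
  }
  if (is.null(component_labels)) component_labels <- paste0("component", seq_len(K))
  structure(list(K = K, m = ncol(means), weights = as.numeric(weights),
                 means = means, covariances = covariances,
                 component_labels = as.character(component_labels)),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d components, m = %d dimensions\n", x$K, x$m))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

# default ridge: small fraction of the average marginal variance
default_ridge <- function(S) 1e-8 * mean(diag(S))

#' Label-informed initialization
#'
#' Initializes the mixture from the labeled training set: weights are group
#' proportions, means are group arithmetic means, and covariances are group
#' population covariances (divide by the group size) plus `ridge` times the
#' identity. Component order follows the first appearance of each label, so
#' component 1 is the first-listed (qualified) group.
#'
#' @param X Feature matrix, one sample per row.
#' @param labels Group identifier per row; exactly K distinct values, each
#'   with at least 2 samples.
#' @param ridge Non-negative diagonal regularizer; `NULL` (default) uses
#'   `1e-8` times the mean marginal variance per component.
#' @return A [gmm_params()] with `component_labels` set from the labels.
#' @export
init_from_labels <- function(X, labels, ridge = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  lev <- unique(labels)             # first-appearance order
  if (length(lev) < 2)
    stop("degenerate labels: need at least 2 distinct groups", call. = FALSE)
  counts <- table(factor(labels, levels = lev))
  if (any(counts < 2))
    stop(sprintf("insufficient group: label '%s' has fewer than 2 samples",
                 names(counts)[which(counts < 2)[1]]), call. = FALSE)
  K <- length(lev)
  m <- ncol(X)
  means <- matrix(0, K, m)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    Xk <- X[labels == lev[k], , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    S <- crossprod(sweep(Xk, 2, means[k, ])) / nrow(Xk)   # population (1/N_k)
    r <- if (is.null(ridge)) default_ridge(S) else ridge
    covs[[k]] <- S + diag(r, m)
  }
  gmm_params(weights = as.numeric(counts) / nrow(X), means = means,
             covariances = covs, component_labels = lev)
}

#' E step: posterior responsibilities
#'
#' Computes \eqn{\gamma_{j,k} = \lambda_k N(x_j; \mu_k, \Sigma_k) /
#' \sum_l \lambda_l N(x_j; \mu_l, \Sigma_l)} in the log domain with
#' max-subtraction, so extreme samples never underflow to an all-zero row.
#'
#' @param X Feature matrix (n x m).
#' @param params A [gmm_params()].
#' @return n x K responsibility matrix; every row sums to 1.
#' @export
e_step <- function(X, params) {
  lg <- log_joint(X, params)
  mx <- apply(lg, 1, max)
  g <- exp(lg - mx)
  g / rowSums(g)
}

# n x K matrix of log(lambda_k) + log N(x_j; mu_k, Sigma_k)
log_joint <- function(X, params) {
  X <- as.matrix(X)
  stopifnot(inherits(params, "gmm_params"), ncol(X) == params$m)
  lg <- vapply(seq_len(params$K), function(k) {
    log(params$weights[k]) +
      log_mvn_rows(X, params$means[k, ], params$covariances[[k]], k)
  }, numeric(nrow(X)))
  matrix(lg, nrow(X), params$K)
}

#' M step: parameter update from responsibilities
#'
#' Standard responsibility-weighted updates: effective counts
#' \eqn{N_k = \sum_j \gamma_{j,k}}, weights \eqn{\lambda_k = N_k / N},
#' weighted means and weighted covariances plus `ridge` times the identity.
#' With hard 0/1 responsibilities these reduce to per-group sample
#' statistics, the form in which the updates are often quoted.
#'
#' @param X Feature matrix (n x m).
#' @param gamma n x K responsibility matrix, rows summing to 1.
#' @param ridge As in [init_from_labels()].
#' @param collapse_tol Minimum effective count; a component below it raises a
#'   collapsed-component error naming the component.
#' @return A [gmm_params()].
#' @export
m_step <- function(X, gamma, ridge = NULL, collapse_tol = NULL) {
  X <- as.matrix(X)
  gamma <- as.matrix(gamma)
  stopifnot(nrow(X) == nrow(gamma))
  n <- nrow(X); m <- ncol(X); K <- ncol(gamma)
  if (is.null(collapse_tol)) collapse_tol <- n * 1e-10 + m * .Machine$double.eps
  Nk <- colSums(gamma)
  low <- which(Nk < collapse_tol)
  if (length(low))
    stop(sprintf("component %d collapsed (effective count %.3g)",
                 low[1], Nk[low[1]]), call. = FALSE)
  means <- matrix(0, K, m)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    w <- gamma[, k]
    means[k, ] <- colSums(X * w) / Nk[k]
    Xc <- sweep(X, 2, means[k, ])
    S <- crossprod(Xc * sqrt(w)) / Nk[k]
    r <- if (is.null(ridge)) default_ridge(S) else ridge
    covs[[k]] <- S + diag(r, m)
  }
  gmm_params(weights = Nk / n, means = means, covariances = covs)
}

#' Mixture log-likelihood
#'
#' \eqn{\sum_j \log \sum_k \lambda_k N(x_j; \mu_k, \Sigma_k)}, evaluated with
#' the log-sum-exp trick.
#'
#' @inheritParams e_step
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(X, params) {
  lg <- log_joint(X, params)
  mx <- apply(lg, 1, max)
  sum(mx + log(rowSums(exp(lg - mx))))
}

#' Fit the mixture by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] from the supplied initialization
#' until the log-likelihood improves by less than `tol` or `max_iter` is
#' reached. The per-iteration log-likelihood trajectory is recorded; EM
#' guarantees it never decreases.
#'
#' @param X Feature matrix (n x m).
#' @param init A [gmm_params()] initialization, e.g. from
#'   [init_from_labels()].
#' @param max_iter Maximum EM iterations (>= 1).
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param ridge Passed to [m_step()].
#' @param hard_em If `TRUE`, responsibilities are hardened to 0/1 by
#'   maximum-posterior assignment before each M step, giving the
#'   classification-EM variant in which updates are plain per-group
#'   statistics.
#' @return List with `params` (final [gmm_params()], component labels carried
#'   over from `init`), `responsibilities` (final soft \eqn{\gamma}), and
#'   `report` (class `gmm_fit_report`): `loglik_trajectory`, `n_iterations`,
#'   `converged`, `N`, `N_k`.
#' @export
fit_em <- function(X, init, max_iter = 100, tol = 1e-8, ridge = NULL,
                   hard_em = FALSE) {
  X <- as.matrix(X)
  stopifnot(inherits(init, "gmm_params"), max_iter >= 1)
  params <- init
  traj <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    gamma <- e_step(X, params)
    ll <- log_likelihood(X, params)
    traj <- c(traj, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
    g_use <- if (hard_em) harden(gamma) else gamma
    params <- tryCatch(m_step(X, g_use, ridge = ridge),
                       error = function(e)
                         stop(sprintf("EM iteration %d: %s", iter,
                                      conditionMessage(e)), call. = FALSE))
  }
  params$component_labels <- init$component_labels
  report <- structure(list(loglik_trajectory = traj, n_iterations = iter,
                           converged = converged, N = nrow(X),
                           N_k = colSums(gamma)),
                      class = "gmm_fit_report")
  list(params = params, responsibilities = gamma, report = report)
}

# 0/1 responsibilities by maximum posterior, ties to the lower index
harden <- function(gamma) {
  idx <- max.col(gamma, ties.method = "first")
  h <- matrix(0, nrow(gamma), ncol(gamma))
  h[cbind(seq_len(nrow(gamma)), idx)] <- 1
  h
}

#' Classify samples by posterior responsibility
#'
#' Assigns each sample to the component with the largest responsibility
#' \eqn{\gamma_{j,k}} (ties go to the lower component index) and returns the
#' responsibilities as the confidence report.
#'
#' @inheritParams e_step
#' @return List with `labels` (factor over the component labels) and
#'   `responsibilities` (n x K matrix).
#' @export
gmm_classify <- function(X, params) {
  gamma <- e_step(X, params)
  idx <- max.col(gamma, ties.method = "first")
  labels <- factor(params$component_labels[idx],
                   levels = params$component_labels)
  colnames(gamma) <- params$component_labels
  list(labels = labels, responsibilities = gamma)
}

#' Train a GMM classifier on labeled features
#'
#' Convenience wrapper: [init_from_labels()] then [fit_em()]; the result is a
#' classifier usable with [predict()] and the robustness harness.
#'
#' @inheritParams init_from_labels
#' @inheritParams fit_em
#' @return Object of class `thz_gmm` with fields `params`,
#'   `responsibilities`, `report`.
#' @export
train_gmm <- function(X, labels, max_iter = 100, tol = 1e-8, ridge = NULL,
                      hard_em = FALSE) {
  init <- init_from_labels(X, labels, ridge = ridge)
  fit <- fit_em(X, init, max_iter = max_iter, tol = tol, ridge = ridge,
                hard_em = hard_em)
  structure(fit, class = "thz_gmm")
}

#' @export
predict.thz_gmm <- function(object, newdata, ...) {
  gmm_classify(as.matrix(newdata), object$params)$labels
}

#' @export
print.thz_gmm <- function(x, ...) {
  cat("GMM classifier\n")
  print(x$params)
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n",
              tail(x$report$loglik_trajectory, 1), x$report$n_iterations,
              if (x$report$converged) " (converged)" else ""))
  invisible(x)
}
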