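#' Column-center a feature matrix
#'
#' @param X Numeric matrix, p samples x q features, p >= 2, no missing values.
#' @return List with `Xc` (centered matrix) and `mean` (length-q vector, kept
#'   for projecting new samples).
#' @export
pca_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("insufficient data: need at least 2 samples", call. = FALSE)
  if (anyNA(X)) stop("missing values are not supported", call. = FALSE)
  mu <- colMeans(X)
  list(Xc = sweep(X, 2, mu), mean = mu)
}

#' Population covariance of a centered matrix
#'
#' Uses the population normalization `M = (1/p) t(Xc) %*% Xc` (divide by the
#' number of samples p, not p - 1).
#'
#' @param Xc Centered numeric matrix.
#' @return Symmetric q x q covariance matrix.
#' @export
pca_covariance <- function(Xc) {
  Xc <- as.matrix(Xc)
  crossprod(Xc) / nrow(Xc)
}

#' Eigendecomposition with a deterministic sign convention
#'
#' Eigenvalues are returned in descending order; each eigenvector is flipped
#' so that its largest-magnitude entry is positive, removing the sign
#' arbitrariness of eigenvectors.
#'
#' @param M Symmetric matrix.
#' @param tol Asymmetry tolerance.
#' @return List with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
pca_eig <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop("invalid input: matrix is not symmetric", call. = FALSE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V)
}

#' Explained-variance ratios
#'
#' @param eigenvalues Non-negative eigenvalues (any order).
#' @return Ratios in descending order summing to 1.
#' @export
explained_variance <- function(eigenvalues) {
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative", call. = FALSE)
  s <- sum(eigenvalues)
  if (s <= 0) stop("degenerate data: all eigenvalues are zero", call. = FALSE)
  sort(pmax(eigenvalues, 0), decreasing = TRUE) / s
}

#' Fit a PCA model
#'
#' Zero-mean the data, form the population covariance (1/p), eigendecompose,
#' and retain the top `q0` components.
#'
#' @param X Numeric matrix, p samples x q features.
#' @param q0 Number of components to retain (default all).
#' @return An object of class `thz_pca`: list with `mean`, `components`
#'   (q x q0, orthonormal columns), `eigenvalues` (length q, descending),
#'   `explained_ratio`, `q0`.
#' @export
pca_fit <- function(X, q0 = ncol(X)) {
  cen <- pca_center(X)
  M <- pca_covariance(cen$Xc)
  e <- pca_eig(M)
  q <- ncol(M)
  q0 <- as.integer(q0)
  if (q0 < 1 || q0 > q) stop("'q0' must be between 1 and the feature count", call. = FALSE)
  structure(list(mean = cen$mean,
                 components = e$vectors[, seq_len(q0), drop = FALSE],
                 eigenvalues = e$values,
                 explained_ratio = explained_variance(e$values),
                 q0 = q0),
            class = "thz_pca")
}

#' Project samples onto a fitted PCA basis
#'
#' Centers `X` with the training mean stored in the model and projects onto
#' the retained components: `Y = Xc %*% P`.
#'
#' @param model A [pca_fit()] result.
#' @param X Numeric matrix with the same feature count as the training data.
#' @return Score matrix p x q0.
#' @export
pca_project <- function(model, X) {
  stopifnot(inherits(model, "thz_pca"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("shape error: feature count does not match the fitted model", call. = FALSE)
  Xc <- sweep(X, 2, model$mean)
  Y <- Xc %*% model$components
  colnames(Y) <- paste0("PC", seq_len(ncol(Y)))
  Y
}

#' @export
print.thz_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d features, %d retained component(s)\n",
              length(x$mean), x$q0))
  cat("Explained variance (%):",
      paste(sprintf("%.2f", 100 * x$explained_ratio), collapse = ", "), "\n")
  invisible(x)
}
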