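#' Train a Gaussian-kernel SVM comparator
#'
#' Soft-margin support vector machine with the Gaussian kernel
#' \eqn{k(x, y) = \exp(-\|x - y\|^2 / (2 \cdot \mathrm{scale}^2))}, the
#' discriminative comparator whose decision boundary shifts with the kernel
#' scale. Training is delegated to [kernlab::ksvm()] (C-SVC), with the kernel
#' scale exposed as the sensitivity knob.
#'
#' @param X Feature matrix, one sample per row.
#' @param labels Two-class label per row.
#' @param kernel_scale Positive kernel scale (bandwidth).
#' @param cost Box constraint C of the soft margin.
#' @return Object of class `thz_svm`.
#' @export
train_svm_rbf <- function(X, labels, kernel_scale = 1, cost = 10) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(labels) != 2) stop("SVM comparator requires exactly two classes", call. = FALSE)
  if (!is.numeric(kernel_scale) || kernel_scale <= 0)
    stop("'kernel_scale' must be positive", call. = FALSE)
  fit <- kernlab::ksvm(X, labels, type = "C-svc",
                       kernel = "rbfdot",
                       kpar = list(sigma = 1 / (2 * kernel_scale^2)),
                       C = cost, scaled = FALSE)
  structure(list(fit = fit, levels = levels(labels),
                 kernel_scale = kernel_scale, cost = cost),
            class = "thz_svm")
}

#' @export
predict.thz_svm <- function(object, newdata, ...) {
  p <- kernlab::predict(object$fit, as.matrix(newdata))
  factor(as.character(p), levels = object$levels)
}

#' @export
print.thz_svm <- function(x, ...) {
  cat(sprintf("Gaussian-kernel SVM: kernel scale %.3g, cost %.3g\n",
              x$kernel_scale, x$cost))
  invisible(x)
}
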