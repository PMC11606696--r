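# Plain-text interchange: traces as two-column delimited files, feature
# tables as CSV with a frequency header, mixture models as JSON.

#' Write / read a time-domain trace
#'
#' Two-column whitespace-delimited text: `time_ps`, `field`.
#'
#' @param trace A [thz_trace()].
#' @param path File path.
#' @return `read_trace` returns a [thz_trace()]; `write_trace` returns the
#'   path invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thz_trace"))
  utils::write.table(data.frame(time_ps = trace$time, field = trace$field),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  thz_trace(d[[1]], d[[2]])
}

#' Write / read a feature table
#'
#' CSV with one row per sample; feature columns are named by frequency, plus
#' an optional `label` column.
#'
#' @param X Feature matrix.
#' @param labels Optional label per row.
#' @param path File path.
#' @return `read_feature_table` returns a list with `features` and `labels`
#'   (or `NULL`).
#' @export
write_feature_table <- function(X, path, labels = NULL) {
  d <- as.data.frame(X)
  if (!is.null(labels)) d$label <- as.character(labels)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(d)) {
    labels <- factor(d$label, levels = unique(d$label))
    d$label <- NULL
  }
  list(features = as.matrix(d), labels = labels)
}

#' Persist / load a fitted mixture model as JSON
#'
#' @param model A `thz_gmm` or [gmm_params()] object.
#' @param path File path.
#' @return `load_gmm` returns a [gmm_params()].
#' @export
save_gmm <- function(model, path) {
  params <- if (inherits(model, "thz_gmm")) model$params else model
  stopifnot(inherits(params, "gmm_params"))
  obj <- list(K = params$K, m = params$m, weights = params$weights,
              means = params$means,
              covariances = lapply(params$covariances, identity),
              component_labels = params$component_labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gmm
#' @export
load_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- if (is.array(obj$covariances) && length(dim(obj$covariances)) == 3) {
    lapply(seq_len(dim(obj$covariances)[1]), function(k)
      matrix(obj$covariances[k, , ], obj$m, obj$m))
  } else {
    lapply(obj$covariances, function(S) matrix(unlist(S), obj$m, obj$m))
  }
  gmm_params(weights = obj$weights,
             means = matrix(unlist(obj$means), obj$K, obj$m),
             covariances = covs,
             component_labels = obj$component_labels)
}
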