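#' Build the two-element linear-combination dataset
#'
#' Under the Beer-Lambert law the spectrum of a blend of two powders is the
#' convex combination of the parents' spectra, so every within-group pair
#' (i, j) and mixing weight alpha yields a physically plausible pseudo-sample
#' `alpha * x_i + (1 - alpha) * x_j` whose expected label is the parents'
#' shared group. Combinations are emitted in deterministic order: group, then
#' pair (lexicographic), then alpha ascending. Cross-group pairs are excluded
#' (their label is undefined).
#'
#' @param X Feature matrix, one sample per row.
#' @param labels Group identifier per row.
#' @param weight_grid Mixing weights alpha, all strictly inside (0, 1).
#' @return Object of class `thz_combinations`: list with `features` (matrix),
#'   `weights` (two-column matrix `alpha`, `1 - alpha`), `parents` (two-column
#'   matrix of row indices), `group` (factor), `weight_grid`.
#' @export
build_linear_combinations <- function(X, labels, weight_grid = 0.5) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  stopifnot(nrow(X) == length(labels))
  if (any(weight_grid <= 0 | weight_grid >= 1))
    stop("mixing weights must lie strictly inside (0, 1)", call. = FALSE)
  weight_grid <- sort(weight_grid)

  feats <- list(); wts <- list(); pars <- list(); grp <- list()
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 2) {
      warning(sprintf("group '%s' has fewer than 2 samples: no combinations emitted", g))
      next
    }
    pairs <- combn(idx, 2)              # lexicographic order
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      for (a in weight_grid) {
        feats[[length(feats) + 1L]] <- a * X[i, ] + (1 - a) * X[j, ]
        wts[[length(wts) + 1L]] <- c(a, 1 - a)
        pars[[length(pars) + 1L]] <- c(i, j)
        grp[[length(grp) + 1L]] <- g
      }
    }
  }
  structure(list(features = do.call(rbind, feats),
                 weights = do.call(rbind, wts),
                 parents = do.call(rbind, pars),
                 group = factor(unlist(grp), levels = levels(labels)),
                 weight_grid = weight_grid),
            class = "thz_combinations")
}

#' @export
print.thz_combinations <- function(x, ...) {
  cat(sprintf("Linear-combination dataset: %d rows (%d weight(s))\n",
              if (is.null(x$features)) 0L else nrow(x$features),
              length(x$weight_grid)))
  if (!is.null(x$group)) print(table(x$group))
  invisible(x)
}

#' Score a classifier on the combination dataset
#'
#' A combination counts as correct when the predicted label equals the
#' parents' shared group.
#'
#' @param model A trained classifier with a [predict()] method returning
#'   labels (e.g. `thz_gmm`, `thz_tree`, `thz_svm`).
#' @param data A [build_linear_combinations()] result.
#' @param model_name Identifier recorded in the result.
#' @return Object of class `comparator_result`: list with `model_name`,
#'   `per_group_accuracy` (named), `overall_accuracy`, `n_per_group`,
#'   `config`.
#' @export
evaluate_on_combinations <- function(model, data, model_name = class(model)[1]) {
  stopifnot(inherits(data, "thz_combinations"))
  pred <- predict(model, data$features)
  if (length(pred) != nrow(data$features))
    stop("shape error: prediction length does not match the combination count", call. = FALSE)
  correct <- as.character(pred) == as.character(data$group)
  per_group <- tapply(correct, data$group, mean)
  structure(list(model_name = model_name,
                 per_group_accuracy = per_group,
                 overall_accuracy = mean(correct),
                 n_per_group = as.integer(table(data$group)),
                 config = list(weight_grid = data$weight_grid)),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s: overall accuracy %.4f\n", x$model_name, x$overall_accuracy))
  for (g in names(x$per_group_accuracy))
    cat(sprintf("  %s: %.4f\n", g, x$per_group_accuracy[[g]]))
  invisible(x)
}

#' Compare classifiers on linear combinations of the training spectra
#'
#' Builds the within-group combination dataset for each mixing weight and
#' scores every supplied model on it, producing the generative-versus-
#' discriminative comparison table. The GMM (if present) is reported first,
#' and its posterior responsibilities over the combinations are attached.
#'
#' @param models Named list of trained classifiers; all must have been
#'   trained on `(X, labels)`.
#' @param X Training feature matrix.
#' @param labels Training labels.
#' @param weight_grid Mixing weights alpha.
#' @return Object of class `robustness_report`: list with `table` (data frame
#'   with columns `model`, `alpha`, per-group accuracies, `overall`),
#'   `gamma` (GMM responsibilities per combination, or `NULL`), and
#'   `combinations` (the alpha = full-grid dataset).
#' @export
run_robustness_report <- function(models, X, labels, weight_grid = 0.5) {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, function(m) class(m)[1], "")
  # GMM first in the report
  ord <- order(!vapply(models, inherits, TRUE, "thz_gmm"))
  models <- models[ord]

  rows <- list()
  gamma <- NULL
  full <- build_linear_combinations(X, labels, weight_grid)
  for (a in sort(weight_grid)) {
    combos <- build_linear_combinations(X, labels, a)
    for (nm in names(models)) {
      res <- evaluate_on_combinations(models[[nm]], combos, model_name = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, alpha = a,
        t(setNames(as.numeric(res$per_group_accuracy),
                   paste0("accuracy_", names(res$per_group_accuracy)))),
        overall = res$overall_accuracy)
    }
  }
  gmm_idx <- which(vapply(models, inherits, TRUE, "thz_gmm"))
  if (length(gmm_idx)) {
    gamma <- gmm_classify(full$features, models[[gmm_idx[1]]]$params)$responsibilities
  }
  structure(list(table = do.call(rbind, rows), gamma = gamma,
                 combinations = full),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Robustness on two-element linear combinations\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
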