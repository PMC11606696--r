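#' Statistical specification of one sample group
#'
#' Parameterizes the distribution of extinction-coefficient features for one
#' quality group. Feature vectors are drawn from a multivariate normal whose
#' mean rises linearly with frequency,
#' `mu(f) = kappa_intercept + kappa_slope * (f - f0) + group_offset`,
#' and whose variance also grows linearly,
#' `var(f) = var_intercept + var_slope * (f - f0)`, with `f0` the lowest
#' selected frequency (0.6 THz by default). Disturbances are equicorrelated
#' across frequencies with correlation `cross_correlation` (compound
#' symmetry): a dominant shared baseline shift per tablet - the combined
#' effect of content-matrix fluctuation and measurement drift on the whole
#' band - plus independent per-frequency noise.
#'
#' @param label Group identifier, e.g. `"qualified"`.
#' @param n_samples Number of samples to draw (>= 1).
#' @param kappa_intercept Mean extinction at the lowest selected frequency.
#' @param kappa_slope Mean extinction increase per THz.
#' @param group_offset Additive extinction shift for this group.
#' @param var_intercept Variance at the lowest selected frequency (> 0).
#' @param var_slope Variance increase per THz.
#' @param cross_correlation Adjacent-frequency disturbance correlation in
#'   `[0, 1)`.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n_samples = 15,
                       kappa_intercept = 0.10, kappa_slope = 0.10,
                       group_offset = 0,
                       var_intercept = 1e-4, var_slope = 2e-4,
                       cross_correlation = 0.93) {
  if (n_samples < 0) stop("'n_samples' must be non-negative", call. = FALSE)
  if (cross_correlation < 0 || cross_correlation >= 1)
    stop("'cross_correlation' must lie in [0, 1)", call. = FALSE)
  structure(list(label = as.character(label), n_samples = as.integer(n_samples),
                 kappa_intercept = kappa_intercept, kappa_slope = kappa_slope,
                 group_offset = group_offset,
                 var_intercept = var_intercept, var_slope = var_slope,
                 cross_correlation = cross_correlation),
            class = "group_spec")
}

#' Default group pair for the two-class study design
#'
#' Fifteen qualified and fifteen unqualified samples. The qualified group
#' (higher active-compound content) absorbs more throughout 0.6-1.2 THz, and
#' increasingly so toward the high-frequency edge (a steeper extinction
#' slope). The mean shift at any single frequency is at most about two
#' per-frequency standard deviations while most of the disturbance is a
#' shared baseline shift, so the two groups overlap at every single frequency
#' yet are jointly separable through the correlation structure.
#'
#' @return Named list with elements `qualified` and `unqualified`.
#' @export
default_group_specs <- function() {
  list(
    qualified   = group_spec("qualified", n_samples = 15,
                             kappa_slope = 0.155, group_offset = 0.005),
    unqualified = group_spec("unqualified", n_samples = 15, group_offset = 0)
  )
}

# mean and covariance implied by a group_spec on a frequency grid
group_moments <- function(spec, frequencies) {
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("'frequencies' must be strictly increasing", call. = FALSE)
  f0 <- frequencies[1]
  mu <- spec$kappa_intercept + spec$kappa_slope * (frequencies - f0) +
    spec$group_offset
  v <- spec$var_intercept + spec$var_slope * (frequencies - f0)
  if (any(v <= 0))
    stop("invalid parameter: variance must be positive at every selected frequency",
         call. = FALSE)
  q <- length(frequencies)
  R <- matrix(spec$cross_correlation, q, q)
  diag(R) <- 1
  Sigma <- sqrt(v) %o% sqrt(v) * R
  ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("invalid parameter: implied covariance is not positive definite",
         call. = FALSE)
  list(mu = mu, Sigma = Sigma)
}

#' Draw group feature vectors
#'
#' Draws `n_samples` extinction-coefficient feature vectors from the
#' multivariate normal implied by a [group_spec()] on a frequency grid.
#' Reproducible: the same seed yields a bit-identical matrix.
#'
#' @param spec A [group_spec()].
#' @param frequencies Strictly increasing THz grid (default the 7-frequency
#'   grid).
#' @param seed Integer seed.
#' @return Numeric matrix `n_samples x length(frequencies)` with frequency
#'   column names.
#' @export
draw_feature_vectors <- function(spec, frequencies = default_frequencies(),
                                 seed) {
  stopifnot(inherits(spec, "group_spec"))
  mo <- group_moments(spec, frequencies)
  X <- withr::with_seed(seed, draw_mvn(spec$n_samples, mo$mu, mo$Sigma))
  colnames(X) <- format(frequencies)
  X
}

# n draws from N(mu, Sigma); returns a matrix even for n in {0, 1}
draw_mvn <- function(n, mu, Sigma) {
  if (n == 0) return(matrix(numeric(0), 0, length(mu)))
  matrix(MASS::mvrnorm(n, mu = mu, Sigma = Sigma), nrow = n)
}

#' Build a labeled synthetic dataset
#'
#' Concatenates draws from the two group specifications (qualified first) into
#' a labeled feature matrix; optionally synthesizes per-sample time-domain
#' trace pairs whose extracted extinction features reproduce the drawn
#' features at the selected frequencies.
#'
#' @param specs Named list of two [group_spec()]s, e.g.
#'   [default_group_specs()]. Order defines the row and label order.
#' @param frequencies THz feature grid.
#' @param seed Integer seed; the `truth` element of the result regenerates the
#'   dataset bit-identically.
#' @param with_traces If `TRUE`, also synthesize `(sample, reference)` trace
#'   pairs per row via [simulate_sample_trace()], using a constant refractive
#'   index and a piecewise-linear extinction curve through the drawn features.
#' @param n_slab Constant refractive index used for trace synthesis.
#' @param d_mm Slab thickness (mm) used for trace synthesis.
#' @param pulse [pulse_model()] for the reference pulse.
#' @return An object of class `thz_dataset`: list with `features` (matrix),
#'   `labels` (factor, level order = group order), `frequencies`, `truth`
#'   (specs + seed), and optionally `traces` (list of lists with `sample`,
#'   `reference`, `d_mm`).
#' @export
build_dataset <- function(specs = default_group_specs(),
                          frequencies = default_frequencies(),
                          seed = 1L, with_traces = FALSE,
                          n_slab = 1.6, d_mm = 1.0,
                          pulse = pulse_model()) {
  stopifnot(length(specs) == 2L)
  labels_order <- vapply(specs, `[[`, "", "label")
  X_all <- withr::with_seed(seed, {
    lapply(specs, function(sp) {
      mo <- group_moments(sp, frequencies)
      draw_mvn(sp$n_samples, mo$mu, mo$Sigma)
    })
  })
  features <- do.call(rbind, X_all)
  colnames(features) <- format(frequencies)
  labels <- factor(rep(labels_order, vapply(specs, `[[`, 1L, "n_samples")),
                   levels = labels_order)

  out <- list(features = features, labels = labels,
              frequencies = frequencies,
              truth = list(specs = specs, seed = seed,
                           frequencies = frequencies))
  if (with_traces) {
    ref <- make_reference_pulse(pulse)
    out$traces <- lapply(seq_len(nrow(features)), function(i) {
      kap <- function(f) approx(frequencies, features[i, ], xout = f, rule = 2)$y
      list(sample = simulate_sample_trace(ref, n_slab, kap, d_mm),
           reference = ref, d_mm = d_mm)
    })
  }
  class(out) <- "thz_dataset"
  out
}

#' @export
print.thz_dataset <- function(x, ...) {
  cat(sprintf("Synthetic THz feature dataset: %d samples x %d frequencies\n",
              nrow(x$features), ncol(x$features)))
  print(table(x$labels))
  invisible(x)
}
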