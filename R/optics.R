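#' Discrete Fourier transform of a time-domain trace
#'
#' Transforms a uniformly sampled trace to a one-sided complex spectrum on a
#' frequency grid in THz. With `window = "none"` and `pad_factor = 1` the
#' underlying transform is exactly invertible, which is what the
#' forward-model round trip relies on.
#'
#' @param trace A [thz_trace()].
#' @param window Taper applied before transforming: `"none"` (default) or
#'   `"hann"`.
#' @param pad_factor Integer >= 1; zero-padding factor refining the frequency
#'   grid.
#' @return An object of class `thz_spectrum`: list with `frequency` (THz,
#'   ascending from 0) and `amplitude` (complex), plus the originating time
#'   step.
#' @export
to_frequency_domain <- function(trace, window = c("none", "hann"),
                                pad_factor = 1L) {
  stopifnot(inherits(trace, "thz_trace"))
  window <- match.arg(window)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L) stop("'pad_factor' must be >= 1", call. = FALSE)

  x <- trace$field
  n0 <- length(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n0) - 1) / (n0 - 1)))
  N <- n0 * pad_factor
  if (N > n0) x <- c(x, numeric(N - n0))

  dt <- trace$time[2] - trace$time[1]
  X <- fft(x)
  idx <- 1:(N %/% 2 + 1)
  structure(list(frequency = onesided_freqs(N, dt),
                 amplitude = X[idx],
                 dt = dt, n_time = n0),
            class = "thz_spectrum")
}

#' Amplitude ratio and phase difference between sample and reference
#'
#' Computes the transfer observables that feed the optical-parameter
#' formulas: the amplitude ratio \eqn{\rho = |S|/|R|} and the unwrapped phase
#' difference \eqn{\phi} of the reference relative to the sample, so that a
#' slab with refractive index above 1 (a delayed pulse) gives positive
#' \eqn{\phi}. Unwrapping removes 2\eqn{\pi} jumps along ascending frequency
#' starting at the low edge of the band; the remaining integer-2\eqn{\pi}
#' branch is fixed by requiring the linear extrapolation of \eqn{\phi(\omega)}
#' to pass through zero at zero frequency.
#'
#' @param sample,reference `thz_spectrum` objects on the same frequency grid.
#' @param band Length-2 numeric, analysis band in THz (default 0.6-1.2).
#' @param min_signal Relative magnitude threshold below which the reference is
#'   considered too weak to divide by.
#' @return An object of class `thz_observables`: data frame with columns
#'   `frequency` (THz), `omega` (rad/s), `rho`, `phi`.
#' @export
transfer_observables <- function(sample, reference, band = c(0.6, 1.2),
                                 min_signal = 1e-8) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"))
  if (length(sample$frequency) != length(reference$frequency) ||
      max(abs(sample$frequency - reference$frequency)) > 1e-9)
    stop("sample and reference spectra must share one frequency grid", call. = FALSE)
  stopifnot(length(band) == 2, band[1] < band[2])
  f <- reference$frequency
  if (band[1] < f[2] || band[2] > f[length(f)])
    stop("analysis band outside the spectral support", call. = FALSE)

  in_band <- f >= band[1] - 1e-12 & f <= band[2] + 1e-12
  R <- reference$amplitude
  weak <- in_band & (Mod(R) < min_signal * max(Mod(R)))
  if (any(weak))
    stop(sprintf("low signal: reference magnitude below threshold at %.3f THz",
                 f[which(weak)[1]]), call. = FALSE)

  # principal-value phase of reference relative to sample, then unwrap
  # within the band, anchored at its low edge
  pv <- Arg(R * Conj(sample$amplitude))
  fb <- f[in_band]
  phi <- signal::unwrap(pv[in_band])
  w <- omega_from_thz(fb)
  # fix the integer-2*pi branch: phi(omega) extrapolates to 0 at omega = 0
  coefs <- stats::coef(stats::lm.fit(cbind(1, w), phi))
  phi <- phi - 2 * pi * round(coefs[1] / (2 * pi))

  rho <- Mod(sample$amplitude[in_band]) / Mod(R[in_band])
  structure(data.frame(frequency = fb, omega = w, rho = rho, phi = phi),
            class = c("thz_observables", "data.frame"))
}

#' Refractive index from the phase difference
#'
#' Implements \eqn{n = \phi c / (\omega d) + 1} elementwise on the analysis
#' band.
#'
#' @param obs A `thz_observables` object.
#' @param d Slab thickness in m.
#' @return Numeric vector of refractive indices, one per band frequency.
#' @export
refractive_index <- function(obs, d) {
  stopifnot(inherits(obs, "thz_observables"))
  if (!is.numeric(d) || d <= 0) stop("thickness 'd' must be positive", call. = FALSE)
  if (any(obs$omega <= 0)) stop("zero angular frequency in band: cannot divide", call. = FALSE)
  obs$phi * .c_light / (obs$omega * d) + 1
}

#' Extinction coefficient from the amplitude ratio
#'
#' Implements \eqn{\kappa = \frac{c}{\omega d}
#' \ln\!\left(\frac{4 n}{\rho (1+n)^2}\right)} elementwise. Negative values
#' are physically suspect (amplification); they are kept but flagged via the
#' `"negative"` attribute.
#'
#' @param obs A `thz_observables` object.
#' @param n Per-frequency refractive index (from [refractive_index()]).
#' @param d Slab thickness in m.
#' @return Numeric vector of extinction coefficients with a logical
#'   `"negative"` attribute marking suspect entries.
#' @export
extinction_coefficient <- function(obs, n, d) {
  stopifnot(inherits(obs, "thz_observables"))
  if (!is.numeric(d) || d <= 0) stop("thickness 'd' must be positive", call. = FALSE)
  if (any(obs$rho <= 0)) stop("invalid input: amplitude ratio must be positive", call. = FALSE)
  if (any(n <= 0)) stop("invalid input: refractive index must be positive", call. = FALSE)
  kappa <- (.c_light / (obs$omega * d)) * log(4 * n / (obs$rho * (1 + n)^2))
  neg <- kappa < 0
  if (any(neg))
    warning(sprintf("%d extinction value(s) are negative (physically suspect)", sum(neg)))
  attr(kappa, "negative") <- neg
  kappa
}

#' Extract optical parameters from a sample/reference trace pair
#'
#' Convenience wrapper chaining [to_frequency_domain()],
#' [transfer_observables()], [refractive_index()] and
#' [extinction_coefficient()].
#'
#' @param sample,reference [thz_trace()] objects on the same time grid.
#' @param d_mm Slab thickness in mm.
#' @param band Analysis band in THz.
#' @return An object of class `optical_parameters`: data frame with columns
#'   `frequency`, `n`, `kappa`; thickness (m) stored as attribute `d`.
#' @export
extract_optical_parameters <- function(sample, reference, d_mm,
                                       band = c(0.6, 1.2)) {
  sp <- to_frequency_domain(sample)
  rf <- to_frequency_domain(reference)
  obs <- transfer_observables(sp, rf, band = band)
  d <- d_mm * 1e-3
  n <- refractive_index(obs, d)
  kappa <- extinction_coefficient(obs, n, d)
  out <- data.frame(frequency = obs$frequency, n = n, kappa = as.numeric(kappa))
  attr(out, "d") <- d
  attr(out, "kappa_negative") <- attr(kappa, "negative")
  class(out) <- c("optical_parameters", "data.frame")
  out
}

#' Sample extinction features at selected frequencies
#'
#' Interpolates the extracted extinction-coefficient curve onto the requested
#' frequencies (by default the seven-frequency grid 0.6-1.2 THz). When a
#' requested frequency coincides with a grid point the stored value is
#' returned unchanged.
#'
#' @param params An `optical_parameters` object.
#' @param frequencies Frequencies in THz at which to sample (ascending).
#' @param method `"linear"` interpolation (default) or `"nearest"` grid value.
#' @return Named numeric vector of extinction coefficients (class
#'   `feature_vector`), names are the frequencies.
#' @export
sample_features <- function(params, frequencies = default_frequencies(),
                            method = c("linear", "nearest")) {
  stopifnot(inherits(params, "optical_parameters"))
  method <- match.arg(method)
  fr <- params$frequency
  if (any(frequencies < min(fr) - 1e-9 | frequencies > max(fr) + 1e-9))
    stop("out of band: requested frequency outside the extracted band", call. = FALSE)
  vals <- if (method == "linear") {
    approx(fr, params$kappa, xout = frequencies, rule = 2)$y
  } else {
    params$kappa[vapply(frequencies, function(f) which.min(abs(fr - f)), 1L)]
  }
  structure(setNames(vals, format(frequencies)), class = "feature_vector")
}
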