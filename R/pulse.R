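#' Parameterization of the emitter pulse
#'
#' Describes a single-cycle terahertz pulse (derivative of a Gaussian) used as
#' the reference waveform by the synthetic data generator. The defaults give a
#' 100 ps observation window sampled at 0.05 ps, so the frequency grid has a
#' spacing of exactly 0.01 THz and every default feature frequency falls on a
#' grid point.
#'
#' @param center_time Pulse arrival time (ps).
#' @param width Gaussian width parameter (ps); the amplitude spectrum peaks at
#'   `1/(2*pi*width)` THz.
#' @param amplitude Peak-scale amplitude (arbitrary units).
#' @param sampling_interval Time step of the trace (ps).
#' @param n_points Number of samples in the window (>= 64).
#'
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(center_time = 10, width = 0.25, amplitude = 1,
                        sampling_interval = 0.05, n_points = 2000) {
  if (!is.numeric(width) || width <= 0)
    stop("invalid parameter: 'width' must be positive", call. = FALSE)
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("invalid parameter: 'sampling_interval' must be positive", call. = FALSE)
  if (n_points < 64)
    stop("invalid parameter: 'n_points' must be at least 64", call. = FALSE)
  structure(list(center_time = center_time, width = width,
                 amplitude = amplitude,
                 sampling_interval = sampling_interval,
                 n_points = as.integer(n_points)),
            class = "pulse_model")
}

#' Construct a time-domain trace
#'
#' @param time Uniform time grid (ps).
#' @param field Real field amplitude (arbitrary units).
#' @return An object of class `thz_trace`: a data frame with columns `time`
#'   and `field`.
#' @export
thz_trace <- function(time, field) {
  stopifnot(length(time) == length(field))
  if (length(time) < 64) stop("trace must have at least 64 points", call. = FALSE)
  dt <- diff(time)
  if (any(!is.finite(field)) || any(!is.finite(time)))
    stop("trace contains non-finite values", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("invalid input: time grid must be uniformly sampled", call. = FALSE)
  structure(data.frame(time = time, field = field),
            class = c("thz_trace", "data.frame"))
}

#' Synthesize the reference pulse
#'
#' Generates a single-cycle pulse shaped as the first derivative of a
#' Gaussian, mimicking the reference waveform of a THz-TDS instrument. The
#' pulse integrates to zero (no DC content) and its amplitude spectrum is
#' proportional to `f * exp(-(2*pi*f*width)^2 / 2)`, peaking at
#' `1/(2*pi*width)` THz.
#'
#' @param model A [pulse_model()].
#' @return A [thz_trace()].
#' @export
make_reference_pulse <- function(model) {
  stopifnot(inherits(model, "pulse_model"))
  t <- model$sampling_interval * (seq_len(model$n_points) - 1)
  u <- (t - model$center_time) / model$width
  field <- -model$amplitude * u * exp(-u^2 / 2)
  thz_trace(t, field)
}

# Evaluate a material curve (scalar, per-grid vector, or function of
# frequency in THz) on a one-sided frequency grid.
eval_curve <- function(curve, f_thz, what) {
  v <- if (is.function(curve)) curve(f_thz)
       else if (length(curve) == 1L) rep(curve, length(f_thz))
       else if (length(curve) == length(f_thz)) as.numeric(curve)
       else stop(sprintf("'%s' must be scalar, a function of frequency, or a vector on the FFT grid (length %d)",
                         what, length(f_thz)), call. = FALSE)
  if (any(!is.finite(v))) stop(sprintf("'%s' evaluates to non-finite values", what), call. = FALSE)
  v
}

# One-sided frequency grid (THz) for a trace of n points at dt ps.
onesided_freqs <- function(n, dt) (0:(n %/% 2)) / (n * dt)

#' Forward-simulate a sample trace through a slab
#'
#' Applies the single-pass slab transfer function
#' \deqn{H(\omega) = \frac{4n}{(1+n)^2} e^{-\kappa \omega d / c}
#'       e^{-i (n - 1)\omega d / c}}
#' to the reference spectrum and returns the inverse transform. The phase sign
#' matches the extraction routines ([transfer_observables()] and friends), so
#' forward simulation followed by extraction recovers `n` and `kappa` exactly
#' (up to FFT round-off).
#'
#' @param reference A [thz_trace()] reference pulse.
#' @param n_curve Refractive index: scalar, function of frequency (THz), or
#'   vector on the one-sided FFT grid of `reference`. Must be positive.
#' @param kappa_curve Extinction coefficient, same forms as `n_curve`.
#' @param d Slab thickness in mm.
#' @return A [thz_trace()] of the transmitted pulse on the same time grid.
#' @export
simulate_sample_trace <- function(reference, n_curve, kappa_curve, d) {
  stopifnot(inherits(reference, "thz_trace"))
  if (!is.numeric(d) || d <= 0) stop("thickness 'd' must be positive", call. = FALSE)
  N <- nrow(reference)
  dt <- reference$time[2] - reference$time[1]
  f <- onesided_freqs(N, dt)
  n <- eval_curve(n_curve, f, "n_curve")
  if (any(n <= 0)) stop("invalid material: refractive index must be positive everywhere", call. = FALSE)
  kappa <- eval_curve(kappa_curve, f, "kappa_curve")

  w <- omega_from_thz(f)
  d_m <- d * 1e-3
  H_pos <- (4 * n / (1 + n)^2) *
    exp(-kappa * w * d_m / .c_light) *
    exp(-1i * (n - 1) * w * d_m / .c_light)

  # assemble a Hermitian two-sided response so the output stays real
  H <- complex(length.out = N)
  half <- N %/% 2
  H[1:(half + 1)] <- H_pos
  if (N %% 2 == 0) H[half + 1] <- Re(H_pos[half + 1])  # Nyquist bin real
  if (N > half + 1) H[(half + 2):N] <- Conj(H_pos[seq(half + (N %% 2), 2)])

  S <- fft(reference$field) * H
  out <- Re(fft(S, inverse = TRUE)) / N
  thz_trace(reference$time, out)
}
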