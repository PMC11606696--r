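test_that("transform locates a pure sinusoid and satisfies Parseval", {
  t <- 0.05 * (0:1999)
  x <- sin(2 * pi * 0.8 * t)
  sp <- to_frequency_domain(thz_trace(t, x))
  expect_equal(sp$frequency[which.max(Mod(sp$amplitude))], 0.8, tolerance = 1e-9)

  # Parseval with no window and no padding (one-sided spectrum, double the
  # interior bins)
  w <- rep(2, length(sp$amplitude)); w[1] <- 1
  if (length(t) %% 2 == 0) w[length(w)] <- 1
  expect_equal(sum(x^2), sum(w * Mod(sp$amplitude)^2) / length(x),
               tolerance = 1e-10)
})

test_that("a delayed trace shows the shift-theorem phase slope", {
  pm <- pulse_model()
  tr <- make_reference_pulse(pm)
  dt_steps <- 30
  delayed <- thz_trace(tr$time, c(numeric(dt_steps),
                                  head(tr$field, -dt_steps)))
  obs <- transfer_observables(to_frequency_domain(delayed),
                              to_frequency_domain(tr))
  delay_s <- dt_steps * 0.05 * 1e-12
  expect_equal(obs$phi, obs$omega * delay_s, tolerance = 1e-6)
})

test_that("identity and pure scaling give trivial observables", {
  sp <- to_frequency_domain(make_reference_pulse(pulse_model()))
  obs <- transfer_observables(sp, sp)
  expect_equal(obs$rho, rep(1, nrow(obs)))
  expect_equal(obs$phi, rep(0, nrow(obs)))

  half <- sp; half$amplitude <- 0.5 * sp$amplitude
  obs2 <- transfer_observables(half, sp)
  expect_equal(obs2$rho, rep(0.5, nrow(obs2)))
  expect_equal(obs2$phi, rep(0, nrow(obs2)))
})

test_that("weak reference signal inside the band is reported with its frequency", {
  # wide pulse centered mid-window: band-limited far below 0.6 THz
  tr <- make_reference_pulse(pulse_model(width = 3, center_time = 50))
  sp <- to_frequency_domain(tr)
  expect_error(transfer_observables(sp, sp, band = c(0.6, 1.2)), "low signal")
})

test_that("optical-parameter formulas reduce correctly in closed-form cases", {
  obs <- structure(data.frame(frequency = c(0.8, 1.0),
                              omega = omega <- 2 * pi * c(0.8, 1.0) * 1e12,
                              rho = c(1, 1), phi = c(0, 0)),
                   class = c("thz_observables", "data.frame"))
  d <- 1e-3
  expect_equal(refractive_index(obs, d), c(1, 1))

  obs$phi <- obs$omega * d / 299792458
  expect_equal(refractive_index(obs, d), c(2, 2))

  # rho = 4n/(1+n)^2 gives kappa = 0 for any n
  n <- c(1.7, 2.3)
  obs$rho <- 4 * n / (1 + n)^2
  expect_equal(as.numeric(extinction_coefficient(obs, n, d)), c(0, 0))
  # n = 1, rho = 1: lossless vacuum slab
  obs$rho <- c(1, 1)
  expect_equal(as.numeric(extinction_coefficient(obs, c(1, 1), d)), c(0, 0))

  obs$rho <- c(2, 2)  # amplification: physically suspect
  expect_warning(k <- extinction_coefficient(obs, c(1, 1), d), "suspect")
  expect_true(all(attr(k, "negative")))
})

test_that("forward model then extraction recovers n and kappa on the band", {
  ref <- make_reference_pulse(pulse_model())
  for (case in list(list(n = 1.6, k0 = 0.05, k1 = 0.0, d = 1),
                    list(n = 2.1, k0 = 0.02, k1 = 0.15, d = 0.7),
                    list(n = 1.3, k0 = 0.10, k1 = 0.08, d = 1.8))) {
    kap <- function(f) case$k0 + case$k1 * f
    samp <- simulate_sample_trace(ref, case$n, kap, d = case$d)
    op <- extract_optical_parameters(samp, ref, d_mm = case$d)
    expect_lt(max(abs(op$n - case$n)), 1e-6)
    expect_lt(max(abs(op$kappa - kap(op$frequency))), 1e-6)
  }
})

test_that("increasing extinction at one frequency strictly decreases the amplitude ratio there", {
  ref <- make_reference_pulse(pulse_model())
  sp_ref <- to_frequency_domain(ref)
  f_grid <- sp_ref$frequency
  kap1 <- rep(0.05, length(f_grid))
  kap2 <- kap1
  target <- which.min(abs(f_grid - 0.9))
  kap2[target] <- 0.08
  s1 <- to_frequency_domain(simulate_sample_trace(ref, 1.6, kap1, 1))
  s2 <- to_frequency_domain(simulate_sample_trace(ref, 1.6, kap2, 1))
  r1 <- Mod(s1$amplitude[target]) / Mod(sp_ref$amplitude[target])
  r2 <- Mod(s2$amplitude[target]) / Mod(sp_ref$amplitude[target])
  expect_lt(r2, r1)
})

test_that("feature sampling interpolates exactly and respects the band", {
  op <- structure(data.frame(frequency = seq(0.5, 1.3, 0.05),
                             n = 1.6, kappa = 0.02 + 0.1 * seq(0.5, 1.3, 0.05)),
                  class = c("optical_parameters", "data.frame"))
  # linear curve: interpolation at midpoints is exact
  mids <- c(0.625, 0.875, 1.125)
  expect_equal(as.numeric(sample_features(op, mids)), 0.02 + 0.1 * mids)
  # a stored grid frequency comes back unchanged
  expect_equal(as.numeric(sample_features(op, 0.8)), op$kappa[op$frequency == 0.8])
  # default list: length 7, ordered 0.6 -> 1.2
  fv <- sample_features(op)
  expect_length(fv, 7)
  expect_equal(as.numeric(names(fv)), seq(0.6, 1.2, 0.1))
  expect_error(sample_features(op, 1.5), "out of band")
  # nearest-grid alternative returns stored values
  expect_equal(as.numeric(sample_features(op, 0.81, method = "nearest")),
               op$kappa[op$frequency == 0.8])
})
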