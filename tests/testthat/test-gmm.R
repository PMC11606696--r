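test_that("multivariate normal density matches closed forms and a whitening oracle", {
  expect_equal(mvn_pdf(0, 0, matrix(1)), 1 / sqrt(2 * pi), tolerance = 1e-7)
  expect_equal(mvn_pdf(c(1, 2), c(1, 2), diag(2)), 1 / (2 * pi), tolerance = 1e-10)

  withr::with_seed(10, {
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
    mu <- rnorm(3)
    for (i in 1:5) {
      x <- rnorm(3, mu)
      # whiten by the Cholesky factor: density is the product of independent
      # standard normals divided by the Jacobian |R|
      R <- chol(S)
      z <- backsolve(R, x - mu, transpose = TRUE)
      oracle <- prod(dnorm(z)) / prod(diag(R))
      expect_equal(mvn_pdf(x, mu, S), oracle, tolerance = 1e-10)
    }
  })
  expect_error(mvn_pdf(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("label initialization reproduces group statistics with first-appearance order", {
  d <- tiny_labeled(15, 15, m = 3)
  init <- init_from_labels(d$X, d$labels)
  expect_equal(init$weights, c(0.5, 0.5))
  expect_equal(init$component_labels, c("a", "b"))
  for (k in 1:2) {
    Xk <- d$X[d$labels == c("a", "b")[k], ]
    expect_equal(init$means[k, ], colMeans(Xk), tolerance = 1e-12)
    S <- crossprod(sweep(Xk, 2, colMeans(Xk))) / nrow(Xk)
    expect_equal(init$covariances[[k]], S + diag(1e-8 * mean(diag(S)), 3),
                 tolerance = 1e-12)
  }

  # duplicated identical samples: ridge keeps the covariance positive definite
  Xdup <- rbind(matrix(1, 3, 2), matrix(c(0, 5), 3, 2, byrow = TRUE))
  lab <- rep(c("a", "b"), each = 3)
  init2 <- init_from_labels(Xdup, lab, ridge = 1e-6)
  expect_equal(init2$covariances[[1]], diag(1e-6, 2))

  expect_error(init_from_labels(d$X, rep("a", 30)), "degenerate")
  expect_error(init_from_labels(d$X, c("b", rep("a", 29))), "insufficient")
})

test_that("responsibilities normalize and respect symmetry", {
  d <- tiny_labeled(6, 6, m = 2)
  p1 <- gmm_params(1, matrix(0, 1, 2), list(diag(2)))
  expect_equal(e_step(d$X, p1), matrix(1, 12, 1))

  # two identical components share responsibility equally
  p2 <- gmm_params(c(0.5, 0.5), matrix(0, 2, 2), list(diag(2), diag(2)))
  expect_equal(e_step(d$X, p2), matrix(0.5, 12, 2))

  # midpoint of the means with shared covariance and equal weights: gamma = 1/2
  mu1 <- c(0, 1); mu2 <- c(3, -2)
  p3 <- gmm_params(c(0.5, 0.5), rbind(mu1, mu2),
                   list(diag(c(1, 2)), diag(c(1, 2))))
  g <- e_step(matrix((mu1 + mu2) / 2, 1), p3)
  expect_equal(as.numeric(g), c(0.5, 0.5), tolerance = 1e-9)

  # extreme outliers never produce NaN rows (log-domain stability)
  gfar <- e_step(matrix(c(1e4, -1e4), 1), p3)
  expect_equal(sum(gfar), 1, tolerance = 1e-12)
})

test_that("M step reduces to closed forms and matches a direct-summation oracle", {
  d <- tiny_labeled(5, 4, m = 2)
  n <- nrow(d$X)
  # K = 1: sample mean and population covariance
  p <- m_step(d$X, matrix(1, n, 1), ridge = 0)
  expect_equal(p$weights, 1)
  expect_equal(p$means[1, ], colMeans(d$X), tolerance = 1e-12)
  expect_equal(p$covariances[[1]],
               crossprod(sweep(d$X, 2, colMeans(d$X))) / n, tolerance = 1e-12)

  # hard responsibilities: per-group statistics
  gh <- cbind(as.numeric(d$labels == "a"), as.numeric(d$labels == "b"))
  ph <- m_step(d$X, gh, ridge = 0)
  for (k in 1:2) {
    Xk <- d$X[d$labels == c("a", "b")[k], ]
    expect_equal(ph$means[k, ], colMeans(Xk), tolerance = 1e-12)
  }

  # random soft responsibilities against brute-force weighted sums
  withr::with_seed(20, {
    g <- matrix(runif(12), 6, 2); g <- g / rowSums(g)
  })
  X6 <- d$X[1:6, ]
  pr <- m_step(X6, g, ridge = 0)
  for (k in 1:2) {
    Nk <- sum(g[, k])
    mu <- colSums(X6 * g[, k]) / Nk
    S <- matrix(0, 2, 2)
    for (j in 1:6) S <- S + g[j, k] * tcrossprod(X6[j, ] - mu)
    expect_equal(pr$weights[k], Nk / 6, tolerance = 1e-12)
    expect_equal(pr$means[k, ], mu, tolerance = 1e-12)
    expect_equal(pr$covariances[[k]], S / Nk, tolerance = 1e-12)
  }

  # component collapse is named
  expect_error(m_step(X6, cbind(rep(1, 6), 0), ridge = 0), "component 2 collapsed")
})

test_that("log-likelihood matches closed forms and a naive oracle", {
  m <- 3
  p1 <- gmm_params(1, matrix(0, 1, m), list(diag(m)))
  expect_equal(log_likelihood(matrix(0, 1, m), p1), -(m / 2) * log(2 * pi),
               tolerance = 1e-12)

  d <- tiny_labeled(4, 4, m = 2)
  init <- init_from_labels(d$X, d$labels)
  ll1 <- log_likelihood(d$X, init)
  ll2 <- log_likelihood(rbind(d$X, d$X), init)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
  expect_equal(ll1, naive_loglik(d$X, init), tolerance = 1e-9)
})

test_that("EM is a no-op at a one-component stationary point", {
  d <- tiny_labeled(10, 0, m = 2)
  X <- d$X[1:10, ]
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / 10
  init <- gmm_params(1, matrix(mu, 1), list(S + diag(1e-8 * mean(diag(S)), 2)))
  fit <- fit_em(X, init, max_iter = 50)
  expect_true(fit$report$converged)
  expect_lte(fit$report$n_iterations, 2)
  expect_equal(fit$params$means[1, ], mu, tolerance = 1e-10)
  expect_equal(fit$params$covariances[[1]], init$covariances[[1]], tolerance = 1e-10)
})

test_that("EM increases the log-likelihood monotonically and converges quickly when separated", {
  ds <- build_dataset(seed = 21)
  fit <- train_gmm(ds$features, ds$labels, max_iter = 10)
  traj <- fit$report$loglik_trajectory
  expect_true(all(diff(traj) >= -1e-9))
  expect_lte(fit$report$n_iterations, 10)
  dev <- max(pmin(fit$responsibilities, 1 - fit$responsibilities))
  expect_lt(dev, 1e-3)
  # every gamma row sums to one
  expect_lt(max(abs(rowSums(fit$responsibilities) - 1)), 1e-12)
})

test_that("hard EM reproduces per-group statistics on separated data", {
  d <- tiny_labeled(10, 10, m = 2, sep = 8)
  fit <- train_gmm(d$X, d$labels, hard_em = TRUE, ridge = 0)
  for (k in 1:2) {
    Xk <- d$X[d$labels == c("a", "b")[k], ]
    expect_equal(fit$params$means[k, ], colMeans(Xk), tolerance = 1e-8)
  }
})

test_that("classification takes the argmax with ties to the lower component", {
  p <- gmm_params(c(0.5, 0.5), rbind(c(0, 0), c(4, 4)),
                  list(diag(2), diag(2)), component_labels = c("q", "u"))
  cls <- gmm_classify(rbind(c(0.1, 0), c(4, 4.2), c(2, 2)), p)
  expect_equal(as.character(cls$labels), c("q", "u", "q"))  # midpoint tie -> q
  expect_equal(cls$responsibilities[3, ], c(q = 0.5, u = 0.5), tolerance = 1e-9)
})

test_that("a fitted mixture survives a JSON round trip", {
  ds <- build_dataset(seed = 22)
  fit <- train_gmm(ds$features, ds$labels)
  path <- withr::local_tempfile(fileext = ".json")
  save_gmm(fit, path)
  back <- load_gmm(path)
  expect_equal(back$weights, fit$params$weights)
  expect_equal(back$means, fit$params$means, ignore_attr = TRUE)
  for (k in 1:2)
    expect_equal(back$covariances[[k]], fit$params$covariances[[k]],
                 ignore_attr = TRUE)
  expect_equal(back$component_labels, fit$params$component_labels)
})
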