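test_that("class moments: unbiased covariance, weights, exchangeability", {
  m <- fit_class(matrix(c(0, 2), ncol = 1))
  expect_equal(m$mean, 1)
  expect_equal(m$cov[1, 1], 2)  # unbiased (n - 1 denominator)
  expect_equal(m$n, 2)

  same <- fit_class(matrix(1, 4, 3))
  expect_equal(same$cov, matrix(0, 3, 3))

  mw <- fit_class(matrix(c(0, 2), ncol = 1), weights = c(1, 0))
  expect_equal(mw$mean, 0)

  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  p <- sample(10)
  a <- fit_class(x); b <- fit_class(x[p, ])
  expect_equal(a$mean, b$mean)
  expect_equal(a$cov, b$cov)

  expect_error(fit_class(matrix(1, 1, 2), weights = c(0)), "weights")
})

test_that("shrinkage interpolates to the mean-eigenvalue identity", {
  cv <- diag(c(2, 4))
  expect_equal(shrink_cov(cv, 0), cv)
  expect_equal(shrink_cov(cv, 1), diag(c(3, 3)))
  expect_equal(shrink_cov(cv, 0.5), diag(c(2.5, 3.5)))
  set.seed(2)
  A <- crossprod(matrix(rnorm(25), 5, 5))
  s <- shrink_cov(A, 0.7)
  expect_equal(sum(diag(s)), sum(diag(A)))  # trace preserved
  expect_true(min(eigen(s, symmetric = TRUE)$values) > 0)
})

test_that("class posterior follows Bayes rule with shrunk Gaussians", {
  # symmetric point, equal covariances and priors
  mc <- fit_class(matrix(rep(c(-1, 1), 5), ncol = 1) - 2)
  mw <- fit_class(matrix(rep(c(-1, 1), 5), ncol = 1) + 2)
  p <- class_posterior(0, mc, mw, decoder_params(lambda = 0))
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(p), 1)

  # 1-D closed form: unit variances, mu_c = 0, mu_w = 2, e = 0:
  # log-odds = (mu_w - mu_c) (e - (mu_c + mu_w)/2) / sigma^2 = 2
  mc1 <- list(mean = 0, cov = matrix(1), n = 100)
  mw1 <- list(mean = 2, cov = matrix(1), n = 100)
  p1 <- class_posterior(0, mc1, mw1, decoder_params(lambda = 0))
  expect_equal(unname(p1[1]), stats::plogis(2), tolerance = 1e-12)

  # well-separated classes: e at mu_c is classified with near certainty
  set.seed(3)
  xc <- matrix(rnorm(200, -5), ncol = 2)
  xw <- matrix(rnorm(200, 5), ncol = 2)
  p2 <- class_posterior(colMeans(xc), fit_class(xc), fit_class(xw))
  expect_gt(p2[1], 0.99)
})

test_that("t predictive matches the univariate Student-t closed form", {
  set.seed(4)
  x <- matrix(rnorm(8), ncol = 1)
  m <- fit_class(x)
  n <- 8; mu <- mean(x); s2 <- stats::var(as.numeric(x))
  sc <- sqrt(s2 * (n + 1) / n)  # = Lambda (n+1) / (n (n-1)) with Lambda the scatter
  for (e in c(-1.2, 0.3, 2.5)) {
    ref <- stats::dt((e - mu) / sc, df = n - 1, log = TRUE) - log(sc)
    expect_equal(t_predictive_logdensity(e, m), ref, tolerance = 1e-10)
  }
})

test_that("t predictive equals the numerical Jeffreys-prior marginalization", {
  x <- c(-0.3, 0.5, 1.1)
  m <- fit_class(matrix(x, ncol = 1))
  # marginalize mu analytically (Gaussian product identity), sigma^2 by
  # quadrature over log sigma^2 under the prior 1/sigma^2
  mu_marg <- function(xx, s2) {
    N <- length(xx); SS <- sum((xx - mean(xx))^2)
    (2 * pi * s2)^(-(N - 1) / 2) * N^(-1 / 2) * exp(-SS / (2 * s2))
  }
  f <- function(u, xx) vapply(u, function(ui) mu_marg(xx, exp(ui)), numeric(1))
  den <- stats::integrate(f, -25, 25, xx = x, rel.tol = 1e-12)$value
  for (e in c(-0.5, 0.8)) {
    num <- stats::integrate(f, -25, 25, xx = c(x, e), rel.tol = 1e-12)$value
    expect_equal(t_predictive_logdensity(e, m), log(num / den),
                 tolerance = 1e-4)
  }
})

test_that("t predictive peaks at the location and tends to the Gaussian", {
  set.seed(5)
  x <- matrix(rnorm(40), ncol = 2)
  m <- fit_class(x)
  at_mode <- t_predictive_logdensity(m$mean, m)
  for (dirn in list(c(0.1, 0), c(0, -0.1), c(0.07, 0.07)))
    expect_gt(at_mode, t_predictive_logdensity(m$mean + dirn, m))

  n <- 1e5 * 2
  X <- matrix(rnorm(n * 2), n, 2)
  mb <- fit_class(X)
  e <- c(0.5, -0.2)
  gt <- t_predictive_logdensity(e, mb)
  gg <- as.numeric(selfbci:::.gauss_logdens(matrix(e, 1), mb$mean, mb$cov))
  expect_lt(abs((gt - gg) / gg), 1e-3)

  expect_error(t_predictive_logdensity(c(0, 0), fit_class(matrix(rnorm(6), 3, 2))),
               class = "selfbci_insufficient_data")
})

test_that("scaling covariance by c^2 and residual by c shifts the log-density by -d log c", {
  set.seed(6)
  x <- matrix(rnorm(60), ncol = 2)
  m <- fit_class(x)
  e <- m$mean + c(0.4, -0.3)
  m2 <- m
  m2$cov <- m$cov * 9
  m2$mean <- m$mean
  e2 <- m$mean + 3 * c(0.4, -0.3)
  expect_equal(t_predictive_logdensity(e2, m2),
               t_predictive_logdensity(e, m) - 2 * log(3), tolerance = 1e-10)
})

test_that("decoder serialization round-trips", {
  set.seed(7)
  mc <- fit_class(matrix(rnorm(30), 10, 3), label = "correct")
  mw <- fit_class(matrix(rnorm(30, 1), 10, 3), label = "error")
  path <- withr::local_tempfile(fileext = ".json")
  write_decoder(mc, mw, 0.5, path)
  back <- read_decoder(path)
  expect_equal(back$model_c$mean, mc$mean)
  expect_equal(back$model_w$cov, unname(mw$cov))
  expect_equal(back$lambda, 0.5)
  e <- rnorm(3)
  expect_equal(class_posterior(e, back$model_c, back$model_w),
               class_posterior(e, mc, mw))
})
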