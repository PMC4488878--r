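#' Fit a Gaussian class model to ErrP feature vectors
#'
#' Per-class empirical moments of the two-class Gaussian signal model: mean,
#' unbiased covariance (denominator `n - 1`), and the contributing sample
#' count. Optional nonnegative weights give the frequency-weighted moments
#' used when class membership is soft; the effective count is `sum(weights)`.
#'
#' @param x Numeric matrix, one feature vector per row (a single vector is
#'   treated as one d-dimensional observation).
#' @param weights Optional nonnegative per-row weights, not all zero.
#' @param label Optional class tag, `"correct"` or `"error"`.
#' @return An object of class `class_model`: list with `mean` (length-d),
#'   `cov` (d x d, unbiased; zero matrix when the effective count is <= 1),
#'   `n` (effective count) and `label`.
#' @export
fit_class <- function(x, weights = NULL, label = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("fit_class: need at least one feature vector", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (length(weights) != nrow(x) || any(weights < 0) || sum(weights) == 0)
    stop("fit_class: weights must be nonnegative, length nrow(x), not all zero",
         call. = FALSE)
  n <- sum(weights)
  mu <- colSums(x * weights) / n
  d <- ncol(x)
  if (n > 1) {
    xc <- sweep(x, 2L, mu)
    cov <- crossprod(xc * sqrt(weights), xc * sqrt(weights)) / (n - 1)
  } else {
    cov <- matrix(0, d, d)
  }
  structure(list(mean = mu, cov = cov, n = n, label = label),
            class = "class_model")
}

#' Shrink a covariance matrix toward a scaled identity
#'
#' Returns `(1 - lambda) * cov + lambda * nu * I` with `nu = trace(cov) / d`
#' (the mean eigenvalue), the standard shrinkage target that keeps
#' `lambda = 1` well defined and the result positive definite for any
#' `lambda > 0` whenever `trace(cov) > 0`.
#'
#' @param cov Symmetric d x d matrix.
#' @param lambda Shrinkage intensity in `[0, 1]`; the decoder default is 0.5.
#' @return Shrunk d x d matrix.
#' @export
shrink_cov <- function(cov, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  d <- nrow(cov)
  nu <- sum(diag(cov)) / d
  (1 - lambda) * cov + lambda * nu * diag(d)
}

#' Decoder parameters
#'
#' @param lambda Covariance shrinkage intensity for the supervised Gaussian
#'   classifier (default 0.5).
#' @param priors Class prior pair `(correct, error)`; equal by default since
#'   no a-priori knowledge of the user's assessment is assumed.
#' @return List of class `decoder_params`.
#' @export
decoder_params <- function(lambda = 0.5, priors = c(0.5, 0.5)) {
  stopifnot(length(priors) == 2L, all(priors > 0),
            abs(sum(priors) - 1) < 1e-12)
  structure(list(lambda = lambda, priors = priors), class = "decoder_params")
}

# Vectorized Gaussian log-density: rows of X under N(mean, cov).
.gauss_logdens <- function(X, mean, cov) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  d <- ncol(X)
  R <- chol(cov)
  z <- backsolve(R, t(X) - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

#' Class posterior of a feature vector (supervised Gaussian decoder)
#'
#' Bayes rule over the two class-conditional Gaussian densities, each
#' evaluated with its shrinkage-regularized covariance, combined with the
#' configured class priors. Computed in log space.
#'
#' @param e Feature vector (or matrix of rows).
#' @param model_c,model_w Fitted [fit_class()] models for the correct and
#'   error classes.
#' @param params [decoder_params()].
#' @return Numeric pair `c(correct = , error = )` summing to 1 (a matrix of
#'   such rows if `e` is a matrix).
#' @export
class_posterior <- function(e, model_c, model_w, params = decoder_params()) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1L)
  lc <- .gauss_logdens(e, model_c$mean, shrink_cov(model_c$cov, params$lambda)) +
    log(params$priors[1L])
  lw <- .gauss_logdens(e, model_w$mean, shrink_cov(model_w$cov, params$lambda)) +
    log(params$priors[2L])
  pw <- stats::plogis(lw - lc)
  out <- cbind(correct = 1 - pw, error = pw)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Heavy-tailed posterior-predictive log-density of a class model
#'
#' The class-conditional likelihood used by the self-calibration
#' pseudo-likelihood: the Gaussian parameters are marginalized under the
#' non-informative (Jeffreys) prior, which yields a multivariate Student-t
#' with `n - d` degrees of freedom, location the empirical mean, and scale
#' matrix `Lambda * (n + 1) / (n * (n - d))`, where `Lambda` is the scatter
#' (sum-of-squares) matrix of the `n` contributing signals and `d` the feature
#' dimensionality. With the unbiased covariance `C` stored by [fit_class()],
#' `Lambda = C * (n - 1)`. Heavier tails than the plugin Gaussian make the
#' pseudo-likelihood robust to outliers such as occasional user
#' mis-assessments.
#'
#' @param e Feature vector.
#' @param model A [fit_class()] model with `n > d + 1` (so the degrees of
#'   freedom `n - d` are at least 2); smaller models raise a condition of
#'   class `selfbci_insufficient_data`, and callers fall back to the
#'   cold-start diagonal predictive (see the package vignette).
#' @return Scalar log-density.
#' @export
t_predictive_logdensity <- function(e, model) {
  d <- length(model$mean)
  n <- model$n
  if (n <= d + 1)
    stop(errorCondition(
      paste0("t predictive needs n > d + 1 (n = ", n, ", d = ", d, ")"),
      class = c("selfbci_insufficient_data", "error")))
  Lambda <- model$cov * (n - 1)
  nu <- n - d
  sf <- (n + 1) / (n * (n - d))
  S <- Lambda * sf
  R <- chol(S)
  z <- backsolve(R, e - model$mean, transpose = TRUE)
  q <- sum(z^2)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - 0.5 * d * log(nu * pi) -
    sum(log(diag(R))) - 0.5 * (nu + d) * log1p(q / nu)
}

# Univariate Jeffreys predictive on each dimension separately, summed.
# mean, var (unbiased) and n describe the per-dimension data; used as the
# cold-start fallback when a class has too few signals for the full
# multivariate form. Variances are floored to keep the density finite on
# degenerate (constant) data.
.t_diag_logdens <- function(e, mean, var, n) {
  var <- pmax(var, 1e-12)
  scale2 <- var * (n + 1) / n
  z <- (e - mean) / sqrt(scale2)
  sum(stats::dt(z, df = n - 1, log = TRUE) - 0.5 * log(scale2))
}

#' Serialize / restore a decoder
#'
#' Writes the two class models and the shrinkage setting to a JSON container,
#' the format used to transfer prior signal models between reaching targets.
#'
#' @param model_c,model_w Fitted [fit_class()] models.
#' @param lambda Shrinkage intensity stored with the models.
#' @param path File path.
#' @return `read_decoder()` returns `list(model_c, model_w, lambda)`.
#' @export
write_decoder <- function(model_c, model_w, lambda, path) {
  obj <- list(
    lambda = lambda,
    correct = list(mean = model_c$mean, cov = model_c$cov, n = model_c$n),
    error = list(mean = model_w$mean, cov = model_w$cov, n = model_w$n))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(x, label) structure(
    list(mean = as.numeric(x$mean), cov = as.matrix(x$cov), n = x$n,
         label = label), class = "class_model")
  list(model_c = mk(obj$correct, "correct"),
       model_w = mk(obj$error, "error"),
       lambda = obj$lambda)
}

#' @export
print.class_model <- function(x, ...) {
  cat("<class_model", if (!is.null(x$label)) paste0(" ", x$label) else "",
      "> d = ", length(x$mean), ", n = ", format(x$n), "\n", sep = "")
  invisible(x)
}
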