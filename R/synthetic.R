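#' Synthetic two-class ErrP feature generator
#'
#' Emulates the statistical structure the self-calibration method relies on:
#' one multivariate Gaussian per assessment class, with the error class
#' carrying more mean signal power (`E[e'e]`) than the correct class, and a
#' simulated user whose assessments are occasionally flipped.
#'
#' Two constructions are available. The default `"erp"` structure is the
#' realistic reference (correlated features, difference-wave mean; see the
#' `structure` argument). The `"isotropic"` structure uses equal `sigma^2 I`
#' covariances with the class means on the constant unit vector,
#' `mu_c = -a u`, `mu_w = b u`, and admits closed forms: a target Bayes
#' accuracy gives mean gap `delta = 2 sigma qnorm(accuracy)` (with
#' `mu_c = 0`, implying `power_gap = 1 + delta^2 / (d sigma^2)`), a target
#' power gap g gives `delta = sigma sqrt((g - 1) d)`, and supplying both
#' solves for `a` and `b` jointly (infeasible combinations error). Explicit
#' `mu_c`/`mu_w`/`cov_c`/`cov_w` override either construction.
#'
#' @param d Feature dimensionality (default 57, the reference feature recipe).
#' @param accuracy Target Bayes-optimal single-trial accuracy in `(0.5, 1)`
#'   (default 0.75 when `power_gap` is not given).
#' @param power_gap Target ratio `E[e'e | error] / E[e'e | correct]`, `> 1`,
#'   enforced by construction (ERP default 1.3).
#' @param structure `"erp"` (default) or `"isotropic"`. The ERP structure is
#'   the realistic reference: features are `n_channels` blocks of a smooth
#'   band-limited time course, with a Kronecker covariance (cross-channel
#'   correlation `rho_chan`, AR(1) temporal correlation `rho_time`) shared by
#'   both classes, and an error-minus-correct mean difference shaped like the
#'   canonical fronto-central ErrP difference wave (positive then negative
#'   peak), scaled so the Mahalanobis gap hits the target `accuracy`. The
#'   isotropic structure uses equal `sigma^2 I` covariances with the mean gap
#'   along the constant unit vector and admits closed forms linking
#'   `accuracy` and `power_gap`.
#' @param sigma Noise standard deviation (per feature).
#' @param rho_chan,rho_time ERP-structure correlations (defaults 0.75, 0.8).
#' @param n_channels ERP-structure channel count; must divide `d` (default 3).
#' @param assessment_error_rate Probability in `[0, 0.5)` that the simulated
#'   user's assessment (and hence the emitted signal class) is flipped
#'   (default 0.05).
#' @param mu_c,mu_w,cov_c,cov_w Optional explicit class moments (override the
#'   construction).
#' @return Object of class `signal_generator` with the class moments, their
#'   Cholesky factors, and the implied `accuracy` (exact for equal
#'   covariances) and `power_gap`.
#' @export
signal_generator <- function(d = 57L, accuracy = NULL, power_gap = NULL,
                             structure = c("erp", "isotropic"),
                             sigma = 1, rho_chan = 0.75, rho_time = 0.8,
                             n_channels = 3L,
                             assessment_error_rate = 0.05,
                             mu_c = NULL, mu_w = NULL,
                             cov_c = NULL, cov_w = NULL) {
  d <- as.integer(d)
  structure_ <- match.arg(structure)
  stopifnot(d >= 1L, sigma > 0,
            assessment_error_rate >= 0, assessment_error_rate < 0.5)
  if (structure_ == "erp" && is.null(mu_c) && is.null(cov_c) &&
      d %% n_channels == 0L) {
    if (is.null(accuracy)) accuracy <- 0.75
    if (is.null(power_gap)) power_gap <- 1.3
    stopifnot(accuracy > 0.5, accuracy < 1, power_gap > 1)
    nt <- d %/% n_channels
    # Kronecker covariance: channels correlated by rho_chan, AR(1) in time
    Cch <- matrix(rho_chan, n_channels, n_channels)
    diag(Cch) <- 1
    Ct <- rho_time^abs(outer(seq_len(nt), seq_len(nt), "-"))
    covm <- sigma^2 * kronecker(Cch, Ct)
    # difference wave: positive bump ~1/3 into the window, negative ~2/3,
    # identical shape on every channel with decreasing gain
    tt <- seq(0, 1, length.out = nt)
    wave <- exp(-0.5 * ((tt - 1 / 3) / 0.1)^2) -
      exp(-0.5 * ((tt - 2 / 3) / 0.12)^2)
    gains <- seq(1, 0.6, length.out = n_channels)
    dirw <- as.numeric(outer(gains, wave))
    # The mean difference must satisfy two constraints at once: its
    # Mahalanobis length sets the Bayes accuracy, its Euclidean energy the
    # power gap. Mix the difference-wave direction with the covariance's top
    # eigenvector (the direction of maximal energy per unit of
    # discriminability) and solve for the mixture that delivers the
    # configured power gap at the configured accuracy.
    delta_target <- 2 * stats::qnorm(accuracy)
    energy_target <- (power_gap - 1) * sum(diag(covm))
    v1 <- eigen(covm, symmetric = TRUE)$vectors[, 1L]
    energy_at <- function(theta) {
      u <- (1 - theta) * dirw / sqrt(sum(dirw^2)) + theta * v1
      u <- u / sqrt(sum(u^2))
      maha <- sqrt(sum(u * solve(covm, u)))
      sum((u * delta_target / maha)^2)
    }
    if (energy_at(1) < energy_target)
      stop("power_gap ", power_gap, " infeasible at accuracy ", accuracy,
           " under the ERP covariance", call. = FALSE)
    theta <- if (energy_at(0) >= energy_target) 0 else
      stats::uniroot(function(th) energy_at(th) - energy_target,
                     c(0, 1), tol = 1e-10)$root
    u <- (1 - theta) * dirw / sqrt(sum(dirw^2)) + theta * v1
    u <- u / sqrt(sum(u^2))
    maha <- sqrt(sum(u * solve(covm, u)))
    mu_c <- rep(0, d)
    mu_w <- u * (delta_target / maha)
    cov_c <- cov_w <- covm
  } else if (is.null(mu_c) || is.null(mu_w)) {
    u <- rep(1 / sqrt(d), d)
    if (!is.null(accuracy) && !is.null(power_gap)) {
      stopifnot(accuracy > 0.5, accuracy < 1, power_gap > 1)
      delta <- 2 * sigma * stats::qnorm(accuracy)
      g <- power_gap
      # mu_c = -a u, mu_w = b u with a + b = delta and
      # (b^2 + d sigma^2) = g (a^2 + d sigma^2)
      disc <- 4 * delta^2 + 4 * (g - 1) * (delta^2 - d * sigma^2 * (g - 1))
      if (disc < 0)
        stop("accuracy and power_gap jointly infeasible at d = ", d,
             call. = FALSE)
      a <- (-2 * delta + sqrt(disc)) / (2 * (g - 1))
      if (a < 0)
        stop("accuracy and power_gap jointly infeasible (power gap too small ",
             "for the requested separation)", call. = FALSE)
      b <- delta - a
      mu_c <- -a * u
      mu_w <- b * u
    } else {
      if (is.null(accuracy) && is.null(power_gap)) accuracy <- 0.75
      if (!is.null(power_gap)) {
        stopifnot(power_gap > 1)
        delta <- sigma * sqrt((power_gap - 1) * d)
      } else {
        stopifnot(accuracy > 0.5, accuracy < 1)
        delta <- 2 * sigma * stats::qnorm(accuracy)
      }
      mu_c <- rep(0, d)
      mu_w <- delta * u
    }
  }
  if (is.null(cov_c)) cov_c <- diag(sigma^2, d)
  if (is.null(cov_w)) cov_w <- diag(sigma^2, d)
  pow_c <- sum(mu_c^2) + sum(diag(cov_c))
  pow_w <- sum(mu_w^2) + sum(diag(cov_w))
  if (pow_w <= pow_c)
    stop("generator must give the error class higher mean power", call. = FALSE)
  # Bayes accuracy from the Mahalanobis gap (exact for equal covariances)
  dm <- mu_w - mu_c
  maha_eff <- sqrt(sum(dm * solve((cov_c + cov_w) / 2, dm)))
  structure(list(
    d = d, mu_c = mu_c, mu_w = mu_w, cov_c = cov_c, cov_w = cov_w,
    chol_c = chol(cov_c), chol_w = chol(cov_w),
    assessment_error_rate = assessment_error_rate,
    power_gap = pow_w / pow_c,
    accuracy = stats::pnorm(maha_eff / 2)),
    class = "signal_generator")
}

#' Draw synthetic class-conditional feature vectors
#'
#' Draws from the configured class Gaussian using R's global RNG stream (seed
#' the run once with `set.seed()` for reproducibility).
#'
#' @param n Number of draws.
#' @param label Class: 1/"correct" or 2/"error".
#' @param gen A [signal_generator()].
#' @return `n` x `d` matrix of feature rows.
#' @export
sample_signal <- function(n, label, gen) {
  k <- if (is.character(label)) match(label, c("correct", "error"))
       else as.integer(label)
  stopifnot(k %in% 1:2)
  mu <- if (k == 1L) gen$mu_c else gen$mu_w
  R <- if (k == 1L) gen$chol_c else gen$chol_w
  Z <- matrix(stats::rnorm(n * gen$d), n, gen$d)
  Z %*% R + matrix(mu, n, gen$d, byrow = TRUE)
}

#' Simulated user with a fixed intended goal
#'
#' @param goal 0-based `(row, col)` cell the user intends; fixed until the
#'   device reaches a target.
#' @param gen A [signal_generator()].
#' @return Object of class `simulated_user`.
#' @export
simulated_user <- function(goal, gen) {
  structure(list(goal = goal, gen = gen), class = "simulated_user")
}

#' Simulate the user's assessment of one cursor action
#'
#' The user assesses the action against the optimal policy of the intended
#' goal; with probability `assessment_error_rate` the assessment is flipped,
#' and the emitted signal is drawn from the class of the (possibly flipped)
#' assessment.
#'
#' @param user A [simulated_user()].
#' @param world The [grid_world()].
#' @param state,action The executed (state, action).
#' @return List with `label` (1/2, the class that generated the signal),
#'   `policy_label` (1/2, the unflipped assessment), and `features`.
#' @export
assess <- function(user, world, state, action) {
  p <- label_probability(world, state, action, user$goal)
  lab <- if (p[1L] == 1) 1L else 2L
  out_lab <- lab
  if (user$gen$assessment_error_rate > 0 &&
      stats::runif(1) < user$gen$assessment_error_rate)
    out_lab <- 3L - lab
  list(label = out_lab, policy_label = lab,
       features = as.numeric(sample_signal(1L, out_lab, user$gen)))
}

#' Bayes-optimal single-trial accuracy of a generator
#'
#' Monte-Carlo estimate: draws `n` signals per class and classifies each by
#' comparing the true class log-densities. Used to state a generator's
#' difficulty; under the default equal-isotropic construction it converges to
#' the closed form `pnorm(delta / (2 sigma))`.
#'
#' @param gen A [signal_generator()].
#' @param n Draws per class.
#' @return Scalar accuracy estimate in `[0.5, 1]`.
#' @export
separability_to_accuracy <- function(gen, n = 20000L) {
  acc <- 0
  for (k in 1:2) {
    X <- sample_signal(n, k, gen)
    g1 <- .gauss_logdens(X, gen$mu_c, gen$cov_c)
    g2 <- .gauss_logdens(X, gen$mu_w, gen$cov_w)
    pred <- 1L + (g2 > g1)
    acc <- acc + mean(pred == k) / 2
  }
  acc
}

#' Synthesize raw ErrP-like epochs (waveform mode)
#'
#' Generates 3-channel epochs at a given sampling rate whose error-class
#' difference wave mimics the canonical fronto-central ErrP shape: a positive
#' peak near 400 ms and a negative peak near 600 ms after action onset, on top
#' of white measurement noise. Running these through [extract_features()]
#' exercises the full feature path (57 features at the 256 Hz defaults).
#'
#' @param n Number of epochs.
#' @param labels Integer labels (1 = correct, 2 = error), length `n`.
#' @param sampling_rate Hz (default 256).
#' @param amplitude Peak amplitude of the error difference wave (a.u.).
#' @param noise_sd White-noise standard deviation.
#' @param channels Channel names (3 by default: Fz, FCz, Cz).
#' @return List of `n` [eeg_epoch()] objects spanning -200..1000 ms.
#' @export
sample_epochs <- function(n, labels, sampling_rate = 256,
                          amplitude = 4, noise_sd = 1,
                          channels = c("Fz", "FCz", "Cz")) {
  stopifnot(length(labels) == n, all(labels %in% 1:2))
  t0 <- round(0.2 * sampling_rate) + 1L
  len <- round(1.2 * sampling_rate)
  tt <- (seq_len(len) - t0) / sampling_rate  # seconds relative to onset
  bump <- function(center, width) exp(-0.5 * ((tt - center) / width)^2)
  wave <- amplitude * (bump(0.4, 0.05) - bump(0.6, 0.07))
  gains <- c(1, 0.8, 0.6)[seq_along(channels)]
  lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(length(channels) * len, sd = noise_sd),
                length(channels), len)
    if (labels[i] == 2L) m <- m + outer(gains, wave)
    eeg_epoch(m, sampling_rate, t0, channels)
  })
}

#' @export
print.signal_generator <- function(x, ...) {
  cat("<signal_generator> d = ", x$d,
      ", Bayes accuracy ~ ", format(x$accuracy, digits = 3),
      ", power gap ", format(x$power_gap, digits = 3),
      ", assessment error rate ", x$assessment_error_rate, "\n", sep = "")
  invisible(x)
}
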