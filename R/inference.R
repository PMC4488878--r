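#' History of (state, action, signal) triplets
#'
#' The ordered record the self-calibration machinery scores: one row of
#' features per executed action, with the grid state the action was taken in.
#' Signals from previously identified targets enter as *prior* data with
#' fixed labels (they are never re-labeled); only their per-class sufficient
#' statistics are kept.
#'
#' @param d Feature dimensionality.
#' @return Object of class `selfcal_history`.
#' @export
selfcal_history <- function(d) {
  d <- as.integer(d)
  structure(list(
    d = d,
    E = matrix(numeric(0), 0L, d),
    states = integer(0),
    actions = integer(0),
    prior_n = c(0, 0),
    prior_sum = matrix(0, d, 2L),
    prior_ssq = matrix(0, d, 2L),
    prior_scatter = list(matrix(0, d, d), matrix(0, d, d))),
    class = "selfcal_history")
}

#' @rdname selfcal_history
#' @param h A `selfcal_history`.
#' @param world The [grid_world()] the states live in.
#' @param state 0-based `(row, col)` state the action was executed in.
#' @param action One of [grid_actions()].
#' @param e Feature vector (length `d`).
#' @export
history_append <- function(h, world, state, action, e) {
  stopifnot(length(e) == h$d)
  h$E <- rbind(h$E, as.numeric(e))
  h$states <- c(h$states, state_index(world, state))
  h$actions <- c(h$actions, .action_index(action))
  h
}

#' @rdname selfcal_history
#' @param X Matrix of pre-labeled feature rows to add as fixed prior data.
#' @param labels Integer labels for `X` rows: 1 = correct, 2 = error.
#' @export
history_add_prior <- function(h, X, labels) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == h$d, length(labels) == nrow(X), all(labels %in% 1:2))
  for (k in 1:2) {
    Xk <- X[labels == k, , drop = FALSE]
    if (!nrow(Xk)) next
    h$prior_n[k] <- h$prior_n[k] + nrow(Xk)
    h$prior_sum[, k] <- h$prior_sum[, k] + colSums(Xk)
    h$prior_ssq[, k] <- h$prior_ssq[, k] + colSums(Xk^2)
    h$prior_scatter[[k]] <- h$prior_scatter[[k]] + crossprod(Xk)
  }
  h
}

#' @rdname selfcal_history
#' @export
history_length <- function(h) nrow(h$E)

#' @export
print.selfcal_history <- function(x, ...) {
  cat("<selfcal_history> d = ", x$d, ", M = ", nrow(x$E),
      ", prior n = (", x$prior_n[1L], ", ", x$prior_n[2L], ")\n", sep = "")
  invisible(x)
}

# Multivariate-t log-density core in whitened coordinates: nu degrees of
# freedom, isotropic scale c (so log|scale| = d log c up to the shared
# whitening determinant, which cancels in label posteriors), q = squared
# distance to the location divided by c.
.t_core <- function(q, ldS, nu, d) {
  lgamma((nu + d) / 2) - lgamma(nu / 2) - 0.5 * d * log(nu * pi) -
    0.5 * ldS - 0.5 * (nu + d) * log1p(q / nu)
}

# Per-task scores: leave-one-out pseudo-log-likelihood and log power ratio,
# computed for every hypothesis of a task_set in one pass.
#
# Signal model: each class is Gaussian with a covariance *shared* by both
# classes and all task hypotheses -- the lambda-shrunk pooled covariance of
# all signals seen so far (the same regularized covariance the supervised
# classifier uses) -- and a class mean with a conjugate prior
# N(m0, Sigma/kappa0) centred on the pooled mean. Marginalizing the mean
# gives a Student-t predictive per class:
#   location (kappa0 m0 + n xbar_k) / (kappa0 + n),
#   scale Sigma (s + 1)/s with s = kappa0 + n, df n + n0 + 2,
# which converges to the shrinkage Gaussian classifier as n grows. The
# shared covariance sidesteps the unstable per-task, per-class covariance
# fits (d x d from a handful of signals) that otherwise drown the label
# information in estimation noise; kappa0 (= prior_strength, default d)
# keeps small-sample class means close to the pooled mean so early label
# posteriors stay near 1/2 instead of saturating on spurious separations.
#
# Each history triplet then contributes the leave-one-out posterior
# probability of the label the task's optimal policy assigns to its
# (state, action) pair:
#   factor_i(t) = p(l = l_t(i) | e_i, D_-i, t)
#               = pred_{l_t(i)}(e_i) / (pred_c(e_i) + pred_w(e_i)),
# the member class's location being refitted without e_i. This is the
# conditional decomposition of the joint per-signal (density x label) factor:
# the remaining task-conditional signal marginal is dominated by estimation
# noise at realistic feature dimensionalities and carries essentially no task
# information, so it is dropped, which also makes scores comparable across
# hypotheses and invariant to a common rescaling of the features.
#
# The power ratio reuses the same class models: responsibilities are the
# (non-LOO) label posteriors, and the ratio compares the responsibility-
# weighted mean signal power (e'e in the original coordinates) of the error
# class against the correct class.
.selfcal_scores <- function(history, tset, lambda = 0.5, power = TRUE,
                            prior_strength = NULL) {
  T_ <- tset$n_tasks
  S <- tset$world$n_states
  E <- history$E
  M <- nrow(E)
  d <- history$d
  if (is.null(prior_strength)) prior_strength <- 20
  k0 <- prior_strength
  out <- list(log_plik = numeric(T_), log_power = numeric(T_),
              mean_c = NULL, mean_w = NULL)
  if (M < 2) return(out)
  pow <- rowSums(E^2)
  tot_n <- sum(history$prior_n) + M
  tot_sum <- rowSums(history$prior_sum) + colSums(E)
  m0 <- tot_sum / tot_n
  Stot <- crossprod(E) + history$prior_scatter[[1L]] +
    history$prior_scatter[[2L]]
  covp <- (Stot - tot_n * tcrossprod(m0)) / (tot_n - 1)
  covp <- shrink_cov((covp + t(covp)) / 2, lambda)
  if (sum(diag(covp)) <= 0) covp <- diag(d)  # all signals identical
  R <- chol(covp)
  # whiten everything once; all Mahalanobis forms become Euclidean
  Ew <- t(backsolve(R, t(E), transpose = TRUE))
  m0w <- backsolve(R, m0, transpose = TRUE)
  pw1 <- backsolve(R, history$prior_sum[, 1L], transpose = TRUE)
  pw2 <- backsolve(R, history$prior_sum[, 2L], transpose = TRUE)
  ee <- rowSums(Ew^2)
  pooled_ok <- TRUE
  Stot <- NULL
  colcode <- (history$actions - 1L) * S + history$states
  mean_c <- matrix(0, T_, d)
  mean_w <- matrix(0, T_, d)
  for (t in seq_len(T_)) {
    labs <- tset$labels[t, colcode]
    mem1 <- labs == 1L
    m1 <- sum(mem1); m2 <- M - m1
    n1 <- history$prior_n[1L] + m1
    n2 <- history$prior_n[2L] + m2
    cs1 <- colSums(Ew[mem1, , drop = FALSE])
    v1 <- k0 * m0w + pw1 + cs1          # kappa0 m0 + class-1 signal sum
    v2 <- k0 * m0w + pw2 + (colSums(Ew) - cs1)
    mean_c[t, ] <- v1 / (k0 + n1)
    mean_w[t, ] <- v2 / (k0 + n2)
    ld1 <- .class_factor_logdens(Ew, ee, mem1, colcode, n1, v1, k0,
                                 prior_strength, d, tot_n, m0w, pooled_ok)
    ld2 <- .class_factor_logdens(Ew, ee, !mem1, colcode, n2, v2, k0,
                                 prior_strength, d, tot_n, m0w, pooled_ok)
    denom <- pmax(ld1, ld2) + log1p(exp(-abs(ld1 - ld2)))
    out$log_plik[t] <- sum(ifelse(mem1, ld1, ld2) - denom)
    if (power) {
      if (is.null(Stot)) Stot <- crossprod(E)
      if (m1 <= m2) {
        S1c <- crossprod(E[mem1, , drop = FALSE])
        S2c <- Stot - S1c
      } else {
        S2c <- crossprod(E[!mem1, , drop = FALSE])
        S1c <- Stot - S2c
      }
      sum1r <- history$prior_sum[, 1L] + colSums(E[mem1, , drop = FALSE])
      sum2r <- history$prior_sum[, 2L] + colSums(E[!mem1, , drop = FALSE])
      out$log_power[t] <- .log_power_ratio(
        E, pow, n1, sum1r, history$prior_scatter[[1L]] + S1c,
        n2, sum2r, history$prior_scatter[[2L]] + S2c, lambda)
    }
  }
  out$mean_c <- mean_c
  out$mean_w <- mean_w
  out
}

# Class-conditional log-score of every whitened signal under one class of a
# task hypothesis: the Gaussian core -||e - location||^2 / 2 in whitened
# coordinates (shared covariance), with the conjugate-damped class mean
# (kappa0 pseudo-observations at the pooled mean). The two classes' scores
# enter a logistic label posterior, so only their *contrast* matters; using
# the equal-covariance core for both classes keeps that contrast free of
# class-size-dependent normalization (a smaller class would otherwise have a
# fatter, lower-peaked predictive, biasing central signals toward whichever
# class is larger irrespective of the task's correctness).
#
# Members (rows the task assigns to this class) are scored under the
# leave-one-pair-out location: all signals recorded at the same
# (state, action) pair are held out together, because they share one unknown
# label and are exchangeable -- holding out only the scored signal would let
# repeated assessments of one pair vouch for each other inside a mislabeled
# class.
.class_factor_logdens <- function(Ew, ee, is_mem, grp, n_k, v, k0, n0, d,
                                  tot_n, m0w, pooled_ok) {
  M <- nrow(Ew)
  out <- numeric(M)
  ev <- as.numeric(Ew %*% v)
  vv <- sum(v^2)
  nm <- !is_mem
  if (any(nm)) {
    s <- k0 + n_k
    out[nm] <- -0.5 * (ee - 2 * ev / s + vv / s^2)[nm]
  }
  mm <- which(is_mem)
  if (length(mm)) {
    g <- match(grp[mm], unique(grp[mm]))
    gs <- rowsum(Ew[mm, , drop = FALSE], g)       # per-pair sums
    gn <- tabulate(g)                              # per-pair counts
    xs <- gs[g, , drop = FALSE]                    # excluded sum per member
    xn <- gn[g]                                    # excluded count per member
    s <- k0 + n_k - xn
    # location = (v - pair sum) / s
    exv <- rowSums(Ew[mm, , drop = FALSE] * xs)    # e_i . xs_i
    vxs <- as.numeric(xs %*% v)                    # v . xs_i
    xx <- rowSums(xs^2)
    out[mm] <- -0.5 * (ee[mm] - 2 * (ev[mm] - exv) / s +
                         (vv - 2 * vxs + xx) / s^2)
  }
  out
}

# Log of the responsibility-weighted power ratio p_w / p_c for one task's
# labeling (the symmetry-breaking statistic). The class models are the
# task-labeled per-class Gaussians with lambda-shrunk covariances -- the same
# family as the supervised classifier -- and the responsibilities are their
# equal-prior posteriors, so tight clusters yield hard responsibilities.
# Degenerate cases (a class with fewer than two signals, zero total
# responsibility, or zero-variance classes) fall back to a ratio of 1.
.log_power_ratio <- function(E, pow, n1, sum1, S1, n2, sum2, S2, lambda) {
  if (n1 < 2 || n2 < 2) return(0)
  mu1 <- sum1 / n1
  mu2 <- sum2 / n2
  C1 <- (S1 - n1 * tcrossprod(mu1)) / (n1 - 1)
  C2 <- (S2 - n2 * tcrossprod(mu2)) / (n2 - 1)
  if (sum(diag(C1)) <= 0 || sum(diag(C2)) <= 0) return(0)
  g1 <- .gauss_logdens(E, mu1, shrink_cov((C1 + t(C1)) / 2, lambda))
  g2 <- .gauss_logdens(E, mu2, shrink_cov((C2 + t(C2)) / 2, lambda))
  rw <- stats::plogis(g2 - g1)
  sw <- sum(rw); sc <- sum(1 - rw)
  if (sw <= 1e-12 || sc <= 1e-12) return(0)
  log(sum(rw * pow) / sw) - log(sum((1 - rw) * pow) / sc)
}

#' Leave-one-out pseudo-log-likelihood of a task hypothesis
#'
#' The self-calibration score of one goal hypothesis: the sum over history
#' triplets of the log posterior probability of the label the hypothesized
#' optimal policy assigns to each (state, action) pair, with the class models
#' fitted -- under the hypothesis's own labeling -- on all triplets *except
#' those sharing the scored triplet's (state, action) pair* (leave-one-pair-
#' out cross-validation). Label posteriors come from the regularized class-
#' conditional model described in the package vignette: a covariance shared
#' by both classes and all hypotheses (the lambda-shrunk pooled covariance,
#' the same regularization the supervised classifier uses) and class means
#' smoothed toward the pooled mean by `prior_strength` pseudo-assessments,
#' which keeps early-operation scores calibrated instead of saturating on
#' small-sample noise. Order-invariant in the history.
#'
#' @param history A [selfcal_history()] with at least 2 triplets.
#' @param task 0-based `(row, col)` goal hypothesis.
#' @param world The [grid_world()].
#' @param prior_strength Location-smoothing strength: the number of
#'   pseudo-assessments at the pooled mean each class mean is shrunk toward
#'   (default 20, the scale of a few dozen trials). See the package vignette.
#' @return Scalar log pseudo-likelihood.
#' @export
pseudo_loglikelihood <- function(history, task, world, prior_strength = NULL) {
  if (history_length(history) < 2L)
    stop("pseudo_loglikelihood needs a history of length >= 2", call. = FALSE)
  ts <- task_set(world, matrix(task, 1L))
  .selfcal_scores(history, ts, power = FALSE,
                  prior_strength = prior_strength)$log_plik[1L]
}

#' Class-power ratio of a task hypothesis
#'
#' The symmetry-breaking statistic: the ratio of the responsibility-weighted
#' mean signal power (inner product `e'e`) of the error class over that of
#' the correct class, with responsibilities given by the task's fitted class
#' models (equal class priors). Error potentials carry more power on average,
#' so among two label-symmetric hypotheses -- whose pseudo-likelihoods are
#' identical by construction -- the one assigning the higher-power signals to
#' the error class gets a ratio above 1.
#'
#' @inheritParams pseudo_loglikelihood
#' @param lambda Shrinkage used for the responsibility models (default 0.5).
#' @return Scalar ratio (1 in degenerate cases).
#' @export
power_ratio <- function(history, task, world, lambda = 0.5) {
  if (history_length(history) < 1L)
    stop("power_ratio needs a nonempty history", call. = FALSE)
  ts <- task_set(world, matrix(task, 1L))
  exp(.selfcal_scores(history, ts, lambda = lambda, power = TRUE)$log_power[1L])
}

.new_task_posterior <- function(log_corrected, log_plik, tset,
                                class_means = NULL) {
  mx <- max(log_corrected)
  scores <- exp(log_corrected - mx)
  scores <- scores / sum(scores)
  if (length(log_corrected) == 1L) {
    conf <- 1
  } else {
    conf <- vapply(seq_along(log_corrected), function(t) {
      rival <- max(log_corrected[-t])
      stats::plogis(log_corrected[t] - rival)
    }, numeric(1))
  }
  structure(list(scores = scores, log_pseudolik = log_plik,
                 log_corrected = log_corrected, confidence = conf,
                 goals = tset$goals, class_means = class_means),
            class = "task_posterior")
}

#' Power-corrected task posterior
#'
#' Scores every goal hypothesis by its leave-one-out pseudo-likelihood
#' multiplied by its class-power ratio, normalized over hypotheses under a
#' uniform task prior. All arithmetic is in log space. With fewer than two
#' triplets the posterior is uniform by convention.
#'
#' @param history A [selfcal_history()].
#' @param tset A [task_set()] of candidate goals.
#' @param lambda Shrinkage for the power-ratio responsibility models.
#' @param power Apply the power correction (default `TRUE`).
#' @param prior_strength Location-smoothing strength (pseudo-assessments at
#'   the pooled mean; default 20).
#' @return An object of class `task_posterior`: `scores` (normalized, sums to
#'   1), `log_pseudolik`, `log_corrected`, per-task `confidence` (the minimum
#'   pairwise normalized likelihood W), and the hypothesis `goals`.
#' @export
corrected_posterior <- function(history, tset, lambda = 0.5, power = TRUE,
                                prior_strength = NULL) {
  sc <- .selfcal_scores(history, tset, lambda = lambda, power = power,
                        prior_strength = prior_strength)
  cm <- if (is.null(sc$mean_c)) NULL else list(c = sc$mean_c, w = sc$mean_w)
  .new_task_posterior(sc$log_plik + sc$log_power, sc$log_plik, tset, cm)
}

#' Decision confidence of each task hypothesis
#'
#' `W^t`, the minimum over rivals x of `P(t) / (P(t) + P(x))` computed from
#' the log-scores of a [corrected_posterior()] (equivalently, the pairwise
#' normalized likelihood against the strongest rival). Values lie in `[0, 1]`
#' and at most one task can exceed 0.5.
#'
#' @param posterior A `task_posterior`.
#' @return Numeric vector of per-task confidences.
#' @export
task_confidence <- function(posterior) posterior$confidence

#' Decide the intended goal
#'
#' Returns the unique task whose confidence `W^t` exceeds the threshold
#' `beta`, or `NULL` when no hypothesis is confident enough yet.
#'
#' @param posterior A `task_posterior`.
#' @param beta Confidence threshold in `[0.5, 1]`.
#' @return `NULL`, or `list(index, goal)` with the 1-based hypothesis index
#'   and its 0-based `(row, col)` goal.
#' @export
decide <- function(posterior, beta) {
  stopifnot(beta >= 0.5, beta <= 1)
  w <- posterior$confidence
  i <- which(w > beta)
  if (length(i) != 1L) return(NULL)
  list(index = i, goal = posterior$goals[i, ])
}

#' Recursive task filter for a calibrated decoder
#'
#' The supervised-regime goal filter: each step multiplies the prior
#' hypothesis scores by the class-conditional Gaussian density of the observed
#' signal under the label the hypothesis assigns to the executed
#' (state, action) pair, and renormalizes. Densities use the fitted decoder's
#' shrunk covariances. Computed in log space.
#'
#' @param prior A `task_posterior` (or `NULL` for a uniform prior).
#' @param e Observed feature vector.
#' @param state,action Where/what the device executed.
#' @param tset A [task_set()].
#' @param model_c,model_w Fitted [fit_class()] models.
#' @param params [decoder_params()].
#' @return Updated `task_posterior`.
#' @export
calibrated_update <- function(prior, e, state, action, tset,
                              model_c, model_w, params = decoder_params()) {
  world <- tset$world
  S <- world$n_states
  lp0 <- if (is.null(prior)) rep(0, tset$n_tasks) else prior$log_corrected
  dens <- c(
    .gauss_logdens(e, model_c$mean, shrink_cov(model_c$cov, params$lambda)),
    .gauss_logdens(e, model_w$mean, shrink_cov(model_w$cov, params$lambda)))
  col <- (.action_index(action) - 1L) * S + state_index(world, state)
  labs <- tset$labels[, col]
  lp <- lp0 + dens[labs]
  lp <- lp - max(lp)
  .new_task_posterior(lp, lp, tset)
}

#' Uniform task posterior
#'
#' @param tset A [task_set()].
#' @return A `task_posterior` with equal scores.
#' @export
uniform_posterior <- function(tset) {
  .new_task_posterior(rep(0, tset$n_tasks), rep(0, tset$n_tasks), tset)
}

#' @export
print.task_posterior <- function(x, ...) {
  i <- which.max(x$scores)
  cat("<task_posterior> ", length(x$scores), " hypotheses; MAP goal (",
      x$goals[i, 1L], ",", x$goals[i, 2L], ") p = ",
      format(x$scores[i], digits = 3), ", W = ",
      format(x$confidence[i], digits = 3), "\n", sep = "")
  invisible(x)
}
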