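#' Planner configuration
#'
#' @param discount Value-iteration discount factor in `(0, 1)` (default 0.95).
#' @param vi_tolerance Sup-norm tolerance on the value function's distance to
#'   the Bellman fixed point (default 1e-6).
#' @param beta Confidence threshold for the explore-to-exploit switch.
#' @param decision_persistence Number of consecutive posterior updates for
#'   which the *same* task must hold `W > beta` before the device commits to
#'   it (default 20). Guards the explore-to-exploit switch against transient
#'   small-sample fluctuations of the pseudo-likelihood: spurious confidence
#'   spikes decay as new signals update the class models, while a genuinely
#'   identified goal sustains its dominance.
#' @param progress_weight Optional weight of an expected-progress term in
#'   the exploration reward (default 0): each pair also earns its posterior
#'   probability of being a correct action, gated by how far the leading
#'   hypothesis's decision confidence W exceeds 1/2. While rival hypotheses
#'   survive the information terms dominate; once a single goal dominates,
#'   the information value vanishes and the device's behaviour turns
#'   increasingly goal-directed, which is what makes the error rate fall
#'   over a target even before the formal explore-to-exploit switch.
#' @param epsilon_halflife Time constant (in collected signals) of the
#'   annealed random-exploration schedule: before the value-iteration policy
#'   is consulted, a uniformly random action is taken with probability
#'   `exp(-M / epsilon_halflife)` where `M` is the current history length
#'   (default 60; 0 disables). Early behaviour is thus close to uniformly
#'   random -- nothing is yet known about the decoder, and random probing
#'   covers the whole pair space -- and fades into targeted uncertainty
#'   planning as evidence accrues.
#' @param n_label_samples Number of predictive draws for the optional
#'   sampled signal-space uncertainty term (0 = analytic terms only, the
#'   default).
#' @return Object of class `planner_config`.
#' @export
planner_config <- function(discount = 0.95, vi_tolerance = 1e-6,
                           beta = 0.9, decision_persistence = 20L,
                           progress_weight = 0, epsilon_halflife = 60,
                           n_label_samples = 0L) {
  stopifnot(discount > 0, discount < 1, vi_tolerance > 0,
            beta >= 0.5, beta <= 1, decision_persistence >= 1,
            progress_weight >= 0, epsilon_halflife >= 0, n_label_samples >= 0)
  structure(list(discount = discount, vi_tolerance = vi_tolerance,
                 beta = beta,
                 decision_persistence = as.integer(decision_persistence),
                 progress_weight = progress_weight,
                 epsilon_halflife = epsilon_halflife,
                 n_label_samples = as.integer(n_label_samples)),
            class = "planner_config")
}

.binary_entropy <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log(p[ok]) - (1 - p[ok]) * log1p(-p[ok])
  h
}

#' Uncertainty reward over (state, action) pairs
#'
#' The signal-space uncertainty of each pair: the posterior-weighted
#' dispersion of the signal means the hypotheses predict there (a
#' second-order approximation of the mutual information between the goal and
#' the next signal), weighted by `2 - q` with
#' `q(s, a) = sum_t P(t) * p(correct | s, a, t)` so that globally ambiguous
#' error-labeled probes -- the ones that separate label-symmetric rivals,
#' whose class models are swapped copies of each other -- are valued first.
#' Before class models exist (posterior without `class_means`, e.g. a
#' [uniform_posterior()]) the reward falls back to the binary entropy of the
#' mixture label distribution `q`. When a `history` is supplied, each pair's
#' reward is divided by one plus the number of times the pair has been
#' assessed: the pair's label is a fixed unknown, repeated assessments of it
#' are exchangeable, so their marginal information decays and the planner
#' moves on instead of farming one uncertain pair. An optional
#' expected-progress term and a sampled signal-space bonus are controlled by
#' the [planner_config()] fields `progress_weight` and `n_label_samples`.
#'
#' @param posterior A `task_posterior` over the hypotheses of `tset`.
#' @param tset A [task_set()].
#' @param history Optional [selfcal_history()], used for the visit counts and
#'   the sampled term.
#' @param cfg A [planner_config()].
#' @return `n_states` x 5 numeric reward matrix (actions in
#'   [grid_actions()] order).
#' @export
uncertainty_reward <- function(posterior, tset, history = NULL,
                               cfg = planner_config()) {
  S <- tset$world$n_states
  if (!is.null(posterior$class_means)) {
    # signal-space uncertainty: posterior-weighted dispersion of the class
    # means the hypotheses predict for the pair's signal (whitened
    # coordinates) -- a second-order approximation of the mutual information
    # between the task and the next signal. Unlike the label entropy it also
    # values pairs where hypotheses agree on the label but predict different
    # signal models; such pairs are the only ones that disambiguate
    # label-symmetric hypotheses, whose class models are swapped copies of
    # each other, so they must compete on equal terms with label-disagreement
    # pairs (whose dispersion is the between-class mean distance).
    pm <- posterior$class_means
    p <- posterior$scores
    disp <- numeric(S * 5L)
    sq_c <- rowSums(pm$c^2)
    sq_w <- rowSums(pm$w^2)
    for (col in seq_len(S * 5L)) {
      isc <- tset$labels[, col] == 1L
      mbar <- crossprod(pm$c, p * isc) + crossprod(pm$w, p * (!isc))
      disp[col] <- sum(p * ifelse(isc, sq_c, sq_w)) - sum(mbar^2)
    }
    # Weight by (2 - q), q the posterior-mixture correct-probability: pairs
    # the plausible goals consider errors carry the globally ambiguous
    # (label-symmetric) structure and are probed first; as visits retire
    # them, exploration shifts to balanced pairs and finally to goal-directed
    # behaviour, reproducing the high-to-low error-rate profile of the
    # closed-loop protocol.
    p_correct <- crossprod(tset$labels == 1L, posterior$scores)
    reward <- matrix(0.5 * disp * (2 - p_correct), S, 5L,
                     dimnames = list(NULL, grid_actions()))
  } else {
    # cold start (no fitted class models yet): binary entropy of the
    # posterior-mixture label distribution
    p_correct <- crossprod(tset$labels == 1L, posterior$scores)
    reward <- matrix(.binary_entropy(p_correct), S, 5L,
                     dimnames = list(NULL, grid_actions()))
  }
  if (!is.null(history) && history_length(history) > 0L) {
    colcode <- (history$actions - 1L) * S + history$states
    visits <- tabulate(colcode, nbins = S * 5L)
    reward <- reward / (1 + matrix(visits, S, 5L))
  }
  if (cfg$progress_weight > 0) {
    # expected task progress: the posterior probability that the action is
    # correct for the intended goal, gated by the posterior mass of the
    # leading hypothesis -- progress is only worth pursuing once some goal is
    # probably right, and it never becomes redundant (no visit discount)
    p_correct <- crossprod(tset$labels == 1L, posterior$scores)
    gate <- max(0, 2 * max(posterior$confidence) - 1)
    reward <- reward + cfg$progress_weight * gate * matrix(p_correct, S, 5L)
  }
  if (cfg$n_label_samples > 0L && !is.null(history) &&
      history_length(history) >= 2L)
    reward <- reward + .sampled_signal_uncertainty(posterior, tset, history,
                                                   cfg$n_label_samples)
  reward
}

# Sampled signal-space uncertainty: for each (s, a), draw labels from the
# posterior-mixture label distribution, draw signals from the pooled per-label
# Gaussian fit of the current history, and score the entropy of the
# posterior-weighted probability that the mixture of task-conditioned
# classifiers calls the draw an error. A diagonal (per-dimension) Gaussian
# fit keeps the term cheap; it is an exploration bonus, not a density model.
.sampled_signal_uncertainty <- function(posterior, tset, history, n_draws) {
  S <- tset$world$n_states
  E <- history$E
  d <- ncol(E)
  colcode <- (history$actions - 1L) * S + history$states
  out <- matrix(0, S, 5L)
  map_t <- which.max(posterior$scores)
  labs <- tset$labels[map_t, colcode]
  if (length(unique(labs)) < 2L) return(out)
  fits <- lapply(1:2, function(k) {
    Xk <- E[labs == k, , drop = FALSE]
    if (nrow(Xk) < 2L) Xk <- E
    list(mean = colMeans(Xk), sd = pmax(apply(Xk, 2L, stats::sd), 1e-6))
  })
  p_correct <- crossprod(tset$labels == 1L, posterior$scores)
  for (col in seq_len(S * 5L)) {
    q <- p_correct[col]
    if (q <= 0 || q >= 1) next
    ks <- 1L + (stats::runif(n_draws) > q)
    hs <- vapply(ks, function(k) {
      e <- stats::rnorm(d, fits[[k]]$mean, fits[[k]]$sd)
      g1 <- sum(stats::dnorm(e, fits[[1L]]$mean, fits[[1L]]$sd, log = TRUE))
      g2 <- sum(stats::dnorm(e, fits[[2L]]$mean, fits[[2L]]$sd, log = TRUE))
      .binary_entropy(stats::plogis(g2 - g1))
    }, numeric(1))
    out[col] <- mean(hs)
  }
  out
}

#' Value iteration on the grid MDP
#'
#' Solves the discounted MDP with the given per-(state, action) reward and the
#' deterministic grid transitions, iterating the Bellman optimality operator
#' until the sup-norm distance to the fixed point is below `vi_tolerance`
#' (iteration stops when the per-sweep change is below
#' `tolerance * (1 - discount) / discount`). The greedy policy breaks ties by
#' the fixed action order of [grid_actions()].
#'
#' @param reward `n_states` x 5 numeric matrix.
#' @param world A [grid_world()].
#' @param cfg A [planner_config()].
#' @param max_iter Iteration cap (error on non-convergence).
#' @return List with `value` (length `n_states`), `policy` (action index per
#'   state), and `iterations`.
#' @export
value_iteration <- function(reward, world, cfg = planner_config(),
                            max_iter = 100000L) {
  S <- world$n_states
  stopifnot(nrow(reward) == S, ncol(reward) == 5L)
  succ <- .successor_matrix(world)
  V <- numeric(S)
  gamma <- cfg$discount
  thr <- cfg$vi_tolerance * (1 - gamma) / gamma
  for (it in seq_len(max_iter)) {
    Q <- reward + gamma * matrix(V[succ], S, 5L)
    Vn <- do.call(pmax, as.data.frame(Q))
    delta <- max(abs(Vn - V))
    V <- Vn
    if (delta < thr) {
      policy <- max.col(Q, ties.method = "first")
      return(list(value = V, policy = policy, iterations = it))
    }
  }
  stop("value iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

# S x 5 matrix of successor state indices.
.successor_matrix <- function(world) {
  S <- world$n_states
  succ <- matrix(0L, S, 5L)
  for (s in seq_len(S)) {
    st <- index_state(world, s)
    for (a in 1:5)
      succ[s, a] <- state_index(world, grid_step(world, st, a))
  }
  succ
}

#' Select the next cursor action
#'
#' In the exploration regime (no decided goal) the action comes from the
#' value-iteration policy for the current uncertainty reward; once a goal is
#' decided the planner exploits greedily, returning the first optimal action
#' (in [grid_actions()] order) for the decided goal -- on the goal cell this is
#' the goal-reached action.
#'
#' @param world A [grid_world()].
#' @param state Current 0-based `(row, col)` state.
#' @param posterior A `task_posterior` (exploration regime).
#' @param tset The [task_set()] posterior was computed over.
#' @param decided `NULL`, or the 0-based `(row, col)` goal to exploit.
#' @param history Optional history for the sampled uncertainty term.
#' @param cfg A [planner_config()].
#' @return Action name (one of [grid_actions()]).
#' @export
select_action <- function(world, state, posterior, tset, decided = NULL,
                          history = NULL, cfg = planner_config()) {
  if (!is.null(decided)) return(optimal_actions(world, state, decided)[1L])
  if (cfg$epsilon_halflife > 0) {
    M <- if (is.null(history)) 0L else history_length(history)
    if (stats::runif(1) < exp(-M / cfg$epsilon_halflife))
      return(grid_actions()[sample.int(5L, 1L)])
  }
  reward <- uncertainty_reward(posterior, tset, history, cfg)
  vi <- value_iteration(reward, world, cfg)
  grid_actions()[vi$policy[state_index(world, state)]]
}
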