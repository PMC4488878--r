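#' Closed-loop experiment configuration
#'
#' Bundles everything one seeded run needs: the grid, the sequence of intended
#' goals, the step budget, the confidence threshold, decoder and planner
#' settings, and the synthetic signal generator standing in for the recording
#' pipeline.
#'
#' @param width,height Grid dimensions (default 5 x 5).
#' @param goals Goal sequence as an n x 2 matrix of 0-based `(row, col)`
#'   cells, cycled when the run outlives it. Default: a fixed documented
#'   tour of the four corners and the centre.
#' @param budget Total number of device actions (default 500).
#' @param beta Confidence threshold for deciding the goal, in `[0.5, 1]`
#'   (default 0.9).
#' @param lambda Covariance shrinkage for the supervised classifier and the
#'   power-ratio responsibilities (default 0.5).
#' @param generator A [signal_generator()] (default settings if omitted).
#' @param planner A [planner_config()]; its `beta` is kept in sync.
#' @param prior_strength Location-smoothing strength of the pseudo-
#'   likelihood's class means (pseudo-assessments at the pooled mean;
#'   default 20).
#' @param seed Integer seed for the run's single RNG stream.
#' @param start 0-based start cell (default: the grid centre).
#' @param max_targets Stop after this many reached targets (default `Inf`,
#'   i.e. run to budget).
#' @param power Apply the power correction in the task posterior.
#' @return Object of class `selfcal_config`.
#' @export
selfcal_config <- function(width = 5L, height = 5L, goals = NULL,
                           budget = 500L, beta = 0.9, lambda = 0.5,
                           generator = signal_generator(),
                           planner = planner_config(beta = beta),
                           prior_strength = NULL,
                           seed = 1L, start = NULL, max_targets = Inf,
                           power = TRUE) {
  if (is.null(goals))
    goals <- matrix(c(0L, 0L,
                      height - 1L, width - 1L,
                      0L, width - 1L,
                      height - 1L, 0L,
                      (height - 1L) %/% 2L, (width - 1L) %/% 2L),
                    ncol = 2L, byrow = TRUE)
  goals <- matrix(as.integer(goals), ncol = 2L)
  stopifnot(budget > 0, beta >= 0.5, beta <= 1)
  planner$beta <- beta
  if (is.null(start))
    start <- c((height - 1L) %/% 2L, (width - 1L) %/% 2L)
  structure(list(width = as.integer(width), height = as.integer(height),
                 goals = goals, budget = as.integer(budget), beta = beta,
                 lambda = lambda, generator = generator, planner = planner,
                 prior_strength = prior_strength,
                 seed = as.integer(seed), start = as.integer(start),
                 max_targets = max_targets, power = power),
            class = "selfcal_config")
}

.new_run_record <- function(steps, events, features, assigned, true_labels,
                            policy_labels, world, config, truncated = FALSE,
                            n_calib = 0L) {
  structure(list(steps = steps, events = events, features = features,
                 assigned = assigned, true_labels = true_labels,
                 policy_labels = policy_labels, world = world,
                 config = config, truncated = truncated, n_calib = n_calib),
            class = "selfcal_run")
}

#' Run a self-calibration experiment
#'
#' The full closed loop with no calibration phase: at each step the planner
#' picks an action (uncertainty-reward exploration, or greedy exploitation of
#' the decided goal), the simulated user assesses it and emits a signal, the
#' triplet is appended to the history, and the power-corrected task posterior
#' and decision confidence are recomputed. When the device performs the
#' goal-reached action on a decided goal, the target ends: the history is
#' labeled by the decided goal's optimal policy, transferred as fixed prior
#' data for subsequent targets, the posterior is reset, and the next goal in
#' the sequence becomes the user's intention. Once a goal is decided the
#' device exploits it until the target ends (the posterior is not revisited).
#'
#' @param config A [selfcal_config()].
#' @return A `selfcal_run` record: per-step log (`steps`), goal events
#'   (`events`), the feature matrix, self-assigned and true labels, and the
#'   configuration.
#' @export
run_selfcal_experiment <- function(config) {
  stopifnot(inherits(config, "selfcal_config"))
  set.seed(config$seed)
  world <- grid_world(config$width, config$height)
  tset <- task_set(world)
  gen <- config$generator
  d <- gen$d
  budget <- config$budget
  S <- world$n_states

  h <- selfcal_history(d)
  posterior <- uniform_posterior(tset)
  decided <- NULL
  cand <- NULL
  cand_task <- 0L
  cand_count <- 0L
  persistence <- config$planner$decision_persistence
  state <- config$start
  target_ix <- 1L
  user <- simulated_user(config$goals[1L, ], gen)
  seg_start <- 1L

  E_all <- matrix(NA_real_, budget, d)
  assigned <- rep(NA_integer_, budget)
  true_labels <- rep(NA_integer_, budget)
  policy_labels <- rep(NA_integer_, budget)
  st_row <- st_col <- integer(budget)
  act <- character(budget)
  mode <- character(budget)
  w_max <- numeric(budget)
  events <- list()
  n_steps <- 0L

  for (step in seq_len(budget)) {
    n_steps <- step
    provisional <- if (!is.null(decided)) decided else
      if (cand_count >= 1L) cand else NULL
    mode[step] <- if (is.null(decided)) {
      if (is.null(provisional)) "explore" else "verify"
    } else "exploit"
    action <- select_action(world, state, posterior, tset,
                            decided = provisional$goal, history = h,
                            cfg = config$planner)
    asmt <- assess(user, world, state, action)
    st_row[step] <- state[1L]; st_col[step] <- state[2L]
    act[step] <- action
    E_all[step, ] <- asmt$features
    true_labels[step] <- asmt$label
    policy_labels[step] <- asmt$policy_label
    h <- history_append(h, world, state, action, asmt$features)

    target_end <- !is.null(decided) && action == "goal" &&
      all(state == decided$goal)
    if (target_end) {
      correct <- all(state == user$goal)
      events[[length(events) + 1L]] <- data.frame(
        step = step, reached_row = state[1L], reached_col = state[2L],
        intended_row = user$goal[1L], intended_col = user$goal[2L],
        correct = correct)
      seg <- seg_start:step
      colcode <- (h$actions - 1L) * S + h$states
      assigned[seg] <- tset$labels[decided$index, colcode]
      h2 <- selfcal_history(d)
      h2$prior_n <- h$prior_n
      h2$prior_sum <- h$prior_sum
      h2$prior_ssq <- h$prior_ssq
      h2$prior_scatter <- h$prior_scatter
      h <- history_add_prior(h2, h$E, assigned[seg])
      posterior <- uniform_posterior(tset)
      decided <- NULL
      cand <- NULL
      cand_task <- 0L
      cand_count <- 0L
      w_max[step] <- NA_real_
      seg_start <- step + 1L
      target_ix <- target_ix + 1L
      if (length(events) >= config$max_targets) break
      user <- simulated_user(
        config$goals[((target_ix - 1L) %% nrow(config$goals)) + 1L, ], gen)
    } else {
      state <- grid_step(world, state, action)
      if (is.null(decided)) {
        posterior <- corrected_posterior(h, tset, lambda = config$lambda,
                                         power = config$power,
                                         prior_strength = config$prior_strength)
        cand_new <- decide(posterior, config$beta)
        if (is.null(cand_new)) {
          cand <- NULL
          cand_task <- 0L
          cand_count <- 0L
        } else if (cand_new$index == cand_task) {
          cand <- cand_new
          cand_count <- cand_count + 1L
        } else {
          cand <- cand_new
          cand_task <- cand_new$index
          cand_count <- 1L
        }
        if (cand_count >= persistence) decided <- cand
      }
      w_max[step] <- max(posterior$confidence)
    }
  }

  keep <- seq_len(n_steps)
  steps <- data.frame(step = keep, row = st_row[keep], col = st_col[keep],
                      action = act[keep], mode = mode[keep],
                      true_label = true_labels[keep],
                      policy_label = policy_labels[keep],
                      w_max = w_max[keep])
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), reached_row = integer(0),
               reached_col = integer(0), intended_row = integer(0),
               intended_col = integer(0), correct = logical(0))
  .new_run_record(steps, events, E_all[keep, , drop = FALSE], assigned[keep],
                  true_labels[keep], policy_labels[keep], world, config)
}

#' Run a calibrated (supervised) control experiment
#'
#' The baseline regime: a decoder is first fitted on labeled training signals,
#' then the recursive task filter controls the device. Before the confidence
#' threshold is met the cursor moves greedily toward the currently most
#' probable goal (never emitting the goal-reached action); once a goal's
#' confidence exceeds `beta` the device exploits it exactly as in the
#' self-calibrating regime. Signals come either from the configured generator
#' (simulated user) or from a replay `pool` of labeled held-out signals, from
#' which each step consumes the next unused signal whose true label matches
#' the user's assessment of the executed action.
#'
#' @param config A [selfcal_config()].
#' @param train_x,train_y Labeled training signals (matrix rows; labels 1/2),
#'   at least two per class.
#' @param pool Optional replay pool `list(features, labels)`; when exhausted
#'   the run stops and is flagged truncated.
#' @return A `selfcal_run` record (no self-assigned labels).
#' @export
run_calibrated_experiment <- function(config, train_x, train_y, pool = NULL) {
  stopifnot(inherits(config, "selfcal_config"))
  train_x <- as.matrix(train_x)
  if (sum(train_y == 1L) < 2L || sum(train_y == 2L) < 2L)
    stop("calibrated run needs at least two training signals per class",
         call. = FALSE)
  set.seed(config$seed)
  world <- grid_world(config$width, config$height)
  tset <- task_set(world)
  params <- decoder_params(lambda = config$lambda)
  model_c <- fit_class(train_x[train_y == 1L, , drop = FALSE], label = "correct")
  model_w <- fit_class(train_x[train_y == 2L, , drop = FALSE], label = "error")
  d <- ncol(train_x)
  budget <- config$budget

  posterior <- uniform_posterior(tset)
  decided <- NULL
  state <- config$start
  target_ix <- 1L
  intended <- config$goals[1L, ]
  pool_used <- if (!is.null(pool)) logical(length(pool$labels)) else NULL
  truncated <- FALSE

  E_all <- matrix(NA_real_, budget, d)
  true_labels <- rep(NA_integer_, budget)
  policy_labels <- rep(NA_integer_, budget)
  st_row <- st_col <- integer(budget)
  act <- character(budget)
  mode <- character(budget)
  w_max <- numeric(budget)
  events <- list()
  n_steps <- 0L

  for (step in seq_len(budget)) {
    mode_s <- if (is.null(decided)) "explore" else "exploit"
    if (!is.null(decided)) {
      action <- optimal_actions(world, state, decided$goal)[1L]
    } else {
      map_goal <- posterior$goals[which.max(posterior$scores), ]
      acts <- setdiff(optimal_actions(world, state, map_goal), "goal")
      if (!length(acts)) {
        # on the MAP goal but not yet confident: take the first movement
        # action that actually moves, to keep collecting evidence
        for (a in grid_actions()[1:4])
          if (!all(grid_step(world, state, a) == state)) { acts <- a; break }
      }
      action <- acts[1L]
    }
    p <- label_probability(world, state, action, intended)
    policy_lab <- if (p[1L] == 1) 1L else 2L
    lab <- policy_lab
    if (!is.null(pool)) {
      i <- which(!pool_used & pool$labels == lab)[1L]
      if (is.na(i)) { truncated <- TRUE; break }
      pool_used[i] <- TRUE
      e <- pool$features[i, ]
    } else {
      asmt <- assess(simulated_user(intended, config$generator), world,
                     state, action)
      e <- asmt$features
      lab <- asmt$label
    }
    n_steps <- step
    st_row[step] <- state[1L]; st_col[step] <- state[2L]
    act[step] <- action
    mode[step] <- mode_s
    E_all[step, ] <- e
    true_labels[step] <- lab
    policy_labels[step] <- policy_lab

    target_end <- !is.null(decided) && action == "goal" &&
      all(state == decided$goal)
    if (target_end) {
      events[[length(events) + 1L]] <- data.frame(
        step = step, reached_row = state[1L], reached_col = state[2L],
        intended_row = intended[1L], intended_col = intended[2L],
        correct = all(state == intended))
      posterior <- uniform_posterior(tset)
      decided <- NULL
      w_max[step] <- NA_real_
      target_ix <- target_ix + 1L
      if (length(events) >= config$max_targets) break
      intended <- config$goals[((target_ix - 1L) %% nrow(config$goals)) + 1L, ]
    } else {
      posterior <- calibrated_update(posterior, e, state, action, tset,
                                     model_c, model_w, params)
      if (is.null(decided)) decided <- decide(posterior, config$beta)
      w_max[step] <- max(posterior$confidence)
      state <- grid_step(world, state, action)
    }
  }

  keep <- seq_len(n_steps)
  steps <- data.frame(step = keep, row = st_row[keep], col = st_col[keep],
                      action = act[keep], mode = mode[keep],
                      true_label = true_labels[keep],
                      policy_label = policy_labels[keep],
                      w_max = w_max[keep])
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), reached_row = integer(0),
               reached_col = integer(0), intended_row = integer(0),
               intended_col = integer(0), correct = logical(0))
  .new_run_record(steps, events, E_all[keep, , drop = FALSE],
                  rep(NA_integer_, n_steps), true_labels[keep],
                  policy_labels[keep], world, config, truncated = truncated)
}

#' Write a per-step run log as delimited text
#'
#' @param run A `selfcal_run`.
#' @param path Output file (tab-separated).
#' @export
write_run_log <- function(run, path) {
  utils::write.table(run$steps, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.selfcal_run <- function(x, ...) {
  cat("<selfcal_run> ", nrow(x$steps), " steps, ", nrow(x$events),
      " target(s) reached (", sum(x$events$correct), " correct)",
      if (x$truncated) ", truncated" else "", "\n", sep = "")
  invisible(x)
}
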