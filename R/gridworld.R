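#' Grid-world environment for ErrP-based reaching
#'
#' A W x H grid of cells over which a virtual cursor moves. The cursor has five
#' instantaneous actions: move one cell up, down, left or right, plus a
#' goal-reached action that leaves the state unchanged. Transitions are
#' deterministic; moves that would exit the grid clamp (the state is
#' unchanged). Coordinates are 0-based `(row, col)` with row 0 at the top, so
#' `"up"` decreases the row index.
#'
#' @param width,height Grid dimensions (cells); the default 5 x 5 matches the
#'   reaching protocol the package simulates.
#' @return An object of class `grid_world` with fields `width`, `height` and
#'   `n_states`.
#' @examples
#' w <- grid_world()
#' grid_step(w, c(2, 2), "up")
#' @export
grid_world <- function(width = 5L, height = 5L) {
  width <- as.integer(width)
  height <- as.integer(height)
  stopifnot(length(width) == 1L, length(height) == 1L, width >= 1L, height >= 1L)
  structure(list(width = width, height = height,
                 n_states = width * height),
            class = "grid_world")
}

#' The five cursor actions
#'
#' Fixed order: `up`, `down`, `left`, `right`, `goal`. The order is also the
#' deterministic tie-break order used by the planner.
#'
#' @return Character vector of length 5.
#' @export
grid_actions <- function() c("up", "down", "left", "right", "goal")

.action_index <- function(action) {
  if (is.numeric(action)) {
    ai <- as.integer(action)
  } else {
    ai <- match(as.character(action), grid_actions())
  }
  if (length(ai) != 1L || is.na(ai) || ai < 1L || ai > 5L)
    stop("invalid action: ", paste(action, collapse = ","), call. = FALSE)
  ai
}

.check_state <- function(world, state) {
  if (length(state) != 2L || anyNA(state))
    stop("state must be a (row, col) pair", call. = FALSE)
  if (state[1L] < 0 || state[1L] >= world$height ||
      state[2L] < 0 || state[2L] >= world$width)
    stop("state (", state[1L], ",", state[2L], ") outside ",
         world$height, "x", world$width, " grid", call. = FALSE)
  invisible(state)
}

#' Convert between (row, col) states and linear indices
#'
#' Linear state indices are 1-based, row-major: `index = row * width + col + 1`.
#'
#' @param world A [grid_world()].
#' @param state 0-based `(row, col)` pair.
#' @param index 1-based linear state index.
#' @return `state_index()` returns an integer; `index_state()` a `(row, col)` pair.
#' @export
state_index <- function(world, state) {
  .check_state(world, state)
  as.integer(state[1L] * world$width + state[2L] + 1L)
}

#' @rdname state_index
#' @export
index_state <- function(world, index) {
  index <- as.integer(index)
  stopifnot(index >= 1L, index <= world$n_states)
  c((index - 1L) %/% world$width, (index - 1L) %% world$width)
}

#' Deterministic grid transition
#'
#' @inheritParams state_index
#' @param action One of [grid_actions()] (name or index 1..5).
#' @return Successor `(row, col)` state. The goal-reached action and clamped
#'   off-grid moves return the state unchanged.
#' @export
grid_step <- function(world, state, action) {
  .check_state(world, state)
  ai <- .action_index(action)
  r <- state[1L]; c <- state[2L]
  if (ai == 1L) r <- max(r - 1L, 0L)
  else if (ai == 2L) r <- min(r + 1L, world$height - 1L)
  else if (ai == 3L) c <- max(c - 1L, 0L)
  else if (ai == 4L) c <- min(c + 1L, world$width - 1L)
  c(r, c)
}

#' Optimal actions for a goal hypothesis
#'
#' On the goal cell the unique optimal action is `"goal"`; elsewhere every
#' movement action that strictly decreases the Manhattan distance to the goal
#' is optimal (one or two actions). The goal-reached action is never optimal
#' off-goal.
#'
#' @inheritParams state_index
#' @param goal 0-based `(row, col)` goal cell.
#' @return Character vector of optimal actions, in the fixed order of
#'   [grid_actions()].
#' @export
optimal_actions <- function(world, state, goal) {
  .check_state(world, state)
  .check_state(world, goal)
  if (state[1L] == goal[1L] && state[2L] == goal[2L]) return("goal")
  acts <- character(0)
  if (state[1L] > goal[1L]) acts <- c(acts, "up")
  if (state[1L] < goal[1L]) acts <- c(acts, "down")
  if (state[2L] > goal[2L]) acts <- c(acts, "left")
  if (state[2L] < goal[2L]) acts <- c(acts, "right")
  acts[order(match(acts, grid_actions()))]
}

#' Label probability of a (state, action) pair under a goal hypothesis
#'
#' The task-conditional label model: an action optimal for the hypothesized
#' goal elicits a correct assessment with probability 1, any other action an
#' error assessment with probability 1. Labels are hard because the user is
#' assumed to assess against the optimal policy; robustness to occasional
#' mis-assessments is delegated to the heavy-tailed signal likelihood, not to
#' label softening.
#'
#' @inheritParams optimal_actions
#' @param action One of [grid_actions()].
#' @return Named numeric pair `c(correct = , error = )` summing to 1.
#' @export
label_probability <- function(world, state, action, goal) {
  acts <- optimal_actions(world, state, goal)
  a <- grid_actions()[.action_index(action)]
  if (a %in% acts) c(correct = 1, error = 0) else c(correct = 0, error = 1)
}

#' All goal hypotheses of a grid
#'
#' One task hypothesis per cell, ordered by linear state index.
#'
#' @inheritParams state_index
#' @return A `n_states` x 2 integer matrix of 0-based `(row, col)` goals.
#' @export
all_tasks <- function(world) {
  idx <- seq_len(world$n_states)
  cbind(row = (idx - 1L) %/% world$width, col = (idx - 1L) %% world$width)
}

#' Label map of a single goal hypothesis
#'
#' @inheritParams optimal_actions
#' @return Logical `n_states` x 5 matrix: `TRUE` where the action is optimal
#'   (correct) for the goal, actions in [grid_actions()] order.
#' @export
task_label_map <- function(world, goal) {
  S <- world$n_states
  m <- matrix(FALSE, S, 5L, dimnames = list(NULL, grid_actions()))
  for (s in seq_len(S)) {
    st <- index_state(world, s)
    m[s, optimal_actions(world, st, goal)] <- TRUE
  }
  m
}

#' Set of task hypotheses with precomputed label maps
#'
#' Bundles a grid with a set of candidate goals and, for each, the labeling the
#' goal's optimal policy assigns to every (state, action) pair. This is the
#' object the task-inference and planning code consume.
#'
#' @inheritParams state_index
#' @param goals A T x 2 matrix of 0-based `(row, col)` goals (default: every
#'   cell).
#' @return An object of class `task_set` with fields `world`, `goals`
#'   (T x 2 matrix), and `labels`, a T x (n_states * 5) integer matrix holding
#'   1 (correct) or 2 (error) at column `(action - 1) * n_states + state`.
#' @export
task_set <- function(world, goals = all_tasks(world)) {
  goals <- matrix(as.integer(goals), ncol = 2L,
                  dimnames = list(NULL, c("row", "col")))
  T_ <- nrow(goals)
  S <- world$n_states
  lab <- matrix(2L, T_, S * 5L)
  for (t in seq_len(T_)) {
    m <- task_label_map(world, goals[t, ])
    lab[t, ] <- ifelse(as.vector(m), 1L, 2L)
  }
  structure(list(world = world, goals = goals, labels = lab,
                 n_tasks = T_), class = "task_set")
}

#' @export
print.grid_world <- function(x, ...) {
  cat("<grid_world> ", x$height, "x", x$width, " (", x$n_states,
      " states, 5 actions)\n", sep = "")
  invisible(x)
}

#' @export
print.task_set <- function(x, ...) {
  cat("<task_set> ", x$n_tasks, " goal hypotheses on a ",
      x$world$height, "x", x$world$width, " grid\n", sep = "")
  invisible(x)
}
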