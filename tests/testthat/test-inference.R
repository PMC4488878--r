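test_that("vectorized pseudo-likelihood equals the naive brute-force oracle", {
  set.seed(11)
  w2 <- grid_world(2, 2)
  for (trial in 1:6) {
    d <- sample(c(1L, 3L), 1L)
    M <- sample(c(4L, 9L, 20L), 1L)
    gen <- signal_generator(d = d, structure = "isotropic", accuracy = 0.8)
    h <- selfcal_history(d)
    # deliberately repeat (state, action) pairs so the pair-block path runs
    sts <- list(c(0, 0), c(0, 1), c(1, 0))
    for (i in seq_len(M))
      h <- history_append(h, w2, sts[[sample(3, 1)]],
                          sample(grid_actions()[c(1, 2, 5)], 1),
                          rnorm(d))
    if (trial >= 4)  # with prior-labeled data too
      h <- history_add_prior(h, matrix(rnorm(6 * d), 6, d),
                             c(1L, 1L, 1L, 2L, 2L, 2L))
    for (t in 1:4) {
      task <- index_state(w2, t)
      ref <- naive_task_scores(h, task, w2)
      expect_equal(pseudo_loglikelihood(h, task, w2), ref$plik,
                   tolerance = 1e-8)
      expect_equal(log(power_ratio(h, task, w2)), ref$log_power,
                   tolerance = 1e-8)
    }
  }
})

test_that("pseudo-likelihood is invariant to history order and feature rescaling", {
  set.seed(12)
  w <- grid_world(3, 3)
  gen <- signal_generator(d = 4, structure = "isotropic")
  h <- make_history(w, gen, c(0, 0), 15)
  task <- c(2, 1)
  base <- pseudo_loglikelihood(h, task, w)

  p <- sample(15)
  hp <- h
  hp$E <- h$E[p, , drop = FALSE]
  hp$states <- h$states[p]
  hp$actions <- h$actions[p]
  expect_equal(pseudo_loglikelihood(hp, task, w), base, tolerance = 1e-10)

  hs <- h
  hs$E <- h$E * 7.3
  expect_equal(pseudo_loglikelihood(hs, task, w), base, tolerance = 1e-8)
  # the power ratio is a ratio of powers, so it is scale-invariant as well
  expect_equal(power_ratio(hs, task, w), power_ratio(h, task, w),
               tolerance = 1e-8)
})

test_that("degenerate posteriors: single task, empty history", {
  w <- grid_world(1, 2)
  ts1 <- task_set(w, matrix(c(0L, 0L), 1))
  gen <- signal_generator(d = 2, structure = "isotropic")
  h <- make_history(w, gen, c(0, 0), 5, seed = 13)
  post <- corrected_posterior(h, ts1)
  expect_equal(post$scores, 1)
  expect_equal(post$confidence, 1)

  ts <- task_set(grid_world(5, 5))
  post0 <- corrected_posterior(selfcal_history(2), ts)
  expect_equal(post0$scores, rep(1 / 25, 25))
})

test_that("exactly label-complementary hypotheses tie in pseudo-likelihood", {
  # on a 1x2 grid, any history of left/right/goal actions is labeled in
  # exactly opposite ways by the two cell hypotheses
  w <- grid_world(2, 1)
  gen <- signal_generator(d = 3, structure = "isotropic", accuracy = 0.9)
  h <- make_symmetric_history(w, gen, c(0, 0), 12, seed = 14)
  lab <- function(task) {
    ts <- task_set(w, matrix(task, 1))
    ts$labels[1, (h$actions - 1L) * 2L + h$states]
  }
  expect_true(all(lab(c(0, 0)) != lab(c(0, 1))))
  expect_equal(pseudo_loglikelihood(h, c(0, 0), w),
               pseudo_loglikelihood(h, c(0, 1), w), tolerance = 1e-9)
})

test_that("power ratio reflects cluster energies and label swaps invert it", {
  w <- grid_world(1, 2)
  # hand-built: class clusters with mean powers ~1 and ~4, tiny spread,
  # labels of the goal-(0,0) hypothesis assign the high-power cluster to the
  # error class
  set.seed(15)
  h <- selfcal_history(1)
  for (i in 1:10) {  # at (0,0): "goal" is correct for task (0,0)
    h <- history_append(h, w, c(0, 0), "goal", 1 + rnorm(1, 0, 1e-3))
  }
  for (i in 1:10) {  # at (0,0): "down" is an error for task (0,0)
    h <- history_append(h, w, c(0, 0), "down", 2 + rnorm(1, 0, 1e-3))
  }
  r <- power_ratio(h, c(0, 0), w)
  expect_equal(r, 4, tolerance = 0.05)
  # the complementary hypothesis swaps the labels and inverts the ratio
  r2 <- power_ratio(h, c(1, 0), w)

  expect_equal(r2, 1 / r, tolerance = 1e-6)

  # identical signals: both class means of power coincide
  hi <- selfcal_history(1)
  for (i in 1:4) hi <- history_append(hi, w, c(0, 0), "goal", 1.5)
  for (i in 1:4) hi <- history_append(hi, w, c(0, 0), "down", 1.5)
  expect_equal(power_ratio(hi, c(0, 0), w), 1, tolerance = 1e-9)
})

test_that("power correction resolves label-symmetric hypotheses the right way", {
  w <- grid_world(2, 1)
  ts <- task_set(w)
  gen <- signal_generator(d = 4, power_gap = 3, structure = "isotropic",
                          assessment_error_rate = 0)
  wins <- 0L
  for (rep in 1:25) {
    h <- make_symmetric_history(w, gen, c(0, 0), 60, seed = 1500 + rep)
    post <- corrected_posterior(h, ts)
    wins <- wins + (which.max(post$scores) == state_index(w, c(0, 0)))
  }
  expect_equal(wins, 25L)
})

test_that("confidence is the minimum pairwise normalized likelihood", {
  ts <- task_set(grid_world(3, 1))
  lp <- log(c(0.9, 0.06, 0.04))
  post <- selfbci:::.new_task_posterior(lp, lp, ts)
  expect_equal(post$confidence[1], 0.9 / (0.9 + 0.06), tolerance = 1e-12)
  expect_equal(post$confidence[2], 0.06 / (0.06 + 0.9), tolerance = 1e-12)

  lp0 <- rep(log(1 / 3), 3)
  post0 <- selfbci:::.new_task_posterior(lp0, lp0, ts)
  expect_equal(post0$confidence, rep(0.5, 3))

  # monotone in the task's own score, rivals held fixed
  lp2 <- lp; lp2[1] <- lp[1] + 1
  post2 <- selfbci:::.new_task_posterior(lp2, lp2, ts)
  expect_gt(post2$confidence[1], post$confidence[1])
})

test_that("at most one task can exceed any beta > 1/2, and decide() finds it", {
  ts5 <- task_set(grid_world(5, 1))
  set.seed(16)
  for (rep in 1:1000) {
    lp <- rnorm(5, sd = 3)
    post <- selfbci:::.new_task_posterior(lp, lp, ts5)
    for (beta in c(0.5, 0.7, 0.9)) {
      over <- sum(post$confidence > beta)
      expect_lte(over, 1L)
      d <- decide(post, beta)
      if (over == 1L) {
        expect_equal(d$index, which.max(post$confidence))
      } else {
        expect_null(d)
      }
    }
  }
  # limit cases
  ts2 <- task_set(grid_world(2, 1))
  near <- selfbci:::.new_task_posterior(log(c(0.51, 0.49)), log(c(0.51, 0.49)), ts2)
  expect_equal(decide(near, 0.5)$index, 1L)
  expect_null(decide(near, 0.9))
  unif <- uniform_posterior(ts2)
  expect_null(decide(unif, 0.51))
  expect_null(decide(near, 1))
})

test_that("calibrated filter reproduces a hand-computed two-step Bayes update", {
  w <- grid_world(1, 2)
  ts <- task_set(w)   # goals (0,0) and (1,0)
  # fixed, well-conditioned 1-D class models
  mc <- list(mean = 0, cov = matrix(1), n = 50)
  mw <- list(mean = 2, cov = matrix(1), n = 50)
  params <- decoder_params(lambda = 0)
  gd <- function(e, mu) stats::dnorm(e, mu, 1)
  # step 1: at (0,0) action "down"; task (0,0) labels it error, (1,0) correct
  # step 2: at (1,0) action "up"; task (0,0) labels it correct, (1,0) error
  e1 <- 1.7; e2 <- -0.4
  post <- calibrated_update(NULL, e1, c(0, 0), "down", ts, mc, mw, params)
  post <- calibrated_update(post, e2, c(1, 0), "up", ts, mc, mw, params)
  lik_t1 <- gd(e1, 2) * gd(e2, 0)   # goal (0,0)
  lik_t2 <- gd(e1, 0) * gd(e2, 2)   # goal (1,0)
  expect_equal(post$scores, c(lik_t1, lik_t2) / (lik_t1 + lik_t2),
               tolerance = 1e-12)
})

test_that("a task contradicted by every confident signal loses all mass", {
  w <- grid_world(1, 2)
  ts <- task_set(w)
  mc <- list(mean = -4, cov = matrix(1), n = 50)
  mw <- list(mean = 4, cov = matrix(1), n = 50)
  post <- NULL
  set.seed(17)
  for (i in 1:10)  # all signals are clearly "error" at ((0,0), goal):
    post <- calibrated_update(post, 4 + rnorm(1, 0, 0.1), c(0, 0), "goal",
                              ts, mc, mw)
  # task (0,0) calls goal-at-(0,0) correct, so it is contradicted each step
  expect_lt(post$scores[state_index(w, c(0, 0))], 1e-6)
})

test_that("the task argmax recovers the generating goal under strong signals", {
  w <- grid_world()
  ts <- task_set(w)
  gen <- signal_generator(accuracy = 0.95, assessment_error_rate = 0)
  hits <- 0L
  for (rep in 1:10) {
    h <- make_history(w, gen, c(0, 0), 80, seed = 1700 + rep)
    post <- corrected_posterior(h, ts)
    hits <- hits + (which.max(post$scores) == state_index(w, c(0, 0)))
  }
  expect_gte(hits, 9L)
})
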