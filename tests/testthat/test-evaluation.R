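fake_run <- function(true_labels, assigned = true_labels, events = NULL,
                     features = NULL, n_calib = 0L) {
  n <- length(true_labels)
  if (is.null(events))
    events <- data.frame(step = integer(0), reached_row = integer(0),
                         reached_col = integer(0), intended_row = integer(0),
                         intended_col = integer(0), correct = logical(0))
  if (is.null(features)) features <- matrix(0, n, 2)
  structure(list(steps = data.frame(step = seq_len(n)), events = events,
                 features = features, assigned = assigned,
                 true_labels = true_labels, policy_labels = true_labels,
                 world = grid_world(), config = NULL, truncated = FALSE,
                 n_calib = n_calib),
            class = "selfcal_run")
}

test_that("task metrics count goal events and credit calibration trials", {
  ev <- data.frame(step = c(101, seq(120, 500, length.out = 17))[1:18],
                   reached_row = 0, reached_col = 0,
                   intended_row = 0, intended_col = 0,
                   correct = c(rep(TRUE, 8), FALSE, rep(TRUE, 8), FALSE))
  run <- fake_run(rep(1L, 500), events = ev)
  tm <- task_metrics(run)
  expect_equal(tm$steps_to_first_target, 101)
  expect_equal(tm$n_correct_targets, 16)
  expect_equal(tm$n_incorrect_targets, 2)

  none <- fake_run(rep(1L, 10))
  expect_true(is.na(task_metrics(none)$steps_to_first_target))
  expect_equal(task_metrics(none)$n_correct_targets, 0)

  cal <- fake_run(rep(1L, 20), events = ev[1, ], n_calib = 200L)
  expect_equal(task_metrics(cal)$steps_to_first_target, 301)
})

test_that("moving-average error rate uses a window of 10 with partial prefix", {
  expect_equal(instantaneous_error_rate(rep(1L, 30)), rep(0, 30))
  alt <- instantaneous_error_rate(rep(c(1L, 2L), 10))
  expect_equal(alt[10:20], rep(0.5, 11))
  # hand-computed series for a 15-step label sequence
  labs <- c(2, 2, 1, 2, 1, 1, 2, 2, 1, 1, 1, 2, 1, 1, 1)
  err <- as.numeric(labs == 2)
  ref <- vapply(seq_along(labs), function(i) {
    lo <- max(1, i - 9)
    mean(err[lo:i])
  }, numeric(1))
  expect_equal(instantaneous_error_rate(labs), ref)
  # window argument
  expect_equal(instantaneous_error_rate(labs, window = 1), err)
})

test_that("ten-fold accuracy separates separable data and not shuffled labels", {
  set.seed(41)
  g <- signal_generator(d = 4, accuracy = 0.999, structure = "isotropic",
                        assessment_error_rate = 0)
  x <- rbind(sample_signal(60, 1, g), sample_signal(60, 2, g))
  y <- rep(1:2, each = 60)
  expect_gt(tenfold_accuracy(x, y), 0.98)
  ysh <- sample(y)
  expect_lt(abs(tenfold_accuracy(x, ysh) - 0.5), 0.12)
  expect_error(tenfold_accuracy(x[1:12, ], y[1:12]), "10 samples per class")
})

test_that("label quality compares assigned labels to the truth", {
  set.seed(42)
  g <- signal_generator(d = 4, accuracy = 0.9, structure = "isotropic")
  y <- rep(1:2, 30)
  x <- matrix(0, 60, 4)
  for (i in 1:60) x[i, ] <- sample_signal(1, y[i], g)
  run <- fake_run(y, assigned = y, features = x)
  lq <- label_quality(run)
  expect_equal(lq$pct_labels_correct, 100)
  expect_equal(lq$acc_cv_true, lq$acc_cv_learned)

  flipped <- y
  flipped[1:6] <- 3L - flipped[1:6]
  lq2 <- label_quality(fake_run(y, assigned = flipped, features = x))
  expect_equal(lq2$pct_labels_correct, 100 * 54 / 60)

  expect_error(label_quality(fake_run(y, assigned = rep(NA_integer_, 60))),
               "completed target")
})

test_that("plateau rule: first run of five values within tolerance of the running max", {
  acc <- c(0.6, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7)
  expect_equal(selfbci:::.plateau_index(acc, 0, 5), 2L)
  rising <- seq(0.5, 0.9, by = 0.05)
  expect_true(is.na(selfbci:::.plateau_index(rising, 0, 5)))
  expect_equal(selfbci:::.plateau_index(rising, 1, 5), 1L)
})

test_that("calibration curve reaches 1 on separable data and chance on noise", {
  set.seed(43)
  g <- signal_generator(d = 3, accuracy = 0.9999, structure = "isotropic",
                        assessment_error_rate = 0)
  y <- rep(1:2, 75)
  x <- matrix(0, 150, 3)
  for (i in seq_along(y)) x[i, ] <- sample_signal(1, y[i], g)
  cc <- calibration_curve(x, y, train_size = 100, test_size = 50,
                          n_shuffles = 3)
  expect_gt(min(cc$accuracy), 0.97)
  expect_equal(cc$n_plateau, cc$n[1])

  ysh <- sample(y)
  cc2 <- calibration_curve(x, ysh, train_size = 100, test_size = 50,
                           n_shuffles = 3)
  expect_lt(mean(cc2$accuracy), 0.65)

  expect_error(calibration_curve(x, y, train_size = 300, test_size = 200),
               "at least")
})

test_that("simulated supervised control replays held-out signals reproducibly", {
  set.seed(44)
  g <- signal_generator(d = 4, accuracy = 0.995, structure = "isotropic",
                        assessment_error_rate = 0)
  y <- rep(1:2, 400)
  x <- matrix(0, 800, 4)
  for (i in seq_along(y)) x[i, ] <- sample_signal(1, y[i], g)
  cfg <- selfcal_config(budget = 120L, max_targets = 2L,
                        generator = signal_generator(d = 4))
  out <- simulated_supervised_control(x, y, cfg, n_calib = 40, n_runs = 3,
                                      seed = 5)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$steps_first > 40 | is.na(out$steps_first)))
  out2 <- simulated_supervised_control(x, y, cfg, n_calib = 40, n_runs = 3,
                                       seed = 5)
  expect_identical(out, out2)
  # with a near-perfect decoder the replays reach correct targets
  expect_gt(sum(out$n_correct), 0)
})
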