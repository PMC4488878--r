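#' Task metrics of a run
#'
#' @param run A `selfcal_run`.
#' @return List with `steps_to_first_target` (step index of the first goal
#'   event plus any supervised calibration trials charged to the run; `NA`
#'   when no target was reached), `n_correct_targets` and
#'   `n_incorrect_targets`.
#' @export
task_metrics <- function(run) {
  ev <- run$events
  list(
    steps_to_first_target =
      if (nrow(ev)) ev$step[1L] + run$n_calib else NA_integer_,
    n_correct_targets = sum(ev$correct),
    n_incorrect_targets = sum(!ev$correct))
}

#' Moving-average instantaneous error rate
#'
#' At step i, the fraction of error assessments among the last `window`
#' actions; the first `window - 1` steps use the partial prefix.
#'
#' @param x A `selfcal_run`, or an integer label vector (1 = correct,
#'   2 = error).
#' @param window Moving-average window (default 10 actions).
#' @return Numeric series, one value per step.
#' @export
instantaneous_error_rate <- function(x, window = 10L) {
  stopifnot(window >= 1L)
  labs <- if (inherits(x, "selfcal_run")) x$true_labels else as.integer(x)
  err <- as.numeric(labs == 2L)
  cs <- cumsum(err)
  n <- length(err)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Stratified ten-fold cross-validated accuracy of the Gaussian classifier
#'
#' @param x Feature matrix (rows).
#' @param y Integer labels (1/2).
#' @param lambda Covariance shrinkage (default 0.5).
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Mean held-out accuracy.
#' @export
tenfold_accuracy <- function(x, y, lambda = 0.5, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (min(table(factor(y, levels = 1:2))) < folds)
    stop("need at least ", folds, " samples per class for ", folds,
         "-fold cross-validation", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (k in 1:2) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  params <- decoder_params(lambda = lambda)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    mc <- fit_class(x[tr & y == 1L, , drop = FALSE])
    mw <- fit_class(x[tr & y == 2L, , drop = FALSE])
    post <- class_posterior(x[!tr, , drop = FALSE], mc, mw, params)
    if (is.null(dim(post))) post <- matrix(post, 1L)
    pred <- 1L + (post[, 2L] > 0.5)
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Label quality of a finished self-calibration run
#'
#' Compares the labels the self-calibration assigned (via each decided goal's
#' optimal policy) with the true labels of the emitted signals, over the steps
#' belonging to completed targets, and reports the ten-fold accuracy of the
#' supervised classifier trained under each labeling.
#'
#' @param run A `selfcal_run` with at least one completed target.
#' @param lambda Shrinkage for the classifier.
#' @param seed Fold seed.
#' @return List with `pct_labels_correct` (percent), `acc_cv_true` and
#'   `acc_cv_learned`.
#' @export
label_quality <- function(run, lambda = 0.5, seed = 1L) {
  ok <- !is.na(run$assigned)
  if (!any(ok))
    stop("label_quality needs a run with at least one completed target",
         call. = FALSE)
  assigned <- run$assigned[ok]
  truth <- run$true_labels[ok]
  x <- run$features[ok, , drop = FALSE]
  list(
    pct_labels_correct = 100 * mean(assigned == truth),
    acc_cv_true = tenfold_accuracy(x, truth, lambda, seed = seed),
    acc_cv_learned = tenfold_accuracy(x, assigned, lambda, seed = seed))
}

#' Incremental-calibration accuracy curve and plateau
#'
#' Splits the data into a training pool and a fixed held-out test set, trains
#' the supervised classifier on an increasing number of trials, and reports
#' the test accuracy averaged over shuffles. The number of trials needed for
#' calibration is the first point from which the mean accuracy stays within
#' `tolerance` of its running maximum for at least `plateau_len` consecutive
#' increments.
#'
#' @param x Feature matrix.
#' @param y Integer labels (1/2).
#' @param train_size,test_size Pool sizes (defaults 300 / 200).
#' @param n_shuffles Number of random reshuffles averaged over (default 10).
#' @param lambda Shrinkage.
#' @param tolerance Plateau tolerance on accuracy (default 0.01, i.e. one
#'   percentage point of the running maximum).
#' @param plateau_len Consecutive increments required (default 5).
#' @param seed Seed for the shuffles.
#' @return List with `n` (trial counts), `accuracy` (mean over shuffles),
#'   `sd`, `n_plateau` and `plateau_accuracy`.
#' @export
calibration_curve <- function(x, y, train_size = 300L, test_size = 200L,
                              n_shuffles = 10L, lambda = 0.5,
                              tolerance = 0.01, plateau_len = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) < train_size + test_size)
    stop("calibration_curve needs at least train_size + test_size = ",
         train_size + test_size, " trials (got ", nrow(x), ")", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- decoder_params(lambda = lambda)
  acc <- NULL
  ns <- NULL
  for (sh in seq_len(n_shuffles)) {
    p <- sample(nrow(x))
    tr <- p[seq_len(train_size)]
    te <- p[train_size + seq_len(test_size)]
    ytr <- y[tr]
    # first n at which both classes have >= 2 trials
    n_min <- max(which(cumsum(ytr == 1L) >= 2L)[1L],
                 which(cumsum(ytr == 2L) >= 2L)[1L])
    if (is.na(n_min))
      stop("a shuffle left a class with fewer than 2 training trials",
           call. = FALSE)
    nseq <- n_min:train_size
    if (is.null(ns)) {
      ns <- nseq
      acc <- matrix(NA_real_, n_shuffles, length(nseq))
    } else if (nseq[1L] < ns[1L]) {
      extra <- nseq[1L]:(ns[1L] - 1L)
      acc <- cbind(matrix(NA_real_, n_shuffles, length(extra)), acc)
      ns <- c(extra, ns)
    }
    for (n in nseq) {
      sub <- tr[seq_len(n)]
      mc <- fit_class(x[sub[y[sub] == 1L], , drop = FALSE])
      mw <- fit_class(x[sub[y[sub] == 2L], , drop = FALSE])
      post <- class_posterior(x[te, , drop = FALSE], mc, mw, params)
      pred <- 1L + (post[, 2L] > 0.5)
      acc[sh, match(n, ns)] <- mean(pred == y[te])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  keep <- !is.nan(mean_acc)
  ns <- ns[keep]; mean_acc <- mean_acc[keep]
  sd_acc <- apply(acc[, keep, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  np <- .plateau_index(mean_acc, tolerance, plateau_len)
  list(n = ns, accuracy = mean_acc, sd = sd_acc,
       n_plateau = if (is.na(np)) NA_integer_ else ns[np],
       plateau_accuracy = if (is.na(np)) NA_real_ else mean_acc[np])
}

# First index i such that the len consecutive values starting at i all stay
# within tol of the maximum accuracy seen up to the end of that window (the
# accuracy has stopped improving).
.plateau_index <- function(acc, tol, len) {
  n <- length(acc)
  if (n < len) return(NA_integer_)
  for (i in seq_len(n - len + 1L)) {
    m <- max(acc[seq_len(i + len - 1L)])
    if (all(acc[i:(i + len - 1L)] >= m - tol - 1e-12)) return(i)
  }
  NA_integer_
}

#' Simulated supervised-control comparison
#'
#' The offline baseline: repeatedly (i) shuffle the labeled dataset,
#' (ii) train the supervised classifier on the first `n_calib` trials,
#' (iii) replay the calibrated control loop consuming the remaining signals as
#' the replay pool, and collect the task metrics. Steps to the first target
#' are charged the `n_calib` calibration trials.
#'
#' @param x Feature matrix.
#' @param y Integer labels (1/2).
#' @param config A [selfcal_config()] describing the control task.
#' @param n_calib Number of calibration trials (drawn stratified by class,
#'   at least two per class).
#' @param n_runs Number of replays (default 100).
#' @param seed Base seed; run r uses `seed + r`.
#' @return Data frame, one row per run: `steps_first`, `n_correct`,
#'   `n_incorrect`, `truncated`.
#' @export
simulated_supervised_control <- function(x, y, config, n_calib,
                                         n_runs = 100L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(n_calib >= 4L, n_calib < nrow(x))
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    # stratified calibration draw: proportional per class, at least 2 each,
    # so the classifier is always fittable
    n2 <- max(2L, min(round(n_calib * mean(y == 2L)), n_calib - 2L))
    n1 <- n_calib - n2
    i1 <- sample(which(y == 1L)); i2 <- sample(which(y == 2L))
    if (length(i1) < n1 + 1L || length(i2) < n2 + 1L)
      stop("not enough trials of each class for n_calib = ", n_calib,
           call. = FALSE)
    tr <- c(i1[seq_len(n1)], i2[seq_len(n2)])
    rest <- sample(setdiff(seq_len(nrow(x)), tr))
    cfg <- config
    cfg$seed <- seed + r
    run <- run_calibrated_experiment(
      cfg, x[tr, , drop = FALSE], y[tr],
      pool = list(features = x[rest, , drop = FALSE], labels = y[rest]))
    run$n_calib <- n_calib
    tm <- task_metrics(run)
    out[[r]] <- data.frame(steps_first = tm$steps_to_first_target,
                           n_correct = tm$n_correct_targets,
                           n_incorrect = tm$n_incorrect_targets,
                           truncated = run$truncated)
  }
  do.call(rbind, out)
}
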