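# Independent, deliberately naive implementation of the task-scoring rule the
# package documents, used as the brute-force oracle for the vectorized
# engine: shared shrunk pooled covariance, whitening, conjugate-damped class
# means, leave-one-pair-out locations for scored signals, logistic label
# posteriors, and the responsibility-weighted power ratio.
naive_task_scores <- function(h, task, world, lambda = 0.5, k0 = 20) {
  E <- h$E
  M <- nrow(E)
  d <- ncol(E)
  lab <- vapply(seq_len(M), function(i) {
    st <- index_state(world, h$states[i])
    p <- label_probability(world, st, grid_actions()[h$actions[i]], task)
    if (p[1] == 1) 1L else 2L
  }, integer(1))
  tot_n <- sum(h$prior_n) + M
  tot_sum <- rowSums(h$prior_sum) + colSums(E)
  m0 <- tot_sum / tot_n
  Stot <- crossprod(E) + h$prior_scatter[[1]] + h$prior_scatter[[2]]
  covp <- (Stot - tot_n * tcrossprod(m0)) / (tot_n - 1)
  covp <- shrink_cov((covp + t(covp)) / 2, lambda)
  if (sum(diag(covp)) <= 0) covp <- diag(d)
  R <- chol(covp)
  wh <- function(x) backsolve(R, x, transpose = TRUE)
  Ew <- t(apply(E, 1, wh))
  if (d == 1) Ew <- matrix(Ew, ncol = 1)
  m0w <- wh(m0)
  pw <- list(wh(h$prior_sum[, 1]), wh(h$prior_sum[, 2]))
  pair <- (h$actions - 1L) * world$n_states + h$states
  score <- function(i, k) {
    mem <- which(lab == k)
    n_k <- h$prior_n[k] + length(mem)
    v <- k0 * m0w + pw[[k]] + colSums(Ew[mem, , drop = FALSE])
    if (i %in% mem) {
      drop <- mem[pair[mem] == pair[i]]
      v <- v - colSums(Ew[drop, , drop = FALSE])
      n_k <- n_k - length(drop)
    }
    loc <- v / (k0 + n_k)
    -0.5 * sum((Ew[i, ] - loc)^2)
  }
  plik <- 0
  for (i in seq_len(M)) {
    l1 <- score(i, 1L); l2 <- score(i, 2L)
    den <- max(l1, l2) + log1p(exp(-abs(l1 - l2)))
    plik <- plik + (if (lab[i] == 1L) l1 else l2) - den
  }
  # power ratio: per-class lambda-shrunk Gaussian responsibilities over the
  # current signals, class moments including prior data
  stat <- function(k) {
    mem <- which(lab == k)
    n <- h$prior_n[k] + length(mem)
    sm <- h$prior_sum[, k] + colSums(E[mem, , drop = FALSE])
    S <- h$prior_scatter[[k]] + crossprod(E[mem, , drop = FALSE])
    list(n = n, mu = sm / n,
         C = if (n >= 2) (S - n * tcrossprod(sm / n)) / (n - 1) else NULL)
  }
  s1 <- stat(1L); s2 <- stat(2L)
  pow <- rowSums(E^2)
  log_power <- 0
  if (s1$n >= 2 && s2$n >= 2 &&
      sum(diag(s1$C)) > 0 && sum(diag(s2$C)) > 0) {
    g1 <- selfbci:::.gauss_logdens(E, s1$mu, shrink_cov((s1$C + t(s1$C)) / 2, lambda))
    g2 <- selfbci:::.gauss_logdens(E, s2$mu, shrink_cov((s2$C + t(s2$C)) / 2, lambda))
    rw <- stats::plogis(g2 - g1)
    sw <- sum(rw); sc <- sum(1 - rw)
    if (sw > 1e-12 && sc > 1e-12)
      log_power <- log(sum(rw * pow) / sw) - log(sum((1 - rw) * pow) / sc)
  }
  list(plik = plik, log_power = log_power)
}

# random-walk history generated under a known intended goal
make_history <- function(world, gen, goal, M, start = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start))
    start <- c((world$height - 1L) %/% 2L, (world$width - 1L) %/% 2L)
  h <- selfcal_history(gen$d)
  st <- start
  for (i in seq_len(M)) {
    a <- sample(grid_actions(), 1L)
    p <- label_probability(world, st, a, goal)
    lab <- if (p[1] == 1) 1L else 2L
    h <- history_append(h, world, st, a,
                        as.numeric(sample_signal(1L, lab, gen)))
    st <- grid_step(world, st, a)
  }
  h
}

# history on a 1x2 (two-cell) grid using only the goal-reached action and the
# move toward the other cell, so the two cell hypotheses label every visited
# pair in exactly opposite ways (clamped moves would be errors under both)
make_symmetric_history <- function(world, gen, goal, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- selfcal_history(gen$d)
  st <- c(0, 0)
  for (i in seq_len(M)) {
    mv <- if (st[2] == 0) "right" else "left"
    a <- sample(c(mv, "goal"), 1L)
    p <- label_probability(world, st, a, goal)
    lab <- if (p[1] == 1) 1L else 2L
    h <- history_append(h, world, st, a,
                        as.numeric(sample_signal(1L, lab, gen)))
    st <- grid_step(world, st, a)
  }
  h
}
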