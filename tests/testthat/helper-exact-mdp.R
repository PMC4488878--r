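# exact optimal value/policy by Howard policy iteration with linear-solve
# policy evaluation (independent of the value-iteration code path)
policy_iteration_exact <- function(reward, world, gamma) {
  S <- world$n_states
  succ <- selfbci:::.successor_matrix(world)
  evaluate <- function(pol) {
    P <- matrix(0, S, S)
    for (s in seq_len(S)) P[s, succ[s, pol[s]]] <- 1
    r <- reward[cbind(seq_len(S), pol)]
    solve(diag(S) - gamma * P, r)
  }
  pol <- rep(1L, S)
  repeat {
    V <- evaluate(pol)
    Q <- reward + gamma * matrix(V[succ], S, 5L)
    newpol <- max.col(Q, ties.method = "first")
    if (all(newpol == pol)) return(list(value = V, policy = pol))
    pol <- newpol
  }
}

# exact optimum by exhaustive enumeration of all stationary policies
enumerate_exact <- function(reward, world, gamma) {
  S <- world$n_states
  succ <- selfbci:::.successor_matrix(world)
  best <- rep(-Inf, S)
  grid <- as.matrix(expand.grid(rep(list(1:5), S)))
  for (i in seq_len(nrow(grid))) {
    pol <- grid[i, ]
    P <- matrix(0, S, S)
    for (s in seq_len(S)) P[s, succ[s, pol[s]]] <- 1
    V <- solve(diag(S) - gamma * P, reward[cbind(seq_len(S), pol)])
    best <- pmax(best, V)
  }
  best
}

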