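# Shared fixtures: tiny hand-built networks, a fabricated trace builder,
# and an exact Markov-chain oracle for the synchronous dynamics.

two_node_net <- function(w = 1.5, tau = c(-1, -1)) {
  W <- matrix(c(0, w, w, 0), 2, 2)
  symptom_network(W, tau)
}

zero_net <- function(J, tau = rep(0, J)) {
  symptom_network(matrix(0, J, J), tau)
}

# The reference synthetic 14-symptom system used across the qualitative
# replication tests: one fixed draw from the generator defaults.
reference_net <- function() random_network(generator_spec(seed = 101))

# Fabricate a sim_trace with a prescribed D sequence (first D[t] symptoms
# active at step t), stress values and sweep directions.
fake_trace <- function(D, stress = rep(0, length(D)),
                       direction = rep("up", length(D)), J = max(D, 1)) {
  n <- length(D)
  states <- t(vapply(D, function(d) c(rep(1L, d), rep(0L, J - d)),
                     integer(J)))
  labels <- paste0("S", seq_len(J))
  out <- data.frame(t = seq_len(n), stress = stress, D = D)
  st <- as.data.frame(states); names(st) <- labels
  out <- cbind(out, st)
  attr(out, "labels") <- labels
  attr(out, "direction") <- direction
  class(out) <- c("sim_trace", "data.frame")
  out
}

# Independent oracle: exact stationary distribution of the synchronous
# update chain by full 2^J enumeration and power iteration.
all_states <- function(J) {
  as.matrix(expand.grid(rep(list(0:1), J)))
}

sync_transition_matrix <- function(net, connectivity = 1, b_mode = "abs",
                                   stress = 0) {
  S <- all_states(net$J)
  b <- threshold_to_b(net$thresholds, b_mode)
  n <- nrow(S)
  P <- matrix(0, n, n)
  for (r in seq_len(n)) {
    p <- plogis(connectivity * as.numeric(net$weights %*% S[r, ]) +
                  stress - b)
    for (cc in seq_len(n))
      P[r, cc] <- prod(ifelse(S[cc, ] == 1, p, 1 - p))
  }
  P
}

stationary_distribution <- function(P, iters = 2000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# Map a trace's state rows onto enumeration indices of all_states(J).
state_index <- function(states_matrix) {
  as.integer(states_matrix %*% 2^(seq_len(ncol(states_matrix)) - 1)) + 1L
}
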