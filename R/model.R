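#' Simulation configuration
#'
#' Bundles the tunables of the stochastic symptom dynamics. Connectivity
#' \code{c} is a global multiplier of the weight matrix: the model's
#' operationalisation of network vulnerability. The activation probability
#' of symptom i uses a per-symptom barrier \code{b_i} derived from its
#' threshold; by default \code{b_i = |tau_i|} (\code{b_mode = "abs"}),
#' with \code{b_mode = "neg"} (\code{b_i = -tau_i}, the conventional Ising
#' reading where negative thresholds mean a preference for 'off')
#' available as an alternative.
#'
#' @param connectivity positive scalar c multiplying the weight matrix.
#' @param n_steps number of time points to simulate (>= 1).
#' @param b_mode \code{"abs"} (default) or \code{"neg"}; how thresholds
#'   map to the probability-function parameter b.
#' @param initial_state optional 0/1 vector of length J; default all off.
#' @param update \code{"synchronous"} (default: every symptom resampled
#'   each step from the previous state) or \code{"asynchronous"} (one
#'   uniformly chosen symptom resampled per step), the latter provided as
#'   a robustness check.
#' @param seed optional integer RNG seed; with a fixed seed a simulation
#'   is reproducible bit for bit.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(connectivity = 1, n_steps = 10000,
                       b_mode = c("abs", "neg"), initial_state = NULL,
                       update = c("synchronous", "asynchronous"),
                       seed = NULL) {
  if (!is.numeric(connectivity) || length(connectivity) != 1 ||
      connectivity <= 0)
    stop("`connectivity` must be a positive scalar", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1)
    stop("`n_steps` must be >= 1", call. = FALSE)
  structure(list(connectivity = connectivity, n_steps = n_steps,
                 b_mode = match.arg(b_mode),
                 initial_state = initial_state,
                 update = match.arg(update), seed = seed),
            class = "sim_config")
}

#' Map thresholds to the probability-function barrier b
#'
#' @param thresholds numeric vector of estimated thresholds tau.
#' @param b_mode \code{"abs"} for \code{b = |tau|}; \code{"neg"} for
#'   \code{b = -tau}.
#' @return numeric vector b.
#' @export
threshold_to_b <- function(thresholds, b_mode = c("abs", "neg")) {
  switch(match.arg(b_mode), abs = abs(thresholds), neg = -thresholds)
}

#' Total activation of each symptom
#'
#' The total activation of symptom i at time t is the connectivity-scaled,
#' weight-weighted sum of its neighbours' activity at time t-1, plus any
#' external stress applied to it:
#' \deqn{A_i = c \sum_j w_{ij} x_j + S_i.}
#'
#' @param net a \code{symptom_network}.
#' @param x_prev 0/1 state vector at the previous time point, length J.
#' @param connectivity positive scalar c.
#' @param stress numeric stress vector S, length J (or a scalar recycled
#'   to all symptoms). Zero reproduces the stress-free dynamics.
#' @return numeric activation vector of length J.
#' @export
total_activation <- function(net, x_prev, connectivity = 1, stress = 0) {
  stopifnot(inherits(net, "symptom_network"))
  if (length(x_prev) != net$J)
    stop(sprintf("state vector has length %d, expected J = %d",
                 length(x_prev), net$J), call. = FALSE)
  if (!all(x_prev %in% c(0, 1)))
    stop("state vector must be binary 0/1", call. = FALSE)
  if (length(stress) == 1) stress <- rep(stress, net$J)
  if (length(stress) != net$J)
    stop(sprintf("stress vector has length %d, expected J = %d",
                 length(stress), net$J), call. = FALSE)
  as.numeric(connectivity * (net$weights %*% x_prev) + stress)
}

#' Probability of each symptom becoming active
#'
#' The logistic probability function
#' \deqn{P(X_i = 1) = 1 / (1 + e^{b_i - A_i}),}
#' evaluated through \code{plogis} so that arbitrarily extreme arguments
#' saturate cleanly at 0 or 1 instead of overflowing.
#'
#' @param activation numeric total-activation vector A.
#' @param b numeric barrier vector (see \code{\link{threshold_to_b}}).
#' @return probability vector in [0, 1].
#' @export
activation_probability <- function(activation, b) {
  if (length(activation) != length(b))
    stop(sprintf("activation has length %d but b has length %d",
                 length(activation), length(b)), call. = FALSE)
  stats::plogis(activation - b)
}

#' Advance the symptom system one time step
#'
#' Computes total activation and activation probabilities from the
#' current state, then resamples symptoms as independent Bernoulli draws.
#' Under the default synchronous scheme all J symptoms are resampled
#' simultaneously; draws are consumed in fixed node order 1..J so traces
#' are reproducible under a fixed RNG state.
#'
#' @param net a \code{symptom_network}.
#' @param x 0/1 state vector at time t.
#' @param b barrier vector.
#' @param connectivity scalar c.
#' @param stress stress vector or scalar for this step.
#' @param update \code{"synchronous"} or \code{"asynchronous"}.
#' @return the 0/1 state vector at time t + 1.
#' @export
step_state <- function(net, x, b, connectivity = 1, stress = 0,
                       update = "synchronous") {
  A <- total_activation(net, x, connectivity, stress)
  p <- activation_probability(A, b)
  if (update == "synchronous") {
    as.integer(stats::runif(net$J) < p)
  } else {
    i <- sample.int(net$J, 1)
    x[i] <- as.integer(stats::runif(1) < p[i])
    as.integer(x)
  }
}

#' Simulate the stochastic symptom dynamics
#'
#' Runs the binary symptom-network dynamics for \code{config$n_steps}
#' time points, starting (by default) with all symptoms off, and tracks
#' the full state plus the state sum \code{D = sum(X)} -- the scalar
#' severity readout, bounded between 0 and J.
#'
#' @param net a \code{symptom_network}.
#' @param config a \code{\link{sim_config}}.
#' @param schedule optional \code{\link{stress_schedule}} whose per-step
#'   values are applied uniformly to all symptoms; its length must equal
#'   \code{config$n_steps}.
#' @return a \code{sim_trace}: a data frame with columns \code{t},
#'   \code{stress}, \code{D} and one 0/1 column per symptom, plus the
#'   configuration as attribute \code{config}.
#' @examples
#' net <- random_network(generator_spec(J = 6, seed = 1))
#' tr <- simulate_network(net, sim_config(connectivity = 1, n_steps = 200,
#'                                        seed = 42))
#' range(tr$D)
#' @export
simulate_network <- function(net, config, schedule = NULL) {
  stopifnot(inherits(net, "symptom_network"), inherits(config, "sim_config"))
  J <- net$J
  n <- config$n_steps
  if (!is.null(schedule)) {
    sv <- if (inherits(schedule, "stress_schedule")) schedule$values
          else as.numeric(schedule)
    if (length(sv) != n)
      stop(sprintf("stress schedule has length %d but n_steps = %d",
                   length(sv), n), call. = FALSE)
  } else {
    sv <- numeric(n)
  }
  x <- config$initial_state
  if (is.null(x)) x <- integer(J)
  if (length(x) != J || !all(x %in% c(0, 1)))
    stop("initial_state must be a 0/1 vector of length J", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  b <- threshold_to_b(net$thresholds, config$b_mode)
  Wc <- config$connectivity * net$weights
  states <- matrix(0L, n, J)
  x <- as.numeric(x)
  sync <- config$update == "synchronous"
  for (t in seq_len(n)) {
    A <- as.numeric(Wc %*% x) + sv[t]
    p <- stats::plogis(A - b)
    if (sync) {
      x <- as.numeric(stats::runif(J) < p)
    } else {
      i <- sample.int(J, 1)
      x[i] <- as.numeric(stats::runif(1) < p[i])
    }
    states[t, ] <- as.integer(x)
  }
  out <- data.frame(t = seq_len(n), stress = sv, D = rowSums(states))
  st <- as.data.frame(states)
  names(st) <- net$labels
  out <- cbind(out, st)
  attr(out, "config") <- config
  attr(out, "labels") <- net$labels
  if (!is.null(schedule) && inherits(schedule, "stress_schedule"))
    attr(out, "direction") <- schedule$direction
  class(out) <- c("sim_trace", "data.frame")
  out
}

#' Extract the 0/1 state matrix from a trace
#'
#' @param trace a \code{sim_trace}.
#' @return integer matrix, n_steps x J.
#' @export
trace_states <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  as.matrix(trace[, attr(trace, "labels"), drop = FALSE])
}

#' Write a simulation trace to CSV
#'
#' Columns \code{t, stress, D, <symptom labels...>}.
#'
#' @param trace a \code{sim_trace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
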