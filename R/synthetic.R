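#' Specification for a synthetic symptom network and dataset
#'
#' Defaults emulate an empirically plausible 14-symptom system: sparse,
#' mostly positive pairwise couplings of modest size and clearly negative
#' thresholds, so that individual symptoms prefer 'off' and population
#' prevalence of the full syndrome is low, while strong global
#' connectivity can still sustain an active state.
#'
#' @param J node count (default 14).
#' @param edge_density probability an unordered pair receives a nonzero
#'   weight (default 0.4).
#' @param weight_range uniform range for nonzero weights (default
#'   \code{c(0.5, 1.5)}, positive).
#' @param threshold_range uniform range for thresholds (default
#'   \code{c(-4, -2.5)}; negative = preference for 'off').
#' @param N sample size for dataset generation (default 5000).
#' @param seed RNG seed.
#' @return a \code{generator_spec}.
#' @export
generator_spec <- function(J = 14, edge_density = 0.4,
                           weight_range = c(0.5, 1.5),
                           threshold_range = c(-4, -2.5),
                           N = 5000, seed = NULL) {
  J <- as.integer(J)
  if (is.na(J) || J < 2) stop("`J` must be >= 2", call. = FALSE)
  if (edge_density < 0 || edge_density > 1)
    stop("`edge_density` must be in [0, 1]", call. = FALSE)
  if (length(weight_range) != 2 || weight_range[1] > weight_range[2])
    stop("`weight_range` must be an ordered pair", call. = FALSE)
  if (length(threshold_range) != 2 ||
      threshold_range[1] > threshold_range[2])
    stop("`threshold_range` must be an ordered pair", call. = FALSE)
  structure(list(J = J, edge_density = edge_density,
                 weight_range = weight_range,
                 threshold_range = threshold_range,
                 N = as.integer(N), seed = seed),
            class = "generator_spec")
}

#' Generate a random symptom network
#'
#' Draws a symmetric zero-diagonal weight matrix with Bernoulli
#' (\code{edge_density}) edges, uniform weights, and uniform thresholds,
#' per the generator spec. Reproducible under the spec's seed.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return a \code{symptom_network}.
#' @export
random_network <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  J <- spec$J
  n_pairs <- J * (J - 1) / 2
  present <- stats::runif(n_pairs) < spec$edge_density
  w <- ifelse(present,
              stats::runif(n_pairs, spec$weight_range[1],
                           spec$weight_range[2]), 0)
  W <- matrix(0, J, J)
  W[upper.tri(W)] <- w
  W <- W + t(W)
  tau <- stats::runif(J, spec$threshold_range[1], spec$threshold_range[2])
  symptom_network(W, tau)
}

# Enumerate all 2^J binary configurations as a (2^J x J) matrix,
# and the exact Ising probability of each:
#   P(x) prop exp( sum_i tau_i x_i + sum_{i<j} w_ij x_i x_j )
ising_enumeration <- function(net) {
  J <- net$J
  if (J > 20)
    stop("exact enumeration needs J <= 20 (2^J states); use ",
         "sample_ising_gibbs() for larger networks", call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:1), J)))[, J:1, drop = FALSE]
  colnames(states) <- net$labels
  energy <- states %*% net$thresholds +
    rowSums((states %*% net$weights) * states) / 2
  logZ <- max(energy) + log(sum(exp(energy - max(energy))))
  list(states = states, prob = exp(energy - logZ))
}

#' Draw exact i.i.d. samples from an Ising distribution
#'
#' Enumerates all 2^J configurations, computes each one's exact
#' probability under
#' \eqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j)},
#' and samples N configurations i.i.d. from that distribution. The
#' conventional Ising parameterisation (tau itself, not |tau|) is used,
#' so the nodewise logistic regressions of the estimator target exactly
#' these parameters.
#'
#' @param net a \code{symptom_network} with J <= 20.
#' @param N number of respondents to draw.
#' @param seed RNG seed.
#' @return a \code{binary_dataset} (N x J).
#' @export
sample_ising_exact <- function(net, N, seed = NULL) {
  stopifnot(inherits(net, "symptom_network"))
  enum <- ising_enumeration(net)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(enum$states), N, replace = TRUE,
                    prob = enum$prob)
  binary_dataset(enum$states[idx, , drop = FALSE], allow_constant = TRUE)
}

#' Draw approximate Ising samples by single-site Gibbs sampling
#'
#' Scalable alternative to \code{\link{sample_ising_exact}} for J > 20.
#' Each sweep resamples every node from its full conditional,
#' \eqn{P(x_i = 1 | x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)};
#' draws are recorded every \code{thin} sweeps after \code{burn_in}
#' sweeps.
#'
#' @param net a \code{symptom_network}.
#' @param N number of recorded draws.
#' @param burn_in discarded initial sweeps (default 500).
#' @param thin sweeps between recorded draws (default 10).
#' @param seed RNG seed.
#' @return a \code{binary_dataset} (N x J).
#' @export
sample_ising_gibbs <- function(net, N, burn_in = 500, thin = 10,
                               seed = NULL) {
  stopifnot(inherits(net, "symptom_network"))
  if (burn_in < 1 || thin < 1)
    stop("`burn_in` and `thin` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  J <- net$J
  W <- net$weights
  tau <- net$thresholds
  x <- as.numeric(stats::runif(J) < 0.5)
  out <- matrix(0L, N, J)
  sweep_once <- function(x) {
    for (i in seq_len(J)) {
      p <- stats::plogis(tau[i] + sum(W[i, ] * x))
      x[i] <- as.numeric(stats::runif(1) < p)
    }
    x
  }
  for (s in seq_len(burn_in)) x <- sweep_once(x)
  for (r in seq_len(N)) {
    for (s in seq_len(thin)) x <- sweep_once(x)
    out[r, ] <- as.integer(x)
  }
  colnames(out) <- net$labels
  binary_dataset(out, allow_constant = TRUE)
}
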