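test_that("total activation is the connectivity-scaled weighted neighbour sum plus stress", {
  net <- two_node_net(w = 1.5)
  # empty sum: nothing active, no stress
  expect_equal(total_activation(net, c(0, 0)), c(0, 0))
  # direct arithmetic at strong connectivity
  expect_equal(total_activation(net, c(1, 1), connectivity = 2.0),
               c(3.0, 3.0))
  # stress enters additively and uniformly
  net3 <- random_network(generator_spec(J = 5, seed = 9))
  x <- c(1, 0, 1, 1, 0)
  base <- total_activation(net3, x, connectivity = 1.3)
  expect_equal(total_activation(net3, x, connectivity = 1.3, stress = 2.5),
               base + 2.5)
  # linearity in c
  expect_equal(total_activation(net3, x, connectivity = 2.6), 2 * base)
  expect_error(total_activation(net3, c(1, 0)), "length 2")
  expect_error(total_activation(net3, x, stress = c(1, 2)), "length 2")
  expect_error(total_activation(net3, c(2, 0, 1, 1, 0)), "binary")
})

test_that("activation probability is the logistic of A - b, stable at extremes", {
  # symmetric point
  expect_equal(activation_probability(2, 2), 0.5)
  # saturation
  expect_gt(activation_probability(22, 2), 0.999999)
  # closed form 1/(1 + e^2), checked against independent evaluation
  expect_equal(activation_probability(0, 2), 1 / (1 + exp(2)),
               tolerance = 1e-12)
  expect_equal(activation_probability(0, 2), 0.11920292, tolerance = 1e-7)
  # extreme arguments clamp, never overflow or NaN
  p <- activation_probability(c(-1e4, 1e4), c(0, 0))
  expect_equal(p, c(0, 1))
  expect_false(anyNA(p))
  # monotone: increasing in A, decreasing in b
  A <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(activation_probability(A, rep(1, 50))) > 0))
  expect_true(all(diff(activation_probability(rep(1, 50),
                                              A)) < 0))
  expect_error(activation_probability(c(1, 2), 1), "length")
})

test_that("isolated high-barrier symptoms stay off; zero-barrier symptoms are fair coins", {
  net <- zero_net(5, tau = rep(-30, 5))
  cfg <- sim_config(connectivity = 1, n_steps = 1000, seed = 11)
  tr <- simulate_network(net, cfg)
  expect_true(all(tr$D == 0))

  net0 <- zero_net(6, tau = rep(0, 6))
  tr0 <- simulate_network(net0, sim_config(1, 10000, seed = 12))
  # D ~ Binomial(6, 0.5) i.i.d. across steps: mean J/2 within 3 SE
  se <- sqrt(6 * 0.25 / 10000)
  expect_lt(abs(mean(tr0$D) - 3), 3 * se)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  net <- reference_net()
  cfg <- sim_config(connectivity = 1.1, n_steps = 300, seed = 99)
  t1 <- simulate_network(net, cfg)
  t2 <- simulate_network(net, cfg)
  expect_identical(trace_states(t1), trace_states(t2))
  t3 <- simulate_network(net, sim_config(1.1, 300, seed = 100))
  expect_false(identical(trace_states(t1), trace_states(t3)))
})

test_that("the state sum stays within [0, J] and traces are self-consistent", {
  net <- reference_net()
  for (cc in c(0.8, 2.0)) {
    tr <- simulate_network(net, sim_config(cc, 2000, seed = 5))
    expect_true(all(tr$D >= 0 & tr$D <= 14))
    expect_equal(tr$D, unname(rowSums(trace_states(tr))))
    expect_true(all(trace_states(tr) %in% c(0, 1)))
  }
  expect_error(simulate_network(net, sim_config(1, 100), schedule = 1:99),
               "length 99")
  expect_error(simulate_network(net, sim_config(1, 10,
                                                initial_state = rep(2, 14))),
               "0/1")
})

test_that("long-run state frequencies match the exact synchronous-chain stationary law", {
  net <- two_node_net(w = 1.2, tau = c(-0.8, -1.5))
  P <- sync_transition_matrix(net, connectivity = 1.4)
  pi_exact <- stationary_distribution(P)
  tr <- simulate_network(net, sim_config(1.4, 50000, seed = 21))
  idx <- state_index(trace_states(tr))
  freq <- tabulate(idx, nbins = 4) / nrow(tr)
  expect_lt(sum(abs(freq - pi_exact)) / 2, 0.02)
})

test_that("a saturated uniformly coupled system stays fully active", {
  J <- 6
  W <- matrix(2, J, J); diag(W) <- 0
  net <- symptom_network(W, rep(-1, J))
  tr <- simulate_network(net, sim_config(
    connectivity = 3, n_steps = 2000, seed = 31,
    initial_state = rep(1, J)))
  # per-step escape probability <= J * plogis(b - c*(J-1)*w) ~ 4e-12
  expect_true(all(tr$D == J))
})

test_that("activation and probability are monotone in connectivity for positive weights", {
  net <- reference_net()
  set.seed(42)
  for (rep in 1:20) {
    x <- rbinom(14, 1, 0.5)
    a1 <- total_activation(net, x, connectivity = 0.8)
    a2 <- total_activation(net, x, connectivity = 1.1)
    a3 <- total_activation(net, x, connectivity = 2.0)
    expect_true(all(a2 >= a1) && all(a3 >= a2))
    b <- threshold_to_b(net$thresholds)
    expect_true(all(activation_probability(a3, b) >=
                      activation_probability(a1, b)))
  }
})

test_that("asynchronous updates change at most one symptom per step", {
  net <- reference_net()
  tr <- simulate_network(net, sim_config(
    2, 500, update = "asynchronous", seed = 7,
    initial_state = rep(1, 14)))
  st <- trace_states(tr)
  flips <- rowSums(abs(diff(st)))
  expect_true(all(flips <= 1))
})

test_that("threshold-to-barrier mapping supports both conventions", {
  tau <- c(-2, 0.5, 1)
  expect_equal(threshold_to_b(tau), c(2, 0.5, 1))
  expect_equal(threshold_to_b(tau, "neg"), c(2, -0.5, -1))
})
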