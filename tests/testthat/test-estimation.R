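test_that("binary dataset validation reports the offending cell", {
  m <- matrix(c(0, 1, 1, 0, 2, 1), 2, 3)
  expect_error(binary_dataset(m), "row 1, column 3")
  m2 <- matrix(c(0, 1, NA, 0), 2, 2)
  expect_error(binary_dataset(m2), "row 1, column 2")
  m3 <- cbind(a = c(0, 1, 0), b = c(0, 0, 0))
  expect_error(binary_dataset(m3), "constant")
  expect_silent(binary_dataset(m3, allow_constant = TRUE))
})

test_that("dataset CSV round-trips through the reader", {
  net <- random_network(generator_spec(J = 4, seed = 21))
  dat <- sample_ising_exact(net, 200, seed = 22)
  f <- withr::local_tempfile(fileext = ".csv")
  write_binary_dataset(dat, f)
  back <- read_binary_dataset(f)
  expect_equal(unclass(back), unclass(dat))
  expect_error(read_binary_dataset(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("nodewise fit guards sample size and constant responses", {
  set.seed(31)
  d <- binary_dataset(matrix(rbinom(40 * 5, 1, 0.5), 40, 5))
  expect_error(fit_node(d, 1), "10 \\* J")
  d2 <- binary_dataset(cbind(matrix(rbinom(600 * 2, 1, 0.5), 600, 2),
                             rep(0L, 600)), allow_constant = TRUE)
  expect_error(fit_node(d2, 3), "constant")
  expect_error(estimate_network(d2), "S3")
})

test_that("independent columns give an empty neighbourhood and empty network", {
  n_empty <- 0
  for (r in 1:10) {
    set.seed(1000 + r)
    d <- binary_dataset(matrix(rbinom(2000 * 5, 1, 0.5), 2000, 5))
    net <- estimate_network(d)
    if (all(net$weights == 0)) n_empty <- n_empty + 1
  }
  expect_gte(n_empty, 9)
})

test_that("a perfectly coupled pair is detected with a large positive weight", {
  set.seed(41)
  a <- rbinom(500, 1, 0.5)
  noise <- matrix(rbinom(500 * 2, 1, 0.5), 500, 2)
  d <- binary_dataset(cbind(a = a, b = a, n1 = noise[, 1],
                            n2 = noise[, 2]))
  f <- fit_node(d, "a")
  expect_gt(f$coefficients["b"], 2)
})

test_that("the selected-path degrees of freedom are monotone along the penalty grid", {
  net <- random_network(generator_spec(J = 6, seed = 51))
  d <- sample_ising_exact(net, 2000, seed = 52)
  for (j in 1:6) {
    f <- fit_node(d, j)
    expect_true(all(diff(f$df_path) >= 0))  # lambda descends along path
    expect_equal(f$df_path[1], 0)           # null model heads the path
  }
})

test_that("a single strong edge among four nodes is isolated", {
  hits <- 0
  for (r in 1:10) {
    W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1.5
    net <- symptom_network(W, rep(-0.5, 4))
    d <- sample_ising_exact(net, 5000, seed = 600 + r)
    est <- estimate_network(d)
    found <- est$weights[1, 2] != 0
    others <- est$weights; others[1, 2] <- others[2, 1] <- 0
    if (found && all(others == 0)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("estimation recovers signs and ranks of a known 6-node Ising network", {
  rhos <- c()
  for (r in 1:3) {
    net0 <- random_network(generator_spec(
      J = 6, edge_density = 0.5, weight_range = c(0.5, 1.5),
      threshold_range = c(-2, -0.5), seed = 700 + r))
    dat <- sample_ising_exact(net0, 5000, seed = 800 + r)
    est <- estimate_network(dat)
    expect_true(isSymmetric(est$weights))
    expect_true(all(diag(est$weights) == 0))
    tw <- net0$weights[upper.tri(net0$weights)]
    ew <- est$weights[upper.tri(est$weights)]
    # every true edge recovered, with the generator's sign
    expect_true(all(ew[tw != 0] != 0))
    expect_true(all(sign(ew[tw != 0]) == sign(tw[tw != 0])))
    both <- ew != 0 & tw != 0
    rhos <- c(rhos, cor(tw[both], ew[both], method = "spearman"))
  }
  expect_true(all(rhos > 0.7))
})

test_that("recovery quality improves with sample size", {
  # weights weak enough that detection is genuinely sample-limited
  net0 <- random_network(generator_spec(
    J = 6, edge_density = 0.5, weight_range = c(0.2, 0.6),
    threshold_range = c(-1.5, -0.5), seed = 901))
  truth <- net0$weights[upper.tri(net0$weights)] != 0
  f1 <- function(est) {
    got <- est$weights[upper.tri(est$weights)] != 0
    tp <- sum(got & truth)
    if (tp == 0) return(0)
    2 * tp / (sum(got) + sum(truth))
  }
  f1s <- sapply(c(500, 2000, 8000), function(N) {
    mean(sapply(1:3, function(r) {
      d <- sample_ising_exact(net0, N, seed = 1000 + 100 * r + N %% 97)
      f1(estimate_network(d))
    }))
  })
  expect_true(all(diff(f1s) >= 0))
})

test_that("OR symmetrisation keeps one-sided edges that AND drops", {
  set.seed(61)
  # borderline coupling so the two directed fits can disagree
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.35
  net <- symptom_network(W, rep(-1, 4))
  d <- sample_ising_exact(net, 1500, seed = 62)
  and_net <- estimate_network(d, estimation_config(symmetrization = "AND"))
  or_net <- estimate_network(d, estimation_config(symmetrization = "OR"))
  # OR keeps at least everything AND keeps
  expect_true(all(or_net$weights[and_net$weights != 0] != 0))
})
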