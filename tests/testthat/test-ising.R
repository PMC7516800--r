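test_that("hamiltonian counts each coupled pair once", {
  J <- two_node_J()
  expect_equal(hamiltonian(c(1, 1), J), -1)
  expect_equal(hamiltonian(c(1, -1), J), 1)
  W <- generate_random_network(5, seed = 4)
  expect_equal(hamiltonian(rep(1, 5), W),
               -sum(unclass(as.matrix(W))[upper.tri(W)]))
  expect_error(hamiltonian(c(1, 1, 1), J), "spins")
})

test_that("delta_energy equals the explicit Hamiltonian difference", {
  expect_equal(delta_energy(c(1, 1), two_node_J(), 1), 2)
  Jz <- matrix(0, 3, 3)
  expect_equal(delta_energy(c(1, -1, 1), Jz, 2), 0)
  set.seed(21)
  for (rep in 1:20) {
    J <- generate_random_network(5, seed = 500 + rep)
    s <- sample(c(-1, 1), 5, replace = TRUE)
    i <- sample(5, 1)
    flipped <- s; flipped[i] <- -flipped[i]
    expect_equal(delta_energy(s, J, i),
                 hamiltonian(flipped, J) - hamiltonian(s, J),
                 tolerance = 1e-12)
  }
  expect_error(delta_energy(c(1, 1), two_node_J(), 3), "range")
})

test_that("flip probability follows the Metropolis rule", {
  expect_identical(flip_probability(-0.5, 2), 1)
  expect_identical(flip_probability(0, 0.7), 1)
  expect_equal(flip_probability(1, 1), exp(-1))
  expect_equal(flip_probability(c(-1, 0, 2), 2), c(1, 1, exp(-1)))
  expect_error(flip_probability(1, 0), "temperature")
})

test_that("synchronous updates flip all spins at zero coupling and freeze a ground state", {
  Jz <- matrix(0, 4, 4)
  s <- c(1, -1, -1, 1)
  expect_identical(step_synchronous(s, Jz, 1), -s)
  # aligned ground state of a positive network at T -> 0: every dE > 0 and
  # the flip probabilities vanish
  J <- generate_random_network(4, seed = 31)
  expect_identical(step_synchronous(rep(1, 4), J, 1e-8), rep(1, 4))
})

test_that("one-step flip frequencies match the Metropolis probabilities", {
  J <- generate_random_network(5, seed = 17)
  s0 <- c(1, -1, 1, 1, -1)
  T_ <- 1.3
  p_expect <- flip_probability(
    vapply(1:5, function(i) delta_energy(s0, J, i), numeric(1)), T_)
  n_draws <- 20000
  set.seed(5)
  flips <- matrix(0, n_draws, 5)
  for (k in seq_len(n_draws)) {
    flips[k, ] <- step_synchronous(s0, J, T_) != s0
  }
  freq <- colMeans(flips)
  se <- sqrt(p_expect * (1 - p_expect) / n_draws)
  expect_true(all(abs(freq - p_expect) <= 3 * se + 1e-9))
  # sequential: one site at a time, chosen uniformly
  set.seed(6)
  changed <- replicate(2000, sum(step_sequential(s0, J, T_) != s0))
  expect_true(all(changed <= 1))
})

test_that("simulated traces are reproducible and mirror the R reference exactly", {
  J <- generate_random_network(4, seed = 12)
  for (mode in c("sequential", "synchronous")) {
    tr1 <- simulate_ising(J, 1.5, n_thermalization = 10, n_iterations = 50,
                          update_mode = mode, seed = 77)
    tr2 <- simulate_ising(J, 1.5, n_thermalization = 10, n_iterations = 50,
                          update_mode = mode, seed = 77)
    expect_identical(tr1$state_code, tr2$state_code)
    ref <- r_reference_simulate(unclass(as.matrix(J)), 1.5, 10, 50, mode, 77)
    expect_identical(tr1$state_code, ref$state_code)
    expect_equal(tr1$magnetization, ref$magnetization, tolerance = 1e-12)
    expect_equal(tr1$energy, ref$energy, tolerance = 1e-10)
  }
  expect_equal(nrow(simulate_ising(J, 1, seed = 1)), 2000)
  expect_equal(nrow(simulate_ising(J, 1, n_iterations = 1, seed = 1)), 1)
})

test_that("sequential sampling reproduces the canonical pair energy", {
  tr <- simulate_ising(two_node_J(), 1, n_thermalization = 500,
                       n_iterations = 40000, update_mode = "sequential",
                       seed = 19)
  se <- batch_se(tr$energy)
  expect_lt(abs(mean(tr$energy) - (-tanh(1))), 3 * se)
})

test_that("temperature grids are log-spaced and endpoint-inclusive", {
  g <- temperature_grid()
  expect_length(g, 200)
  expect_equal(g[1], 0.1)
  expect_equal(g[200], 4)
  expect_equal(temperature_grid(2), c(0.1, 4))
  ratios <- g[-1] / g[-length(g)]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_error(temperature_grid(low = 0), "low")
  expect_error(temperature_grid(low = 2, high = 1), "low")
})

test_that("traces persist as CSV with JSON run metadata", {
  J <- generate_random_network(3, seed = 5)
  tr <- simulate_ising(J, 2, n_iterations = 25, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_trace(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$state_code, tr$state_code)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$temperature, 2)
  expect_equal(meta$update_mode, "sequential")
})
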