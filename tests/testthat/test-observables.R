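test_that("summary statistics match their closed forms", {
  expect_equal(magnetization(rep(1, 5)), 1)
  expect_equal(magnetization(c(1, 1, -1, 1, -1)), 0.2)
  expect_equal(magnetization(c(1, -1)), 0)
  expect_equal(time_average(c(0, 1)), 0.5)
  expect_equal(time_average(rep(3.2, 10)), 3.2)
  expect_equal(magnetic_susceptibility(c(0, 1), 2), 0.125)
  expect_equal(magnetic_susceptibility(rep(0.4, 9), 1), 0)
  expect_equal(generalized_susceptibility(c(0, 1)), 0.25)
  expect_equal(generalized_susceptibility(rep(2, 5)), 0)
  expect_equal(specific_heat(rep(-1.3, 7), 0.5), 0)
  expect_equal(ensemble_variance(c(0, 2)), 1)
  expect_equal(ensemble_variance(rep(0.7, 6)), 0)
  expect_error(magnetic_susceptibility(c(0, 1), 0), "temperature")
})

test_that("fluctuation statistics agree with an independent variance oracle", {
  set.seed(10)
  x <- stats::rnorm(500)
  pvar <- mean((x - mean(x))^2)     # two-pass population variance
  expect_equal(generalized_susceptibility(x), pvar, tolerance = 1e-12)
  expect_equal(magnetic_susceptibility(x, 1.7), pvar / 1.7, tolerance = 1e-12)
  expect_equal(specific_heat(x, 1.3), pvar / 1.3^2, tolerance = 1e-12)
  # internal consistency: chi == chi_O / T for the same series
  expect_equal(magnetic_susceptibility(x, 2.5),
               generalized_susceptibility(x) / 2.5)
  # variances are permutation-invariant and nonnegative
  perm <- sample(x)
  expect_equal(generalized_susceptibility(perm), pvar, tolerance = 1e-12)
  expect_gte(generalized_susceptibility(perm), 0)
})

test_that("simulated specific heat matches the analytic pair value", {
  # single coupled pair at T = 1: Cv = sech^2(1/T) / T^2
  tr <- simulate_ising(two_node_J(), 1, n_thermalization = 500,
                       n_iterations = 40000, update_mode = "sequential",
                       seed = 8)
  cv_hat <- specific_heat(tr$energy, 1)
  cv_exact <- (1 / cosh(1))^2
  # standard error via batch-means replication of the variance estimate
  reps <- vapply(1:8, function(r) {
    trr <- simulate_ising(two_node_J(), 1, 500, 10000,
                          update_mode = "sequential", seed = 100 + r)
    specific_heat(trr$energy, 1)
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(8)
  expect_lt(abs(cv_hat - cv_exact), 3 * se + 0.01)
})

test_that("trace summaries assemble the per-temperature statistics", {
  J <- generate_random_network(3, seed = 6)
  tr <- simulate_ising(J, 1.4, n_iterations = 200, seed = 2)
  row <- summarize_trace(tr)
  expect_equal(row$temperature, 1.4)
  expect_equal(row$M_mean, mean(tr$magnetization))
  expect_equal(row$chi, magnetic_susceptibility(tr$magnetization, 1.4))
  expect_equal(row$Cv, specific_heat(tr$energy, 1.4))
})

test_that("Monte-Carlo energy fluctuations obey fluctuation-dissipation", {
  # Cv from trace fluctuations vs the numerical T-derivative of the exact
  # canonical energy, at mid-range temperature
  J <- generate_random_network(5, seed = 66)
  T_ <- 2
  h <- 1e-3
  dEdT <- (enumerate_canonical(J, T_ + h)$E_mean -
           enumerate_canonical(J, T_ - h)$E_mean) / (2 * h)
  cvs <- vapply(1:6, function(r) {
    tr <- simulate_ising(J, T_, 1000, 20000, update_mode = "sequential",
                         seed = 200 + r)
    specific_heat(tr$energy, T_)
  }, numeric(1))
  se <- stats::sd(cvs) / sqrt(6)
  expect_lt(abs(mean(cvs) - dEdT), max(0.05 * dEdT, 3 * se))
})
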