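test_that("state-by-node TPM entries follow the flip rule", {
  # zero coupling: every dE = 0, so every node flips surely
  Jz <- matrix(0, 3, 3)
  tpm <- build_tpm(Jz, 1)
  S <- spin_states(3)
  expect_equal(unclass(as.matrix(tpm)), ifelse(S == 1, 0, 1))
  # coupled pair, both up: dE = 2 for each node
  tpm2 <- build_tpm(two_node_J(), 1)
  expect_equal(unname(tpm2[4, ]), rep(1 - exp(-2), 2))
  expect_error(build_tpm(two_node_J(), 0), "temperature")
})

test_that("one-step simulation frequencies match the TPM row", {
  J <- generate_random_network(5, seed = 23)
  T_ <- 1.1
  tpm <- build_tpm(J, T_)
  for (code in c(0L, 13L, 31L)) {
    s0 <- code_to_state(code, 5)
    n_draws <- 20000
    set.seed(code + 1)
    up <- matrix(0, n_draws, 5)
    for (k in seq_len(n_draws)) up[k, ] <- step_synchronous(s0, J, T_) == 1
    freq <- colMeans(up)
    p <- tpm[code + 1, ]
    se <- sqrt(p * (1 - p) / n_draws)
    expect_true(all(abs(freq - p) <= 3 * se + 1e-9))
  }
})

test_that("state-by-state expansion is the product of per-node conditionals", {
  J <- generate_random_network(4, seed = 41)
  tpm <- build_tpm(J, 0.9)
  P <- tpm_state_by_state(tpm)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  # zero coupling: permutation mapping each state to its complement
  Pz <- tpm_state_by_state(zero_coupling_tpm(3))
  expect_equal(unclass(as.matrix(Pz)),
               outer(0:7, 0:7, function(s, t) as.numeric(t == 7 - s)))
  # one-node chain with P(up) = 0.3 from either state
  P1 <- tpm_state_by_state(matrix(c(0.3, 0.3), 2, 1))
  expect_equal(unclass(as.matrix(P1)), matrix(c(0.7, 0.7, 0.3, 0.3), 2, 2))
  # collapsing recovers the marginals exactly
  expect_equal(collapse_tpm(P), unclass(as.matrix(tpm)), tolerance = 1e-12)
})

test_that("the kernel approaches the complement permutation as T grows", {
  J <- generate_random_network(3, seed = 9)
  tpm <- build_tpm(J, 1e7)
  expect_equal(unclass(as.matrix(tpm)),
               unclass(as.matrix(zero_coupling_tpm(3))), tolerance = 1e-6)
  # monotonicity: from the aligned state all dE > 0, and staying up gets
  # surer as the temperature drops
  temps <- c(4, 2, 1, 0.5, 0.25)
  stay <- vapply(temps, function(T_) min(build_tpm(J, T_)[8, ]), numeric(1))
  expect_true(all(diff(stay) >= 0))
})

test_that("stationary distributions are exact fixed points with ergodicity checks", {
  # ergodic synchronous kernels: interior per-node probabilities give a
  # strictly positive state-by-state kernel
  set.seed(40)
  for (rep in 1:5) {
    sbn <- matrix(stats::runif(8 * 3, 0.05, 0.95), 8, 3)
    P <- tpm_state_by_state(sbn)
    pi_ <- stationary_distribution(P)
    Pm <- unclass(as.matrix(P))
    expect_lt(sum(abs(pi_ %*% Pm - pi_)), 1e-10)
    pw <- rep(1 / 8, 8)                       # power-iteration oracle
    for (k in 1:5000) pw <- drop(pw %*% Pm)
    expect_equal(pi_, pw, tolerance = 1e-8)
  }
  # a doubly stochastic kernel leaves the uniform law invariant
  sbn_half <- matrix(0.5, 8, 3)
  expect_equal(stationary_distribution(tpm_state_by_state(sbn_half)),
               rep(1 / 8, 8), tolerance = 1e-12)
  # the zero-coupling complement map is periodic: no unique stationary law
  expect_error(stationary_distribution(tpm_state_by_state(zero_coupling_tpm(2))),
               "periodic|reducible")
  # Metropolis synchronous kernels of weighted complete graphs contain a
  # deterministic max-cut two-cycle at every temperature, so they are
  # refused too
  J <- generate_random_network(3, seed = 14)
  expect_error(stationary_distribution(tpm_state_by_state(build_tpm(J, 2))),
               "periodic|reducible")
})

test_that("TPMs round-trip through CSV with their sidecar", {
  J <- generate_random_network(3, seed = 2, label = "rt")
  tpm <- build_tpm(J, 1.7)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_tpm(tpm, path)
  back <- read_tpm(path)
  expect_equal(unclass(as.matrix(back)), unclass(as.matrix(tpm)),
               tolerance = 1e-12)
  expect_equal(attr(back, "temperature"), 1.7)
  expect_identical(attr(back, "label"), "rt")
  bad <- tempfile(fileext = ".csv")
  on.exit(unlink(bad), add = TRUE)
  utils::write.csv(matrix(0.5, 3, 2), bad, row.names = FALSE)
  expect_error(read_tpm(bad), "2\\^n")
})
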