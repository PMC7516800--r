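test_that("the earth-mover distance behaves as a metric on repertoires", {
  expect_equal(repertoire_emd(c(0.25, 0.75), c(0.25, 0.75)), 0)
  expect_equal(repertoire_emd(c(1, 0), c(0, 1)), 1)       # 1 node, Hamming 1
  expect_equal(repertoire_emd(c(1, 0, 0, 0), c(0, 0, 0, 1)), 2)
  set.seed(12)
  for (rep in 1:25) {
    m <- sample(c(2, 4, 8), 1)
    p <- stats::runif(m); p <- p / sum(p)
    q <- stats::runif(m); q <- q / sum(q)
    r <- stats::runif(m); r <- r / sum(r)
    dpq <- repertoire_emd(p, q)
    expect_gte(dpq, 0)
    expect_equal(dpq, repertoire_emd(q, p), tolerance = 1e-10)
    expect_lte(dpq, repertoire_emd(p, r) + repertoire_emd(r, q) + 1e-10)
    expect_lt(repertoire_emd(p, p), 1e-12)
  }
  expect_error(repertoire_emd(c(1, 0), c(1, 0, 0, 0)), "purview")
})

test_that("repertoires capture deterministic and unconstrained mechanisms", {
  # zero coupling: node 1's past tells nothing about node 2
  tpm <- zero_coupling_tpm(3)
  expect_equal(cause_repertoire(tpm, 0, mechanism = 1, purview = 2),
               c(0.5, 0.5))
  # the NOT loop: a node in state +1 pins its own past to -1 and its own
  # future to -1
  not1 <- matrix(c(1, 0), 2, 1)
  expect_equal(cause_repertoire(not1, 1, 1, 1), c(1, 0))
  expect_equal(effect_repertoire(not1, 1, 1, 1), c(1, 0))
  # repertoires normalize over the purview
  J <- generate_random_network(3, seed = 7)
  tpm3 <- build_tpm(J, 1.2)
  for (mech in list(1, c(1, 3), c(1, 2, 3))) {
    cr <- cause_repertoire(tpm3, 5, mech, c(1, 2, 3))
    er <- effect_repertoire(tpm3, 5, mech, c(2, 3))
    expect_equal(sum(cr), 1, tolerance = 1e-12)
    expect_equal(sum(er), 1, tolerance = 1e-12)
    expect_true(all(cr >= 0) && all(er >= 0))
  }
})

test_that("single-mechanism phi of the NOT loop matches hand enumeration", {
  # the only valid partition replaces the whole point-mass repertoire with
  # the uniform unconstrained one: EMD = 0.5 in each direction
  not1 <- matrix(c(1, 0), 2, 1)
  expect_equal(small_phi(not1, 1, 1, "cause")$phi, 0.5, tolerance = 1e-9)
  expect_equal(small_phi(not1, 1, 1, "effect")$phi, 0.5, tolerance = 1e-9)
})

test_that("reducible systems carry no integrated information", {
  # zero coupling: multi-node mechanisms factorize exactly
  tpm <- zero_coupling_tpm(3)
  expect_equal(small_phi(tpm, 0, c(1, 2), "cause")$phi, 0)
  expect_equal(small_phi(tpm, 0, c(1, 2, 3), "effect")$phi, 0)
  # only single-node concepts survive in the cause-effect structure
  ces <- compute_ces(tpm, 0)
  expect_true(all(ces$mechanism %in% c("1", "2", "3")))
  # a fully noisy kernel constrains nothing at all
  noisy <- matrix(0.5, 8, 3)
  expect_equal(nrow(compute_ces(noisy, 0)), 0)
  expect_equal(big_phi(noisy, 0)$phi, 0)
  # concept count is bounded by the number of nonempty mechanisms
  J <- generate_random_network(3, seed = 19)
  tpm3 <- build_tpm(J, 0.8)
  expect_lte(nrow(compute_ces(tpm3, 3)), 7)
})

test_that("Phi is invariant under global spin flip and node relabeling", {
  for (seed in c(3, 8, 15)) {
    J <- generate_random_network(3, seed = seed)
    tpm <- build_tpm(J, 1.4)
    for (code in c(0, 3, 5)) {
      phi_a <- big_phi(tpm, code)$phi
      phi_b <- big_phi(tpm, 7 - code)$phi       # complement state
      expect_equal(phi_a, phi_b, tolerance = 1e-9)
    }
    # permuting node labels permutes nothing observable
    perm <- c(2, 3, 1)
    Jp <- unclass(as.matrix(J))[perm, perm]
    tpmp <- build_tpm(Jp, 1.4)
    s <- c(1, -1, 1)
    expect_equal(big_phi(tpmp, s[perm])$phi, big_phi(tpm, s)$phi,
                 tolerance = 1e-9)
  }
})

test_that("the n > 5 guard and single-node base case hold", {
  J <- generate_random_network(6, seed = 1)
  tpm <- build_tpm(J, 1)
  expect_error(big_phi(tpm, 0), "n <= 5")
  expect_equal(big_phi(matrix(c(1, 0), 2, 1), 1)$phi, 0)
})

test_that("per-state caching and the spin-flip shortcut change nothing", {
  J <- generate_random_network(3, seed = 28)
  tpm <- build_tpm(J, 2.2)
  codes <- c(0, 5, 5, 2, 7, 0)
  direct <- vapply(codes, function(cd) big_phi(tpm, cd)$phi, numeric(1))
  expect_equal(phi_states(tpm, codes, symmetry = "none"), direct,
               tolerance = 1e-12)
  expect_equal(phi_states(tpm, codes, symmetry = "auto"), direct,
               tolerance = 1e-9)
  cache <- new.env(parent = emptyenv())
  phi_states(tpm, codes, cache = cache, symmetry = "none")
  expect_length(ls(cache), length(unique(codes)))
})

test_that("Phi over a trace averages the cached per-state values", {
  J <- generate_random_network(3, seed = 33)
  T_ <- 2.5
  tpm <- build_tpm(J, T_)
  tr <- simulate_ising(J, T_, 200, 800, update_mode = "synchronous", seed = 4)
  res <- phi_over_trace(tr, tpm)
  series <- phi_states(tpm, tr$state_code)
  expect_equal(res$phi_mean, mean(series), tolerance = 1e-12)
  expect_equal(res$chi_phi, generalized_susceptibility(series),
               tolerance = 1e-12)
  expect_equal(sum(res$per_state$weight), 1, tolerance = 1e-12)
  # a trace pinned to one state has no Phi fluctuations
  one <- tr[1, , drop = FALSE]
  attr(one, "config") <- attr(tr, "config")
  expect_equal(phi_over_trace(one, tpm)$chi_phi, 0)
  # stationary weighting: exact expectation under the chain's stationary
  # law, checked on an ergodic (interior-probability) synchronous kernel
  set.seed(9)
  sbn <- matrix(stats::runif(8 * 3, 0.1, 0.9), 8, 3)
  codes <- simulate_sbn_chain(sbn, 20000, seed = 5)
  fake_trace <- data.frame(state_code = codes)
  visit <- phi_over_trace(fake_trace, sbn, weighting = "visit")$phi_mean
  st <- phi_over_trace(fake_trace, sbn, weighting = "stationary")
  pi_ <- stationary_distribution(tpm_state_by_state(sbn))
  expect_equal(st$phi_mean, sum(pi_ * st$per_state$phi), tolerance = 1e-12)
  expect_lt(abs(visit - st$phi_mean), 0.05)
})
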