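test_that("peak detection finds maxima with deterministic tie handling", {
  temps <- temperature_grid(50)
  # unimodal bump centered at T = 1.8, width comparable to a susceptibility
  # peak on this grid
  curve <- exp(-((log(temps) - log(1.8)) / 0.5)^2)
  pk <- find_peak(temps, curve, smooth = 1)
  expect_equal(pk$T_peak, temps[which.max(curve)])
  expect_warning(pk0 <- find_peak(temps, rep(1, 50)), "degenerate")
  expect_equal(pk0$T_peak, temps[1])          # ties resolve to the lowest T
  # noisy unimodal curves: the smoothed peak lands within 2 grid steps
  set.seed(71)
  hits <- vapply(1:100, function(r) {
    noisy <- curve + stats::rnorm(50, sd = 0.08)
    abs(find_peak(temps, noisy, smooth = 5)$index - which.max(curve))
  }, numeric(1))
  expect_true(all(hits <= 2))
})

test_that("network sweeps assemble per-temperature summaries deterministically", {
  J <- generate_random_network(3, seed = 61)
  sw <- sweep_network(J, temperatures = 1.5, n_thermalization = 50,
                      n_iterations = 100, seed = 1)
  expect_equal(nrow(sw), 1)
  expect_named(sw, c("temperature", "M_mean", "E_mean", "chi", "Cv"))
  sw2 <- sweep_network(J, temperature_grid(5), n_thermalization = 50,
                       n_iterations = 200, seed = 9)
  sw3 <- sweep_network(J, temperature_grid(5), n_thermalization = 50,
                       n_iterations = 200, seed = 9)
  expect_identical(as.data.frame(sw2), as.data.frame(sw3))
  # a zero-coupling fixture generates no integrated information at any T
  Jz <- structure(matrix(0, 3, 3), class = c("connectivity", "matrix"))
  swz <- sweep_network(Jz, c(0.5, 1, 2), n_thermalization = 20,
                       n_iterations = 100, compute_phi = TRUE, seed = 2)
  expect_equal(swz$Phi_mean, rep(0, 3))
  expect_equal(swz$chi_Phi, rep(0, 3))
})

test_that("swept susceptibility tracks the exact canonical curve", {
  J <- two_node_J()
  temps <- c(0.4, 0.8, 1.3, 2.1, 3.4)
  reps <- lapply(1:8, function(r) {
    sweep_network(J, temps, n_thermalization = 500, n_iterations = 10000,
                  update_mode = "sequential", seed = 400 + r)$chi
  })
  chi_mat <- do.call(rbind, reps)
  chi_exact <- exact_chi(J, temps)
  for (k in seq_along(temps)) {
    se <- stats::sd(chi_mat[, k]) / sqrt(8)
    expect_lt(abs(mean(chi_mat[, k]) - chi_exact[k]), 3 * se + 0.005)
  }
})

test_that("ensemble summaries aggregate curves and locate consensus peaks", {
  J <- generate_random_network(3, seed = 77)
  temps <- temperature_grid(8)
  sw <- sweep_network(J, temps, 100, 300, seed = 5)
  # identical duplicated networks: zero across-network variance everywhere
  summ <- summarize_ensemble(list(sw, sw), smooth = 1)
  expect_true(all(summ$curves$chi_sigma_J2 == 0))
  expect_true(all(summ$curves$M_mean_sd == 0))
  expect_equal(summ$curves$M_mean_mean, sw$M_mean)
  # hand-built curves: means and variances are plain arithmetic
  a <- sw; b <- sw
  b$chi <- sw$chi + 1
  s2 <- summarize_ensemble(list(a, b), smooth = 1)
  expect_equal(s2$curves$chi_mean, sw$chi + 0.5)
  expect_equal(s2$curves$chi_sigma_J2, rep(0.25, 8))
  expect_true(summ$Tc_chi %in% temps)
  expect_length(summ$per_network_Tc_chi, 2)
  expect_error(summarize_ensemble(list(sw)), "2")
})

test_that("sweep results round-trip through CSV with their metadata", {
  J <- generate_random_network(3, seed = 88, label = "io-net")
  sw <- sweep_network(J, temperature_grid(3), 20, 50, seed = 7)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_sweep(sw, path)
  back <- read_sweep(path)
  expect_equal(as.data.frame(back), as.data.frame(sw), tolerance = 1e-12)
  expect_identical(attr(back, "label"), "io-net")
  expect_equal(attr(back, "config")$n_iterations, 50)
})

test_that("ensemble sweeps derive independent per-network seeds", {
  nets <- generate_ensemble(3, 3, master_seed = 6)
  temps <- temperature_grid(4)
  res <- sweep_ensemble(nets, temps, n_thermalization = 30, n_iterations = 80,
                        master_seed = 10)
  res2 <- sweep_ensemble(nets, temps, n_thermalization = 30, n_iterations = 80,
                         master_seed = 10)
  expect_identical(lapply(res, as.data.frame), lapply(res2, as.data.frame))
  expect_false(identical(res[[1]]$chi, res[[2]]$chi))
})

test_that("across-network Phi variance falls off in the high-temperature tail", {
  # in the disordered regime the kernel approaches the complement map for
  # every network, so connectivity stops mattering and sigma_J^2(Phi) decays
  temps <- temperature_grid(12, 0.5, 4)
  nets <- generate_ensemble(6, 3, master_seed = 55)
  phi_means <- sapply(nets, function(J) {
    vapply(temps, function(T_) {
      tpm <- build_tpm(J, T_)
      mean(phi_states(tpm, 0:7))
    }, numeric(1))
  })
  sig <- apply(phi_means, 1, function(x) mean(x^2) - mean(x)^2)
  upper <- sig[temps >= stats::median(temps)]
  trend <- stats::cor.test(seq_along(upper), upper, method = "spearman",
                           exact = FALSE)
  expect_lt(trend$estimate, 0)
})
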