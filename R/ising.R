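#' Ising Hamiltonian on a weighted network
#'
#' Configuration energy `H = -sum_{i<j} J_ij s_i s_j`, each unordered pair of
#' coupled spins counted once. With weights normalized to a maximum of 1 this
#' convention places the mean-field critical temperature of a fully connected
#' five-node network near `sum_j J_ij ~ 2`, the regime the temperature grid
#' below is designed to straddle.
#'
#' @param spins Vector of -1/+1 spins.
#' @param J Connectivity matrix (symmetric, zero diagonal).
#' @return Scalar energy (dimensionless, kB = 1).
#' @export
hamiltonian <- function(spins, J) {
  J <- as.matrix(J)
  if (length(spins) != nrow(J)) {
    stop(sprintf("state has %d spins but network has %d nodes",
                 length(spins), nrow(J)), call. = FALSE)
  }
  -0.5 * drop(spins %*% J %*% spins)
}

#' Energy change of a single spin flip
#'
#' `dE = 2 s_i sum_j J_ij s_j`, exactly equal to
#' `hamiltonian(flipped) - hamiltonian(state)` for the pair-once Hamiltonian.
#'
#' @inheritParams hamiltonian
#' @param i Node index (1-based).
#' @export
delta_energy <- function(spins, J, i) {
  J <- as.matrix(J)
  if (i < 1 || i > length(spins)) {
    stop("node index out of range", call. = FALSE)
  }
  2 * spins[i] * sum(J[i, ] * spins)
}

#' Metropolis flip probability
#'
#' Energy-lowering (and energy-neutral) flips are always accepted;
#' energy-raising flips are accepted with the Boltzmann factor
#' `exp(-dE / T)` (kB = 1).
#'
#' @param delta_e Energy change(s) of the proposed flip; vectorized.
#' @param temperature Heat-bath temperature, > 0.
#' @return Probabilities in (0, 1].
#' @export
flip_probability <- function(delta_e, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  ifelse(delta_e > 0, exp(-delta_e / temperature), 1)
}

#' One synchronous (all-spin) Metropolis update
#'
#' Every node draws one fresh uniform variate (in node order) and flips
#' independently with its Metropolis probability, all energy changes being
#' evaluated against the *current* state. This is the update scheme whose
#' one-step kernel is the state-by-node TPM of [build_tpm()].
#'
#' @inheritParams hamiltonian
#' @param temperature Heat-bath temperature.
#' @return The next spin state.
#' @export
step_synchronous <- function(spins, J, temperature) {
  J <- as.matrix(J)
  dE <- 2 * spins * drop(J %*% spins)
  p <- flip_probability(dE, temperature)
  u <- stats::runif(length(spins))
  ifelse(u < p, -spins, spins)
}

#' One sequential (single-site) Metropolis update
#'
#' A uniformly chosen node is offered a flip with its Metropolis probability;
#' all other spins are unchanged. Two variates are drawn per step, site first
#' then acceptance. Sequential updates satisfy detailed balance for the
#' Boltzmann distribution and are the scheme used wherever canonical
#' (equilibrium) averages are asserted.
#'
#' @inheritParams step_synchronous
#' @export
step_sequential <- function(spins, J, temperature) {
  J <- as.matrix(J)
  n <- length(spins)
  i <- floor(stats::runif(1) * n) + 1L
  dE <- 2 * spins[i] * sum(J[i, ] * spins)
  if (stats::runif(1) < flip_probability(dE, temperature)) {
    spins[i] <- -spins[i]
  }
  spins
}

#' Run a Metropolis Ising simulation
#'
#' Initializes each spin uniformly at random, discards `n_thermalization`
#' time steps, then records `n_iterations` time steps. One time step is one
#' simultaneous all-spin update (synchronous mode) or `N` random single-site
#' attempts (sequential mode, the standard Monte-Carlo step-per-site
#' convention), so the two modes advance the system comparably per
#' iteration. Each recorded step logs the state code, the magnetization
#' `|sum s_i| / N` and the energy. The full draw order (initialization, then
#' per-step variates) is fixed, so a trace is reproducible from
#' `(J, config, seed)`.
#'
#' @param J Connectivity matrix.
#' @param temperature Heat-bath temperature, > 0.
#' @param n_thermalization Discarded equilibration time steps (default 500).
#' @param n_iterations Recorded time steps (default 2000).
#' @param update_mode `"sequential"` (random single-site Metropolis attempts;
#'   samples the Boltzmann distribution) or `"synchronous"` (all spins at
#'   once; the dynamics encoded by the TPM).
#' @param seed Optional integer seed (`set.seed()` is called if given).
#' @return An `ising_trace`: data frame with columns `iteration`,
#'   `state_code`, `magnetization`, `energy`, and the configuration stored in
#'   attributes.
#' @export
#' @examples
#' J <- generate_random_network(5, seed = 1)
#' tr <- simulate_ising(J, temperature = 2, seed = 42)
#' mean(tr$magnetization)
simulate_ising <- function(J, temperature,
                           n_thermalization = 500, n_iterations = 2000,
                           update_mode = c("sequential", "synchronous"),
                           seed = NULL) {
  update_mode <- match.arg(update_mode)
  W <- validate_connectivity(J)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  stopifnot(n_thermalization >= 0, n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate(W, temperature, as.integer(n_thermalization),
                      as.integer(n_iterations),
                      update_mode == "synchronous")
  out <- data.frame(iteration = seq_len(n_iterations),
                    state_code = res$state_code,
                    magnetization = res$magnetization,
                    energy = res$energy)
  class(out) <- c("ising_trace", "data.frame")
  attr(out, "config") <- list(temperature = temperature,
                              n_thermalization = n_thermalization,
                              n_iterations = n_iterations,
                              update_mode = update_mode, seed = seed,
                              n_nodes = nrow(W),
                              label = attr(J, "label"))
  out
}

#' Logarithmic temperature grid
#'
#' `n_points` log-uniformly spaced temperatures, endpoints inclusive. The
#' defaults (200 points in \[0.1, 4\]) are the sweep resolution of the study
#' design this package emulates.
#'
#' @param n_points Number of temperatures (>= 2).
#' @param low,high Grid endpoints, `0 < low < high`.
#' @export
temperature_grid <- function(n_points = 200, low = 0.1, high = 4) {
  if (low <= 0 || low >= high) {
    stop("need 0 < low < high for a logarithmic grid", call. = FALSE)
  }
  stopifnot(n_points >= 2)
  exp(seq(log(low), log(high), length.out = n_points))
}

#' Persist a simulation trace as CSV plus JSON metadata
#'
#' @param trace An `ising_trace`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(attr(trace, "config"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
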