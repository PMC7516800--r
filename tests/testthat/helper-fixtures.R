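# Shared fixtures and small oracles, all built in code.

# single coupled pair with unit weight
two_node_J <- function() matrix(c(0, 1, 1, 0), 2, 2)

# deterministic complement map: the synchronous kernel of a zero-coupling
# network (every flip has dE = 0, so every spin flips with probability 1)
zero_coupling_tpm <- function(n) {
  S <- spin_states(n)
  tpm <- ifelse(S == 1, 0, 1)
  structure(tpm, class = c("state_by_node_tpm", "matrix"),
            temperature = 1, n_nodes = n)
}

# pure-R reference simulator replicating the C++ draw order exactly:
# initialization draws one variate per spin; a synchronous time step draws
# one variate per node (node order); a sequential time step performs n
# single-site attempts, each drawing (site, acceptance)
r_reference_simulate <- function(J, temperature, n_thermalization,
                                 n_iterations, update_mode, seed) {
  set.seed(seed)
  n <- nrow(J)
  spins <- ifelse(stats::runif(n) < 0.5, -1, 1)
  out <- data.frame(state_code = integer(n_iterations),
                    magnetization = numeric(n_iterations),
                    energy = numeric(n_iterations))
  for (t in seq_len(n_thermalization + n_iterations)) {
    spins <- if (update_mode == "synchronous") {
      step_synchronous(spins, J, temperature)
    } else {
      for (k in seq_len(n)) spins <- step_sequential(spins, J, temperature)
      spins
    }
    if (t > n_thermalization) {
      k <- t - n_thermalization
      out$state_code[k] <- state_to_code(spins)
      out$magnetization[k] <- magnetization(spins)
      out$energy[k] <- hamiltonian(spins, J)
    }
  }
  out
}

# simulate the synchronous chain of an arbitrary state-by-node TPM (each
# node updated independently from its conditional, given the current state)
simulate_sbn_chain <- function(sbn, n_steps, seed) {
  set.seed(seed)
  n <- ncol(sbn)
  code <- sample(0:(2^n - 1), 1)
  codes <- integer(n_steps)
  for (t in seq_len(n_steps)) {
    p <- sbn[code + 1, ]
    bits <- as.integer(stats::runif(n) < p)
    code <- sum(bits * 2^(0:(n - 1)))
    codes[t] <- code
  }
  codes
}

# standard error of a time average from an autocorrelated series via
# non-overlapping batch means
batch_se <- function(x, n_batches = 20) {
  n <- length(x)
  size <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

phi_reference_dir <- function() {
  system.file("extdata", "phi_reference", package = "isingphi")
}

read_plain_tpm <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  structure(m, class = c("state_by_node_tpm", "matrix"))
}
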