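#' State-by-node transition probability matrix of the synchronous dynamics
#'
#' Under the synchronous Metropolis update every node flips independently,
#' conditioned on the current global state, so the one-step dynamics are
#' fully described by a `2^n x n` matrix whose `(s, i)` entry is the
#' probability that node `i` is up (+1) at `t+1` given global state `s` at
#' `t`. Rows are in little-endian state order (see [state_to_code()]). This
#' conditionally independent, state-by-node form is the input required by the
#' Phi engine.
#'
#' @param J Connectivity matrix (n <= 12 nodes).
#' @param temperature Heat-bath temperature, > 0.
#' @return A `state_by_node_tpm`: `2^n x n` matrix with attributes
#'   `temperature`, `n_nodes`, `label`.
#' @export
#' @examples
#' J <- matrix(c(0, 1, 1, 0), 2, 2)
#' build_tpm(J, temperature = 1)
build_tpm <- function(J, temperature) {
  W <- as.matrix(J)
  n <- nrow(W)
  if (n > 12) stop("dense TPMs are limited to n <= 12 nodes", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  S <- spin_states(n)
  dE <- 2 * S * (S %*% W)                   # (state, node) flip costs
  p_flip <- ifelse(dE > 0, exp(-dE / temperature), 1)
  p_up <- ifelse(S == 1, 1 - p_flip, p_flip)
  structure(p_up, class = c("state_by_node_tpm", "matrix"),
            temperature = temperature, n_nodes = n, label = attr(J, "label"))
}

#' Expand a state-by-node TPM to the full state-by-state Markov kernel
#'
#' `P(s -> s') = prod_i p_i(s)^{[s'_i = +1]} (1 - p_i(s))^{[s'_i = -1]}`:
#' the product of the per-node conditionals, valid because synchronous
#' updates are conditionally independent. Rows sum to 1.
#'
#' @param sbn A `state_by_node_tpm` (or plain `2^n x n` probability matrix).
#' @return A row-stochastic `2^n x 2^n` matrix over little-endian state codes.
#' @export
tpm_state_by_state <- function(sbn) {
  p <- unclass(as.matrix(sbn))
  n <- ncol(p)
  ns <- nrow(p)
  stopifnot(ns == 2^n, all(p >= 0), all(p <= 1))
  bits <- (outer(0:(ns - 1), 0:(n - 1), function(s, b) (s %/% 2^b) %% 2))
  P <- matrix(1, ns, ns)
  for (i in seq_len(n)) {
    # factor for node i: rows index s (current), cols index s' (next)
    P <- P * outer(p[, i], bits[, i], function(pi, b) ifelse(b == 1, pi, 1 - pi))
  }
  structure(P, class = c("state_by_state_tpm", "matrix"),
            temperature = attr(sbn, "temperature"), n_nodes = n,
            label = attr(sbn, "label"))
}

#' Collapse a state-by-state kernel back to per-node marginals
#'
#' Inverse of [tpm_state_by_state()] for conditionally independent kernels;
#' used as a round-trip consistency check.
#'
#' @param P Row-stochastic `2^n x 2^n` matrix.
#' @export
collapse_tpm <- function(P) {
  P <- as.matrix(P)
  ns <- nrow(P)
  n <- round(log2(ns))
  stopifnot(2^n == ns)
  bits <- outer(0:(ns - 1), 0:(n - 1), function(s, b) (s %/% 2^b) %% 2)
  P %*% bits
}

#' Stationary distribution of a synchronous Ising chain
#'
#' Left fixed point `pi P = pi` of the state-by-state kernel, computed by
#' dense eigen-decomposition with a power-iteration fallback. The chain must
#' be ergodic: strong connectivity and aperiodicity of the positive-entry
#' support graph are checked first, and a chain without a unique stationary
#' law (e.g. the deterministic period-2 complement map of a zero-coupling
#' network) raises an error.
#'
#' @param P A `state_by_state_tpm` (or any row-stochastic matrix).
#' @param tol Entries below `tol` are treated as structural zeros.
#' @return Probability vector `pi` with `max |pi P - pi| < 1e-12` and
#'   residual 1-norm below 1e-10.
#' @export
stationary_distribution <- function(P, tol = 1e-14) {
  P <- unclass(as.matrix(P))
  ns <- nrow(P)
  stopifnot(ncol(P) == ns, all(abs(rowSums(P) - 1) < 1e-9))
  adj <- P > tol
  if (!is_strongly_connected(adj)) {
    stop("chain is reducible: no unique stationary distribution", call. = FALSE)
  }
  if (graph_period(adj) != 1L) {
    stop("chain is periodic: no unique stationary distribution", call. = FALSE)
  }
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  pi_ <- abs(v) / sum(abs(v))
  if (sum(abs(pi_ %*% P - pi_)) > 1e-10) {
    # power-iteration fallback for ill-conditioned eigenproblems
    pi_ <- rep(1 / ns, ns)
    for (it in seq_len(100000)) {
      nxt <- drop(pi_ %*% P)
      if (sum(abs(nxt - pi_)) < 1e-14) { pi_ <- nxt; break }
      pi_ <- nxt
    }
    if (sum(abs(pi_ %*% P - pi_)) > 1e-10) {
      stop("stationary distribution did not converge", call. = FALSE)
    }
  }
  pi_ / sum(pi_)
}

# BFS-based strong-connectivity check on a small dense adjacency matrix.
is_strongly_connected <- function(adj) {
  reach <- function(A) {
    seen <- rep(FALSE, nrow(A)); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier) > 0) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

# Period of a strongly connected graph: gcd over edges (u, v) of
# level(u) + 1 - level(v), levels from a BFS tree.
graph_period <- function(adj) {
  ns <- nrow(adj)
  level <- rep(NA_integer_, ns); level[1] <- 0L
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      vs <- which(adj[u, ] & is.na(level))
      level[vs] <- level[u] + 1L
      nxt <- c(nxt, vs)
    }
    frontier <- nxt
  }
  g <- 0L
  edges <- which(adj, arr.ind = TRUE)
  for (k in seq_len(nrow(edges))) {
    d <- level[edges[k, 1]] + 1L - level[edges[k, 2]]
    g <- gcd_int(g, abs(d))
  }
  if (g == 0L) 1L else g
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Read / write state-by-node TPMs as CSV with JSON sidecar
#'
#' @param tpm A `state_by_node_tpm`.
#' @param path CSV path; the sidecar `<path>.json` records the node count,
#'   state ordering, temperature and network label.
#' @export
write_tpm <- function(tpm, path) {
  utils::write.csv(unclass(as.matrix(tpm)), path, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = attr(tpm, "n_nodes"),
                            ordering = "little-endian",
                            temperature = attr(tpm, "temperature"),
                            label = attr(tpm, "label")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_tpm
#' @export
read_tpm <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  dimnames(m) <- NULL
  n <- ncol(m)
  if (nrow(m) != 2^n) {
    stop(sprintf("TPM must have 2^n rows: got %d rows for %d nodes", nrow(m), n),
         call. = FALSE)
  }
  if (any(m < 0 | m > 1)) stop("TPM entries must lie in [0, 1]", call. = FALSE)
  meta_path <- paste0(path, ".json")
  temperature <- NULL; label <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    temperature <- meta$temperature; label <- meta$label
  }
  structure(m, class = c("state_by_node_tpm", "matrix"),
            temperature = temperature, n_nodes = n, label = label)
}

#' @export
as.matrix.state_by_node_tpm <- function(x, ...) {
  y <- unclass(x)
  attr(y, "temperature") <- NULL
  attr(y, "n_nodes") <- NULL
  attr(y, "label") <- NULL
  y
}

#' @export
as.matrix.state_by_state_tpm <- function(x, ...) {
  y <- unclass(x)
  attr(y, "temperature") <- NULL
  attr(y, "n_nodes") <- NULL
  attr(y, "label") <- NULL
  y
}
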