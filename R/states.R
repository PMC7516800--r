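#' Encode a spin configuration as an integer state code
#'
#' States are coded little-endian: node 1 is the least-significant bit, with
#' spin +1 mapped to bit 1 and spin -1 to bit 0. This single convention is
#' shared by the simulator, the transition-probability matrices and the Phi
#' engine, so a code produced by one component can be consumed by any other.
#'
#' @param spins Integer or numeric vector with entries in \{-1, +1\}.
#' @return A single integer in `0:(2^n - 1)` where `n = length(spins)`.
#' @seealso [code_to_state()]
#' @export
#' @examples
#' state_to_code(c(1, -1, 1))   # bits 101 -> 5
state_to_code <- function(spins) {
  if (!all(spins %in% c(-1, 1))) {
    stop("spins must be a vector of -1/+1 values", call. = FALSE)
  }
  bits <- (spins + 1L) %/% 2L
  as.integer(sum(bits * 2^(seq_along(spins) - 1L)))
}

#' Decode an integer state code into a spin configuration
#'
#' @param code Integer state code in `0:(2^n - 1)`.
#' @param n_nodes Number of spins.
#' @return Numeric vector of -1/+1 spins, node 1 first (little-endian).
#' @export
code_to_state <- function(code, n_nodes) {
  stopifnot(length(code) == 1L, code >= 0, code < 2^n_nodes)
  bits <- (code %/% 2^(0:(n_nodes - 1L))) %% 2
  2 * bits - 1
}

#' All spin configurations of an n-node system
#'
#' @param n_nodes Number of spins (n <= 20 guard).
#' @return A `2^n x n` matrix of -1/+1 spins; row `k` is the configuration
#'   with state code `k - 1`.
#' @export
spin_states <- function(n_nodes) {
  stopifnot(n_nodes >= 1, n_nodes <= 20)
  codes <- 0:(2^n_nodes - 1)
  bits <- outer(codes, 0:(n_nodes - 1), function(s, b) (s %/% 2^b) %% 2)
  2 * bits - 1
}

# Population variance (1/N), the convention used by every fluctuation
# statistic in this package.
pop_var <- function(x) mean(x^2) - mean(x)^2

#' Derive child seeds from a master seed
#'
#' Deterministically derives `count` distinct child seeds without disturbing
#' the caller's RNG stream. Ensemble generation and temperature sweeps give
#' every work unit its own derived seed, so any unit can be reproduced in
#' isolation and results do not depend on execution order.
#'
#' @param master_seed Integer seed.
#' @param count Number of child seeds (>= 1).
#' @return Integer vector of `count` distinct seeds.
#' @export
derive_seeds <- function(master_seed, count) {
  stopifnot(count >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, count)
}
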