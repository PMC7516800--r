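#' Cause and effect repertoires of a mechanism
#'
#' Core probability objects of IIT 3.0. The cause repertoire is the
#' distribution over past states of the purview implied by the mechanism's
#' current state under a maximum-entropy prior on the past; the effect
#' repertoire is the distribution over next-step purview states given the
#' mechanism's current state with all other inputs marginalized uniformly.
#' Repertoires are indexed little-endian over the purview's nodes in
#' ascending order.
#'
#' @param tpm A `state_by_node_tpm` from [build_tpm()] (or a `2^n x n`
#'   probability matrix; conditional independence of the per-node updates is
#'   assumed, which holds by construction for synchronous Ising kernels).
#' @param state Full system spin state (-1/+1 vector) or integer state code.
#' @param mechanism Integer vector of node indices (1-based), nonempty.
#' @param purview Integer vector of node indices, nonempty.
#' @return Numeric probability vector of length `2^length(purview)`.
#' @export
cause_repertoire <- function(tpm, state, mechanism, purview) {
  cpp_cause_repertoire(prep_tpm(tpm), prep_state(state, tpm),
                       as.integer(mechanism), as.integer(purview))
}

#' @rdname cause_repertoire
#' @export
effect_repertoire <- function(tpm, state, mechanism, purview) {
  cpp_effect_repertoire(prep_tpm(tpm), prep_state(state, tpm),
                        as.integer(mechanism), as.integer(purview))
}

#' Earth-mover distance between repertoires
#'
#' Exact EMD with Hamming ground metric between two distributions over the
#' same purview, solved as a small min-cost-flow problem. This is the
#' distance that drives every partition comparison in the Phi engine.
#'
#' @param p,q Probability vectors of equal power-of-two length.
#' @export
repertoire_emd <- function(p, q) {
  if (length(p) != length(q)) {
    stop("repertoires must live on the same purview", call. = FALSE)
  }
  cpp_emd_hamming(as.numeric(p), as.numeric(q))
}

#' Integrated information of a single mechanism (small phi)
#'
#' The irreducibility of one mechanism's cause or effect repertoire: the
#' EMD between the whole repertoire and the closest partitioned
#' (factorized) repertoire, minimized over mechanism/purview bipartitions
#' and maximized over candidate purviews. Purview ties at equal phi prefer
#' the larger purview.
#'
#' @inheritParams cause_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @return List with `phi` and the maximally irreducible `purview`.
#' @export
small_phi <- function(tpm, state, mechanism, direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  cpp_small_phi(prep_tpm(tpm), prep_state(state, tpm),
                as.integer(mechanism), direction)
}

#' Cause-effect structure of a system state
#'
#' All concepts (mechanisms with irreducible cause and effect) of the system
#' in the given state: per concept the mechanism, its small phi (the minimum
#' of the cause and effect values) and the two core purviews.
#'
#' @inheritParams cause_repertoire
#' @return A data frame with one row per concept: `mechanism` (comma-joined
#'   node indices), `phi`, `phi_cause`, `phi_effect`, `cause_purview`,
#'   `effect_purview`.
#' @export
compute_ces <- function(tpm, state) {
  res <- cpp_ces(prep_tpm(tpm), prep_state(state, tpm))
  fmt <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))
  mechs <- vapply(res$mechanism_mask, function(m) {
    paste(which(bitwAnd(m, 2^(0:30)) > 0), collapse = ",")
  }, character(1))
  data.frame(mechanism = mechs, phi = res$phi,
             phi_cause = res$phi_cause, phi_effect = res$phi_effect,
             cause_purview = fmt(res$cause_purview),
             effect_purview = fmt(res$effect_purview),
             stringsAsFactors = FALSE)
}

#' Integrated conceptual information of a system state (big Phi)
#'
#' The distance between the system's cause-effect structure and the closest
#' structure obtainable after a unidirectional system cut, minimized over
#' all `2^n - 2` cuts. A positive value means no way of severing the system
#' into feed-forward parts preserves its cause-effect structure; zero means
#' the system is reducible in this state. Guarded to `n <= 5` nodes: the
#' search cost grows super-exponentially with system size.
#'
#' @inheritParams cause_repertoire
#' @return List with `phi`, the minimizing cut (`cut_from` severed toward
#'   `cut_to`), `n_concepts` and `sum_small_phi`.
#' @export
#' @examples
#' J <- generate_random_network(3, seed = 1)
#' tpm <- build_tpm(J, temperature = 1.5)
#' big_phi(tpm, code_to_state(0, 3))$phi
big_phi <- function(tpm, state) {
  cpp_big_phi(prep_tpm(tpm), prep_state(state, tpm))
}

#' Phi for a set of states, with per-state caching
#'
#' Evaluates [big_phi()] once per distinct state code and reuses the value,
#' the key cost optimization for temperature sweeps: at n = 5 a sweep
#' needs at most 32 Phi evaluations per temperature regardless of trace
#' length.
#'
#' Phi additionally inherits the global spin-flip symmetry of field-free
#' Ising dynamics: complementing every spin maps the TPM onto itself (up and
#' down swap roles), so `Phi(s) == Phi(complement(s))` exactly. With
#' `symmetry = "auto"` (default) this is exploited whenever the supplied TPM
#' passes the complement-symmetry check, halving the number of distinct
#' evaluations; `"none"` always evaluates every state directly.
#'
#' @inheritParams cause_repertoire
#' @param codes Integer state codes (possibly with repeats, e.g. a trace).
#' @param cache Optional environment reused across calls at the same
#'   (network, temperature).
#' @param symmetry `"auto"` or `"none"`; see Details.
#' @return Numeric vector of Phi values, one per element of `codes`.
#' @export
phi_states <- function(tpm, codes, cache = new.env(parent = emptyenv()),
                       symmetry = c("auto", "none")) {
  symmetry <- match.arg(symmetry)
  tpm_m <- prep_tpm(tpm)
  n <- ncol(tpm_m)
  use_flip <- symmetry == "auto" && tpm_flip_symmetric(tpm_m)
  canon <- function(code) {
    if (use_flip) min(code, 2^n - 1 - code) else code
  }
  uniq <- unique(codes)
  for (code in uniq) {
    key <- as.character(canon(code))
    if (is.null(cache[[key]])) {
      cache[[key]] <- cpp_big_phi(tpm_m, code_to_state(canon(code), n))$phi
    }
  }
  vapply(codes, function(code) cache[[as.character(canon(code))]], numeric(1))
}

# TRUE if complementing the state maps the TPM onto itself with up/down
# swapped: p(i on | s) == 1 - p(i on | complement(s)) for all s, i.
tpm_flip_symmetric <- function(tpm_m, tol = 1e-12) {
  ns <- nrow(tpm_m)
  max(abs(tpm_m + tpm_m[ns:1, , drop = FALSE] - 1)) < tol
}

#' Phi statistics over a simulation trace
#'
#' Evaluates Phi for each state visited by the trace (cached per distinct
#' state), then summarizes it like any other observable: the time average
#' and the generalized susceptibility `chi_Phi = <Phi^2> - <Phi>^2`.
#' Optionally the average can be taken under the exact stationary
#' distribution of the synchronous chain instead of visit frequencies.
#'
#' @param trace An `ising_trace` from [simulate_ising()].
#' @param tpm The synchronous `state_by_node_tpm` at the same temperature.
#' @param weighting `"visit"` (default): weight states by visit frequency in
#'   the trace; `"stationary"`: weight all `2^n` states by the exact
#'   stationary law of the synchronous chain.
#' @return List with `phi_mean`, `chi_phi`, and `per_state` (data frame of
#'   state code, Phi, and weight).
#' @export
phi_over_trace <- function(trace, tpm, weighting = c("visit", "stationary")) {
  weighting <- match.arg(weighting)
  tpm_m <- prep_tpm(tpm)
  n <- ncol(tpm_m)
  cache <- new.env(parent = emptyenv())
  if (weighting == "visit") {
    series <- phi_states(tpm_m, trace$state_code, cache)
    tab <- table(trace$state_code)
    codes <- as.integer(names(tab))
    weights <- as.numeric(tab) / length(trace$state_code)
    phis <- phi_states(tpm_m, codes, cache)
    list(phi_mean = mean(series),
         chi_phi = generalized_susceptibility(series),
         per_state = data.frame(state_code = codes, phi = phis,
                                weight = weights))
  } else {
    P <- tpm_state_by_state(tpm_m)
    pi_ <- stationary_distribution(P)
    codes <- 0:(2^n - 1)
    phis <- phi_states(tpm_m, codes, cache)
    mu <- sum(pi_ * phis)
    list(phi_mean = mu,
         chi_phi = sum(pi_ * phis^2) - mu^2,
         per_state = data.frame(state_code = codes, phi = phis,
                                weight = pi_))
  }
}

# Normalize tpm / state arguments for the C++ interface.
prep_tpm <- function(tpm) {
  m <- unclass(as.matrix(tpm))
  storage.mode(m) <- "double"
  m
}

prep_state <- function(state, tpm) {
  n <- ncol(as.matrix(tpm))
  if (length(state) == n && all(state %in% c(-1, 1))) {
    return(as.numeric(state))
  }
  if (length(state) == 1 && state >= 0 && state < 2^n) {
    return(code_to_state(state, n))
  }
  stop("state must be a full -1/+1 spin vector or an integer state code",
       call. = FALSE)
}
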