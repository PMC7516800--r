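#' Summary statistics of Ising observables
#'
#' All fluctuation statistics use the population (1/N) variance, and the
#' magnetization carries the absolute value, so simulated and
#' exact-enumeration values are directly comparable.
#'
#' @param spins Vector of -1/+1 spins.
#' @return `magnetization()`: `|sum(s)| / N`, in \[0, 1\].
#' @name observables
NULL

#' @rdname observables
#' @export
magnetization <- function(spins) abs(sum(spins)) / length(spins)

#' @rdname observables
#' @param series Numeric vector of per-iteration observable values.
#' @export
time_average <- function(series) mean(series)

#' Magnetic susceptibility from a magnetization series
#'
#' `chi = (<M^2> - <M>^2) / T`: the temperature-scaled temporal fluctuation
#' of the order parameter. Its peak over a temperature sweep locates the
#' critical temperature.
#'
#' @param m_series Per-iteration magnetization values.
#' @param temperature Heat-bath temperature.
#' @export
magnetic_susceptibility <- function(m_series, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  pop_var(m_series) / temperature
}

#' Generalized susceptibility of an arbitrary observable
#'
#' `chi_O = <O^2> - <O>^2`: the plain temporal variance, with no division by
#' temperature. Applied to integrated information it yields chi_Phi, the
#' quantity whose peak demarcates the phase transition of Phi.
#'
#' @param series Per-iteration observable values.
#' @export
generalized_susceptibility <- function(series) pop_var(series)

#' Specific heat from an energy series
#'
#' `Cv = (<E^2> - <E>^2) / T^2`, the standard canonical fluctuation form.
#'
#' @param e_series Per-iteration energies.
#' @param temperature Heat-bath temperature.
#' @export
specific_heat <- function(e_series, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  pop_var(e_series) / temperature^2
}

#' Across-network variance of an observable
#'
#' `sigma_J^2(O) = <<O>^2>_J - <<O>>_J^2`: the population variance, across
#' networks, of per-network time averages. It quantifies how strongly the
#' choice of connectivity matrix influences an observable at a given
#' temperature.
#'
#' @param per_network_means One time-averaged value per network.
#' @export
ensemble_variance <- function(per_network_means) pop_var(per_network_means)

#' Summarize a simulation trace at one temperature
#'
#' @param trace An `ising_trace` from [simulate_ising()].
#' @return One-row data frame with `M_mean`, `E_mean`, `chi`, `Cv`, and the
#'   temperature.
#' @export
summarize_trace <- function(trace) {
  temperature <- attr(trace, "config")$temperature
  data.frame(temperature = temperature,
             M_mean = mean(trace$magnetization),
             E_mean = mean(trace$energy),
             chi = magnetic_susceptibility(trace$magnetization, temperature),
             Cv = specific_heat(trace$energy, temperature))
}
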