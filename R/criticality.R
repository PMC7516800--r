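#' Temperature sweep of one network
#'
#' For each temperature: run a seeded Metropolis simulation, summarize the
#' thermodynamic observables, and (optionally) build the synchronous TPM,
#' evaluate Phi once per visited state and summarize it like any other
#' observable. Per-temperature seeds are derived deterministically from
#' `seed`, so any single (network, temperature) cell can be reproduced in
#' isolation and results are independent of execution order.
#'
#' @param J Connectivity matrix.
#' @param temperatures Temperature grid (see [temperature_grid()]).
#' @param n_thermalization,n_iterations Simulation protocol (defaults 500 and
#'   2000 steps).
#' @param update_mode Update scheme for the trace; `"sequential"` (default)
#'   samples the Boltzmann distribution, which is what the susceptibility and
#'   specific-heat peaks assume. Phi always uses the synchronous TPM.
#' @param compute_phi If `TRUE`, add `Phi_mean` and `chi_Phi` columns
#'   (requires `n <= 5` nodes).
#' @param phi_weighting Passed to [phi_over_trace()].
#' @param seed Integer seed for the whole sweep.
#' @return A `sweep_result`: data frame with one row per temperature and
#'   columns `temperature`, `M_mean`, `E_mean`, `chi`, `Cv` (plus `Phi_mean`,
#'   `chi_Phi`), with the network label and config in attributes.
#' @export
sweep_network <- function(J, temperatures,
                          n_thermalization = 500, n_iterations = 2000,
                          update_mode = c("sequential", "synchronous"),
                          compute_phi = FALSE,
                          phi_weighting = c("visit", "stationary"),
                          seed = 1) {
  update_mode <- match.arg(update_mode)
  phi_weighting <- match.arg(phi_weighting)
  stopifnot(length(temperatures) >= 1, all(temperatures > 0))
  seeds <- derive_seeds(seed, length(temperatures))
  rows <- lapply(seq_along(temperatures), function(k) {
    T_ <- temperatures[k]
    tr <- simulate_ising(J, T_, n_thermalization, n_iterations,
                         update_mode = update_mode, seed = seeds[k])
    row <- summarize_trace(tr)
    if (compute_phi) {
      tpm <- build_tpm(J, T_)
      ph <- phi_over_trace(tr, tpm, weighting = phi_weighting)
      row$Phi_mean <- ph$phi_mean
      row$chi_Phi <- ph$chi_phi
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "label") <- attr(J, "label")
  attr(out, "config") <- list(n_thermalization = n_thermalization,
                              n_iterations = n_iterations,
                              update_mode = update_mode,
                              compute_phi = compute_phi, seed = seed)
  out
}

#' Locate the peak of a susceptibility curve
#'
#' Temperature of the curve's maximum, after an optional centered moving
#' average (default window 5 grid points; raw Monte-Carlo curves at a few
#' thousand iterations are noisy, so smoothing is on by default and the
#' window shrinks symmetrically at the grid edges). Ties resolve to the
#' lowest temperature; a constant curve warns about a degenerate peak.
#'
#' @param temperatures Increasing temperature grid.
#' @param values Curve values, one per temperature.
#' @param smooth Moving-average window in grid points (odd; `1` = raw).
#' @return List with `T_peak`, `value` (smoothed value at the peak) and
#'   `index` into the grid.
#' @export
find_peak <- function(temperatures, values, smooth = 5) {
  stopifnot(length(temperatures) == length(values), smooth >= 1)
  sm <- moving_average(values, smooth)
  if (max(sm) - min(sm) < .Machine$double.eps * 100) {
    warning("degenerate peak: curve is constant; returning the lowest temperature")
  }
  idx <- which.max(sm) # which.max takes the first (lowest-T) maximum
  list(T_peak = temperatures[idx], value = sm[idx], index = idx)
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Sweep an ensemble of networks
#'
#' Runs [sweep_network()] on each network with per-network seeds derived
#' from `master_seed`. Work units are independent, so results are identical
#' regardless of execution order.
#'
#' @param networks List of connectivity matrices (e.g. from
#'   [generate_ensemble()]).
#' @inheritParams sweep_network
#' @param master_seed Seed for the whole ensemble sweep.
#' @return List of `sweep_result` objects.
#' @export
sweep_ensemble <- function(networks, temperatures, ...,
                           master_seed = 1) {
  seeds <- derive_seeds(master_seed, length(networks))
  lapply(seq_along(networks), function(k) {
    sweep_network(networks[[k]], temperatures, ..., seed = seeds[k])
  })
}

#' Ensemble summary: mean curves, spread, and consensus critical temperature
#'
#' Pointwise means and standard deviations of every observable across
#' networks, the across-network variance `sigma_J^2` of the per-network
#' values at each temperature, and peak temperatures of the ensemble-mean
#' susceptibility curves. The consensus critical temperature `Tc_chi` is
#' the peak of the mean-chi curve (the mean-curve peak, not the mean of
#' per-network peaks; per-network peaks are also returned).
#'
#' @param results List of `sweep_result` objects on a common grid.
#' @param smooth Peak-detection smoothing window (see [find_peak()]).
#' @return List with `curves` (data frame of per-temperature means, SDs and
#'   `sigma_J2` columns), `Tc_chi`, `Tc_Cv`, `Tc_chi_Phi` (when present),
#'   and `per_network_Tc_chi`.
#' @export
summarize_ensemble <- function(results, smooth = 5) {
  stopifnot(length(results) >= 2)
  temps <- results[[1]]$temperature
  for (r in results) {
    if (!isTRUE(all.equal(r$temperature, temps))) {
      stop("all sweeps must share one temperature grid", call. = FALSE)
    }
  }
  obs <- setdiff(colnames(results[[1]]), "temperature")
  curves <- data.frame(temperature = temps)
  for (o in obs) {
    mat <- vapply(results, function(r) r[[o]], numeric(length(temps)))
    curves[[paste0(o, "_mean")]] <- rowMeans(mat)
    curves[[paste0(o, "_sd")]] <- apply(mat, 1, stats::sd)
    curves[[paste0(o, "_sigma_J2")]] <- apply(mat, 1, pop_var)
  }
  out <- list(curves = curves,
              Tc_chi = find_peak(temps, curves$chi_mean, smooth)$T_peak,
              Tc_Cv = find_peak(temps, curves$Cv_mean, smooth)$T_peak)
  if ("chi_Phi_mean" %in% colnames(curves)) {
    out$Tc_chi_Phi <- find_peak(temps, curves$chi_Phi_mean, smooth)$T_peak
  }
  out$per_network_Tc_chi <- vapply(results, function(r) {
    find_peak(temps, r$chi, smooth)$T_peak
  }, numeric(1))
  out
}

#' Write sweep results as CSV plus JSON metadata
#'
#' @param result A `sweep_result`.
#' @param path Output CSV path; config and label go to `<path>.json`.
#' @export
write_sweep <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  meta <- attr(result, "config")
  meta$label <- attr(result, "label")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("sweep_result", "data.frame")
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "label") <- meta$label
    meta$label <- NULL
    attr(out, "config") <- meta
  }
  out
}
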