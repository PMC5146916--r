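# Free-chain validation studies: center-of-mass diffusion and gyration
# radius across chain lengths, the two observables that anchor the polymer
# model against exact Rouse/Flory expectations.

#' Simulate a free structured chain
#'
#' Runs a membrane-free chain at `T_p` with the Langevin thermostat and
#' records the polymer center of mass and gyration radius.
#'
#' @inheritParams free_chain_system
#' @param n_steps Production steps.
#' @param therm_steps Discarded equilibration steps.
#' @param sample_stride Steps between samples.
#' @param dt,xi Integrator settings.
#' @return A list with the final `system` and the `samples` tibble.
#' @export
simulate_free_chain <- function(n, n_steps, therm_steps = 2e4,
                                sample_stride = 50L, dt = 5e-3, xi = 1,
                                T_p = 1.5, seed = NULL, kf = 30) {
  sys <- free_chain_system(n, seed = seed, T_p = T_p, kf = kf)
  th <- thermostat_spec(T_p = T_p, T_m = 0, xi = xi, dt = dt)
  if (therm_steps > 0) sys <- run_langevin(sys, therm_steps, th)$system
  out <- run_langevin(sys, n_steps, th, sample_stride = sample_stride)
  list(system = out$system, samples = out$samples)
}

#' Center-of-mass diffusion across chain lengths
#'
#' For each repeat count in `n_values`, simulates `replicates` independent
#' free chains, estimates `D` from the center-of-mass MSD slope of each
#' replicate, and averages. The expected scaling is `D = k_B T / (N xi)`.
#'
#' @param n_values Repeat counts (chains of `N = 3n + 1` beads).
#' @param replicates Independent chains per length.
#' @param n_steps Production steps per replicate.
#' @param msd_window Lag-time window for the MSD slope fit.
#' @param seed Master seed; replicate `j` of length `i` derives its own.
#' @inheritParams simulate_free_chain
#' @return A tibble with columns `n`, `N`, `D`, `D_se`.
#' @export
free_chain_diffusion <- function(n_values, replicates = 4, n_steps = 2e5,
                                 msd_window = c(20, 200), sample_stride = 20L,
                                 dt = 5e-3, xi = 1, T_p = 1.5, seed = 1,
                                 therm_steps = 1e4) {
  rows <- vector("list", length(n_values))
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    Ds <- vapply(seq_len(replicates), function(j) {
      sim <- simulate_free_chain(n, n_steps, therm_steps = therm_steps,
                                 sample_stride = sample_stride, dt = dt,
                                 xi = xi, T_p = T_p,
                                 seed = seed + 1000L * i + j)
      diffusion_constant(sim$samples, window = msd_window)$D
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      n = n, N = 3L * n + 1L, D = mean(Ds),
      D_se = if (replicates > 1) stats::sd(Ds) / sqrt(replicates) else NA_real_)
  }
  dplyr::bind_rows(rows)
}

#' Equilibrium gyration radius across chain lengths
#'
#' For each repeat count, simulates `replicates` independent free chains and
#' averages the gyration radius over decorrelated production samples. The
#' chain relaxation time grows roughly as the squared bead count, so
#' `replicates`, `n_steps` and `therm_steps` may be vectors along
#' `n_values`, letting longer chains equilibrate and sample longer.
#'
#' @inheritParams free_chain_diffusion
#' @param replicates,n_steps,therm_steps Scalars or vectors recycled along
#'   `n_values`.
#' @return A tibble with columns `n`, `N`, `rg`, `rg_se` (the standard error
#'   across replicate means).
#' @export
free_chain_rg <- function(n_values, replicates = 4, n_steps = 1e5,
                          sample_stride = 250L, dt = 5e-3, xi = 1, T_p = 1.5,
                          seed = 1, therm_steps = 2e4) {
  replicates <- rep_len(replicates, length(n_values))
  n_steps <- rep_len(n_steps, length(n_values))
  therm_steps <- rep_len(therm_steps, length(n_values))
  rows <- vector("list", length(n_values))
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    rgs <- vapply(seq_len(replicates[i]), function(j) {
      sim <- simulate_free_chain(n, n_steps[i], therm_steps = therm_steps[i],
                                 sample_stride = sample_stride, dt = dt,
                                 xi = xi, T_p = T_p,
                                 seed = seed + 2000L * i + j)
      mean(sim$samples$rg)
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      n = n, N = 3L * n + 1L, rg = mean(rgs),
      rg_se = if (replicates[i] > 1) stats::sd(rgs) / sqrt(replicates[i]) else NA_real_)
  }
  dplyr::bind_rows(rows)
}
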