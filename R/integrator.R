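# Langevin dynamics driver: BAOAB splitting with an exact Ornstein-Uhlenbeck
# velocity sub-step, per-bead temperature and mass, and frozen-bead support.
# With friction xi = 0 the scheme reduces to velocity Verlet.

#' Thermostat specification
#'
#' Per-group Langevin thermostat settings: the polymer is held at `T_p`
#' (default 3/2) and the membrane at `T_m` with `0 <= T_m <= T_p`; both share
#' the friction coefficient `xi` (default 1) and the time step `dt` (default
#' 5e-3). The noise satisfies the fluctuation-dissipation relation
#' \eqn{\langle\eta_i(t)\eta_j(t')\rangle = 2 \xi k_B T \delta_{ij}
#' \delta(t-t')} for each group's temperature.
#'
#' @param T_p Polymer temperature (>= 0).
#' @param T_m Membrane temperature (>= 0).
#' @param xi Friction coefficient (>= 0; 0 disables both friction and noise).
#' @param dt Integration time step (> 0).
#' @return An object of class `poremd_thermostat`.
#' @export
thermostat_spec <- function(T_p = 1.5, T_m = 0, xi = 1, dt = 5e-3) {
  stopifnot(T_p >= 0, T_m >= 0, xi >= 0, dt > 0)
  structure(list(T_p = T_p, T_m = T_m, xi = xi, dt = dt),
            class = "poremd_thermostat")
}

# Internal: run the compiled BAOAB loop on a system and fold results back.
engine_run <- function(system, n_steps, dt, xi, sample_stride = 0L,
                       transloc = NULL, traj_stride = 0L,
                       traj_max_frames = 0L, skin = 0.3) {
  s <- system
  tr <- transloc
  res <- cpp_run(
    s$pos, s$vel, s$beads$kind - 1L,
    as.integer(s$beads$group == "membrane"), s$frozen, s$beads$mass, s$temp,
    s$ff$sigma, s$ff$eps,
    bonds_matrix(s), s$bonds$R0, s$bonds$K,
    s$tether_k, s$anchor, s$box[1], s$box[2], s$mm_pairs,
    if (s$pull_on) s$pulled - 1L else -1L, s$ff$F_pull,
    xi, dt, n_steps, skin,
    as.integer(sample_stride),
    !is.null(tr),
    if (is.null(tr)) 10L else as.integer(tr$check_stride),
    if (is.null(tr)) 1.5 else tr$slab_half,
    if (is.null(tr)) Inf else tr$fail_r2,
    if (is.null(tr)) Inf else tr$fail_sustain_steps,
    if (is.null(tr)) integer(0) else as.integer(tr$rim_idx - 1L),
    if (is.null(tr)) 1 / 3 else tr$rim_sigma,
    if (is.null(tr)) 0L else as.integer(tr$reff_stride),
    as.integer(traj_stride), as.integer(traj_max_frames))
  system$pos <- res$pos
  system$vel <- res$vel
  system$step <- system$step + as.integer(res$steps)
  system$time <- system$time + res$steps * dt
  list(system = system, res = res)
}

#' Advance a system with Langevin dynamics
#'
#' Integrates `n_steps` BAOAB steps at time step `dt`. Frozen beads (the
#' immobile membrane, or the pinned bead during thermalization) keep their
#' positions and velocities exactly. The run is bitwise reproducible for a
#' fixed R random seed.
#'
#' @param system A `poremd_system`.
#' @param n_steps Number of steps (>= 0).
#' @param thermostat A [thermostat_spec()]; the default `NULL` uses the
#'   temperatures stored in the system with `xi = 1`, `dt = 5e-3`.
#' @param sample_stride If > 0, record observables (polymer center of mass,
#'   gyration radius, kinetic energies per group, mean squared tether
#'   displacement per axis) every this many steps.
#' @param traj_stride,traj_max_frames If `traj_stride > 0`, store up to
#'   `traj_max_frames` full-position frames every `traj_stride` steps.
#' @param seed Optional seed set before the run.
#' @return A list with the advanced `system`, a `samples` tibble, the
#'   per-bead mean squared velocity `msv` over samples, and optionally a
#'   `traj` array of frames.
#' @export
run_langevin <- function(system, n_steps, thermostat = NULL,
                         sample_stride = 0L, traj_stride = 0L,
                         traj_max_frames = 1000L, seed = NULL) {
  stopifnot(inherits(system, "poremd_system"), n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(thermostat)) {
    thermostat <- thermostat_spec(T_p = system$T_p, T_m = system$T_m)
  }
  if (!inherits(thermostat, "poremd_thermostat")) {
    rlang::abort("thermostat must be a thermostat_spec()")
  }
  system$temp <- ifelse(system$beads$group == "membrane",
                        thermostat$T_m, thermostat$T_p)
  out <- engine_run(system, n_steps, thermostat$dt, thermostat$xi,
                    sample_stride = sample_stride, traj_stride = traj_stride,
                    traj_max_frames = traj_max_frames)
  samples <- tibble::as_tibble(out$res$samples)
  nsamp <- max(1, out$res$n_samples)
  traj <- NULL
  if (!is.null(out$res$traj)) {
    traj <- array(t(out$res$traj),
                  dim = c(3, nrow(system$pos), out$res$traj_frames))
    traj <- aperm(traj, c(2, 1, 3))
  }
  list(system = out$system, samples = samples,
       msv = out$res$sumv2 / nsamp, traj = traj)
}

#' @rdname run_langevin
#' @export
step_langevin <- function(system, thermostat = NULL, seed = NULL) {
  run_langevin(system, 1L, thermostat, seed = seed)$system
}
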