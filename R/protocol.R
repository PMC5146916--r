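# Translocation protocol: pin the first bead at the pore center, thermalize
# the cis-side chain, switch the pulling force on at t = 0, run until every
# polymer bead is on the trans side (or the trajectory fails / times out),
# and repeat over seeded ensembles.

#' Translocation run configuration
#'
#' Declarative description of one state point of the translocation
#' experiment. Defaults are the reference study conditions: the `N = 49`
#' chain (`n = 16`), time step 5e-3, polymer temperature 3/2, friction 1,
#' ensembles of `N_t = 1000` trajectories, a thermalization run of 2e5 steps
#' and a step budget of 1e8. Desk-scale work passes smaller `n_traj`,
#' `therm_steps` and `max_steps` explicitly.
#'
#' @param n Polymer repeat count (chain has `3n + 1` beads).
#' @param f Dimensionless pulling force (> 0; the study range is 0.2 to 60).
#' @param pore `"small"` (radius 1.25) or `"large"` (radius 1.75), or a
#'   numeric radius.
#' @param mode Membrane mode: `"immobile"` or `"kinetic"`.
#' @param k Tether stiffness for the kinetic membrane.
#' @param T_m Membrane temperature.
#' @param T_p Polymer temperature.
#' @param m_C Membrane bead mass.
#' @param dt Time step.
#' @param xi Friction coefficient.
#' @param n_traj Ensemble size `N_t`.
#' @param therm_steps Thermalization steps before the force is switched on.
#' @param max_steps Step budget per trajectory; exhausting it yields status
#'   `"timeout"`, not an error.
#' @param seed Master seed of the ensemble; trajectory `i` uses `seed + i`.
#' @param cells Membrane extent in lattice cells (see [build_membrane()]).
#' @param d Membrane bond length (calibrated default 0.375).
#' @param check_stride Steps between termination/failure checks.
#' @param fail_lateral Lateral distance of the pulled bead from the pore axis
#'   that counts as sliding away when the bead is still cis-side and no bead
#'   has crossed; `Inf` disables failure detection. In the periodic box a
#'   sliding chain can wander back and re-engage the pore, so the threshold
#'   is generous and the condition must persist for `fail_sustain` steps.
#' @param fail_sustain Steps the sliding condition must persist before the
#'   trajectory is marked `"failed_slide"`.
#' @param slab_half Half-thickness of the pore slab used for per-bead waiting
#'   times (default `sigma_B = 1.5`).
#' @param reff_stride Steps between effective-pore-radius samples in kinetic
#'   mode (0 = off).
#' @param kf FENE stiffness prefactor.
#' @return An object of class `poremd_config` (a named list).
#' @export
protocol_config <- function(n = 16, f = 2, pore = c("small", "large"),
                            mode = c("immobile", "kinetic"), k = Inf,
                            T_m = 0, T_p = 1.5, m_C = 1, dt = 5e-3, xi = 1,
                            n_traj = 1000L, therm_steps = 2e5,
                            max_steps = 1e8, seed = 1L,
                            cells = c(49L, 28L), d = 0.375,
                            check_stride = 10L, fail_lateral = 8,
                            fail_sustain = 1e5, slab_half = 1.5,
                            reff_stride = 0L, kf = 30) {
  if (is.character(pore)) {
    pore <- match.arg(pore)
    R <- if (pore == "small") 1.25 else 1.75
  } else {
    R <- pore
  }
  mode <- match.arg(mode)
  stopifnot(f > 0, n_traj >= 1, max_steps > therm_steps, R > 0)
  structure(list(
    n = as.integer(n), f = f, pore_radius = R, mode = mode, k = k,
    T_m = T_m, T_p = T_p, m_C = m_C, dt = dt, xi = xi,
    n_traj = as.integer(n_traj), therm_steps = as.integer(therm_steps),
    max_steps = max_steps, seed = as.integer(seed),
    cells = as.integer(cells), d = d,
    check_stride = as.integer(check_stride), fail_lateral = fail_lateral,
    fail_sustain = fail_sustain, slab_half = slab_half,
    reff_stride = as.integer(reff_stride), kf = kf
  ), class = c("poremd_config", "list"))
}

#' @export
print.poremd_config <- function(x, ...) {
  cat("<poremd_config> n =", x$n, " f =", x$f, " R =", x$pore_radius,
      " mode =", x$mode,
      if (x$mode == "kinetic") paste0("(k = ", x$k, ", T_m = ", x$T_m, ")"),
      "\n  N_t =", x$n_traj, " therm =", x$therm_steps,
      " budget =", format(x$max_steps, scientific = TRUE), " seed =", x$seed,
      "\n")
  invisible(x)
}

#' Initialize one translocation instance
#'
#' Builds the carved membrane and a cis-side polymer conformation, pins the
#' first (pulled) P bead exactly at the pore center `(0, 0, 0)`, and draws
#' Maxwell velocities: the polymer at `T_p` (the pinned bead at rest), the
#' membrane at `T_m` (exactly zero when `T_m = 0` or the membrane is
#' immobile).
#'
#' @param config A [protocol_config()].
#' @param seed Seed for the conformation growth and velocity draw.
#' @param membrane Optional pre-built carved membrane (rebuilt from the
#'   config when `NULL`); passing it avoids rebuilding per trajectory.
#' @return A `poremd_system` ready for [thermalize()].
#' @export
init_translocation <- function(config, seed = NULL, membrane = NULL) {
  stopifnot(inherits(config, "poremd_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(membrane)) {
    membrane <- carve_pore(
      build_membrane(cells = config$cells, d = config$d, n_ref = config$n),
      config$pore_radius)
  }
  pol <- build_polymer(config$n, kf = config$kf, avoid = membrane$sites,
                       box = membrane$box)
  sys <- assemble_system(pol, membrane, mode = config$mode, k = config$k,
                         T_m = config$T_m, T_p = config$T_p, m_C = config$m_C,
                         f = config$f, kf = config$kf)
  sys$frozen[sys$pulled] <- TRUE
  nb <- nrow(sys$beads)
  sys$vel <- maxwell_velocities(nb, 1, sys$beads$mass) *
    sqrt(ifelse(sys$beads$group == "membrane", sys$T_m, sys$T_p))
  sys$vel[sys$pulled, ] <- 0
  if (config$mode == "immobile") {
    sys$vel[sys$beads$group == "membrane", ] <- 0
  }
  sys
}

#' Thermalize a pinned system
#'
#' Equilibrates the cis-side chain at `T_p` (and the kinetic membrane at
#' `T_m`) with the pulled bead held fixed at the pore center and no pulling
#' force. The returned system has its step counter and clock reset to zero,
#' so the force switch-on of [run_translocation()] defines `t = 0`.
#'
#' @param system A pinned `poremd_system` from [init_translocation()].
#' @param steps Thermalization steps (>= 0).
#' @param dt,xi Integrator settings.
#' @return The thermalized system.
#' @export
thermalize <- function(system, steps, dt = 5e-3, xi = 1) {
  stopifnot(inherits(system, "poremd_system"), steps >= 0)
  if (!system$frozen[system$pulled]) {
    rlang::abort("the pulled bead must be pinned during thermalization")
  }
  if (system$pull_on) rlang::abort("the pulling force must be off during thermalization")
  if (steps > 0) {
    system <- run_langevin(system, steps,
                           thermostat_spec(system$T_p, system$T_m, xi, dt))$system
  }
  system$step <- 0L
  system$time <- 0
  system
}

#' Run one translocation trajectory
#'
#' Releases the pinned bead with a fresh thermal velocity, switches the
#' pulling force on (this instant is `t = 0`) and integrates until every
#' polymer bead is on the trans side (`z > 0`, checked every `check_stride`
#' steps), the chain slides away from the pore, or the step budget runs out.
#'
#' @param system A thermalized `poremd_system`.
#' @param config The [protocol_config()] of the run.
#' @return A `poremd_record`: status (`"translocated"`, `"failed_slide"` or
#'   `"timeout"`), the translocation time in steps and LJ time (present only
#'   when translocated), per-bead waiting times inside the pore slab, and the
#'   effective-pore-radius series when sampled.
#' @export
run_translocation <- function(system, config) {
  stopifnot(inherits(system, "poremd_system"), inherits(config, "poremd_config"))
  system$frozen[system$pulled] <- FALSE
  system$vel[system$pulled, ] <- stats::rnorm(3, 0, sqrt(system$T_p))
  system$pull_on <- TRUE
  tr <- list(
    check_stride = config$check_stride,
    slab_half = config$slab_half,
    fail_r2 = config$fail_lateral^2,
    fail_sustain_steps = config$fail_sustain,
    rim_idx = system$rim_idx,
    rim_sigma = 1 / 3,
    reff_stride = if (system$mode == "kinetic") config$reff_stride else 0L)
  out <- engine_run(system, config$max_steps, config$dt, config$xi,
                    transloc = tr)
  status <- c("timeout", "translocated", "failed_slide")[out$res$status + 1]
  poly_ids <- which(system$beads$group == "polymer")
  structure(list(
    status = status,
    tau = if (status == "translocated") out$res$tau else NA_real_,
    tau_steps = if (status == "translocated") out$res$tau / config$dt else NA_real_,
    steps = out$res$steps,
    waiting = tibble::tibble(
      bead = poly_ids,
      label = system$beads$label[poly_ids],
      wait = out$res$waiting),
    reff = tibble::tibble(time = out$res$reff_time, reff = out$res$reff),
    system = out$system
  ), class = "poremd_record")
}

#' @export
print.poremd_record <- function(x, ...) {
  cat("<poremd_record>", x$status,
      if (x$status == "translocated") paste0("tau = ", signif(x$tau, 5)),
      "after", x$steps, "steps\n")
  invisible(x)
}

#' Instantaneous failed-slide predicate
#'
#' A trajectory is abandoned when the chain leaves the pore: the pulled bead
#' sits beyond `fail_lateral` from the pore axis while still on the cis side.
#' During a run the condition must persist for `fail_sustain` steps before
#' the trajectory is marked failed; this helper evaluates the instantaneous
#' predicate on a state.
#'
#' @param system A `poremd_system`.
#' @param config A [protocol_config()]; `fail_lateral = Inf` never fails.
#' @return `TRUE` if the sliding condition holds at this instant.
#' @export
detect_failure <- function(system, config) {
  stopifnot(inherits(system, "poremd_system"))
  p <- system$pos[system$pulled, ]
  is.finite(config$fail_lateral) && p[3] < 0 &&
    sqrt(p[1]^2 + p[2]^2) > config$fail_lateral
}

#' Run a seeded translocation ensemble
#'
#' Executes `config$n_traj` independent trajectories. Trajectory `i` derives
#' its seed as `config$seed + i`; the seed governs the conformation growth,
#' the velocity draws and the thermostat noise, so the ensemble is exactly
#' reproducible from the configuration alone. The membrane is built once and
#' shared; each trajectory grows its own chain.
#'
#' @param config A [protocol_config()].
#' @param keep_waiting Keep per-bead waiting-time tables as a list column.
#' @param keep_reff Keep effective-pore-radius series as a list column.
#' @param progress Print a one-line progress message per trajectory.
#' @return A `poremd_ensemble`: a tibble with one row per trajectory (seed,
#'   status, translocation time in steps and LJ units) carrying the config
#'   and status tallies as attributes.
#' @export
run_ensemble <- function(config, keep_waiting = FALSE, keep_reff = FALSE,
                         progress = FALSE) {
  stopifnot(inherits(config, "poremd_config"))
  membrane <- carve_pore(
    build_membrane(cells = config$cells, d = config$d, n_ref = config$n),
    config$pore_radius)
  rows <- vector("list", config$n_traj)
  for (i in seq_len(config$n_traj)) {
    seed_i <- config$seed + i
    sys <- init_translocation(config, seed = seed_i, membrane = membrane)
    sys <- thermalize(sys, config$therm_steps, config$dt, config$xi)
    rec <- run_translocation(sys, config)
    rows[[i]] <- tibble::tibble(
      traj = i, seed = seed_i, status = rec$status,
      tau_steps = rec$tau_steps, tau = rec$tau,
      waiting = if (keep_waiting) list(rec$waiting) else list(NULL),
      reff = if (keep_reff) list(rec$reff) else list(NULL))
    if (progress) {
      message(sprintf("trajectory %d/%d: %s%s", i, config$n_traj, rec$status,
                      if (rec$status == "translocated")
                        sprintf(" (tau = %.1f)", rec$tau) else ""))
    }
  }
  ens <- dplyr::bind_rows(rows)
  if (!keep_waiting) ens$waiting <- NULL
  if (!keep_reff) ens$reff <- NULL
  attr(ens, "config") <- config
  attr(ens, "tallies") <- table(factor(
    ens$status, levels = c("translocated", "failed_slide", "timeout")))
  class(ens) <- c("poremd_ensemble", class(ens))
  ens
}

#' @export
print.poremd_ensemble <- function(x, ...) {
  tal <- attr(x, "tallies")
  cfg <- attr(x, "config")
  cat("<poremd_ensemble> f =", cfg$f, " R =", cfg$pore_radius, " mode =",
      cfg$mode, ":", paste(names(tal), as.integer(tal), collapse = ", "),
      "\n")
  NextMethod()
}

#' Effective pore radius
#'
#' The instantaneous clearance of the pore in kinetic mode: the minimum over
#' pore-rim beads of their planar distance from the pore axis minus the bead
#' steric radius (`sigma_C = 1/3`). With all rim beads at their anchors this
#' is the static value fixed by the carved geometry; displacing every rim
#' bead radially outward by `x` increases it by exactly `x`.
#'
#' @param x A `poremd_system` (rim set fixed at carve time) or a matrix of
#'   rim-bead positions.
#' @param rim_sigma Steric radius subtracted from the planar distance.
#' @return The effective pore radius (scalar).
#' @export
effective_pore_radius <- function(x, rim_sigma = 1 / 3) {
  pos <- if (inherits(x, "poremd_system")) {
    if (length(x$rim_idx) == 0) rlang::abort("empty pore-rim set")
    x$pos[x$rim_idx, , drop = FALSE]
  } else {
    rbind(x)
  }
  if (nrow(pos) == 0) rlang::abort("empty pore-rim set")
  min(sqrt(pos[, 1]^2 + pos[, 2]^2) - rim_sigma)
}

#' Mean translocation time across a force sweep
#'
#' Runs one ensemble per force value and collects the summary statistics used
#' for the force-scaling analysis.
#'
#' @param config Base [protocol_config()]; its `f` is replaced by each value
#'   of `f_values` in turn (the master seed is offset per force so ensembles
#'   are independent).
#' @param f_values Dimensionless forces to sweep.
#' @param ... Passed to [run_ensemble()].
#' @return A tibble with columns `f`, `n_success`, `tau`, `tau_se`, carrying
#'   the list of ensembles as attribute `"ensembles"`.
#' @export
force_sweep <- function(config, f_values, ...) {
  stopifnot(inherits(config, "poremd_config"), length(f_values) >= 1)
  ensembles <- vector("list", length(f_values))
  rows <- vector("list", length(f_values))
  for (i in seq_along(f_values)) {
    cfg <- config
    cfg$f <- f_values[i]
    cfg$seed <- config$seed + (i - 1L) * (config$n_traj + 1L)
    ens <- run_ensemble(cfg, ...)
    mt <- mean_translocation_time(ens)
    ensembles[[i]] <- ens
    rows[[i]] <- tibble::tibble(f = f_values[i], n_success = mt$n_success,
                                tau = mt$tau, tau_se = mt$tau_se)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ensembles") <- ensembles
  out
}
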