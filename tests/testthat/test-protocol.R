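# Translocation protocol: initialization, thermalization, the run loop with
# its termination/failure observers, ensembles and the effective pore radius.

small_cfg <- function(f = 20, ...) {
  protocol_config(n = 2, f = f, pore = "large", mode = "immobile",
                  n_traj = 2, therm_steps = 2000, max_steps = 2e5,
                  cells = c(12L, 7L), seed = 1, ...)
}

test_that("initialization pins the pulled bead at the pore center", {
  cfg <- small_cfg()
  sys <- init_translocation(cfg, seed = 3)
  expect_identical(sys$pos[sys$pulled, ], c(0, 0, 0))
  expect_true(sys$frozen[sys$pulled])
  # every other polymer bead strictly cis-side
  poly <- which(sys$beads$group == "polymer")
  expect_true(all(sys$pos[setdiff(poly, sys$pulled), 3] < 0))
  # immobile membrane at rest; polymer thermal
  expect_true(all(sys$vel[sys$beads$group == "membrane", ] == 0))
  expect_gt(mean(abs(sys$vel[poly, ])), 0.1)
})

test_that("kinetic initialization draws membrane velocities at T_m", {
  cfg0 <- protocol_config(n = 2, f = 5, pore = "large", mode = "kinetic",
                          k = 300, T_m = 0, n_traj = 1, therm_steps = 100,
                          max_steps = 1000, cells = c(12L, 7L))
  sys0 <- init_translocation(cfg0, seed = 4)
  expect_true(all(sys0$vel[sys0$beads$group == "membrane", ] == 0))

  cfg1 <- protocol_config(n = 2, f = 5, pore = "large", mode = "kinetic",
                          k = 300, T_m = 1.5, n_traj = 1, therm_steps = 100,
                          max_steps = 1000, cells = c(12L, 7L))
  sys1 <- init_translocation(cfg1, seed = 4)
  vm <- sys1$vel[sys1$beads$group == "membrane", ]
  expect_equal(mean(vm^2), 1.5, tolerance = 0.15)
})

test_that("thermalization equilibrates the pinned chain and resets the clock", {
  cfg <- protocol_config(n = 4, f = 5, pore = "large", mode = "immobile",
                         n_traj = 1, therm_steps = 2e4, max_steps = 1e5,
                         cells = c(12L, 7L))
  sys <- init_translocation(cfg, seed = 5)
  th <- thermalize(sys, cfg$therm_steps)
  expect_identical(th$step, 0L)
  expect_identical(th$time, 0)
  # mean squared velocity per dof of the thermalized chain stays at T_p,
  # time-averaged over a short continuation run
  cont <- run_langevin(th, 4000, sample_stride = 20L, seed = 51)
  poly <- which(th$beads$group == "polymer" & !th$frozen)
  temp_est <- 2 * cont$samples$ke_poly / (3 * length(poly))
  expect_lt(abs(mean(temp_est) - 1.5), 3 * block_se(temp_est) + 0.05)
  # confinement: the chain lives in the cis half-space
  expect_true(all(th$pos[setdiff(which(th$beads$group == "polymer"),
                                 th$pulled), 3] < 0))
  expect_lt(mean(th$pos[poly, 3]), 0)

  # duration 0 only resets the counters
  untouched <- thermalize(sys, 0)
  expect_identical(untouched$pos, sys$pos)

  # the pulled bead must be pinned and the force off
  loose <- sys
  loose$frozen[loose$pulled] <- FALSE
  expect_error(thermalize(loose, 10), "pinned")
})

test_that("high-force trajectories translocate and report a complete crossing", {
  cfg <- small_cfg()
  sys <- thermalize(init_translocation(cfg, seed = 6), cfg$therm_steps)
  rec <- run_translocation(sys, cfg)
  expect_identical(rec$status, "translocated")
  expect_gt(rec$tau, 0)
  expect_equal(rec$tau_steps * cfg$dt, rec$tau)
  # monotone completion: at termination every polymer bead is trans-side
  poly <- which(rec$system$beads$group == "polymer")
  expect_true(all(rec$system$pos[poly, 3] > 0))
  # waiting times are non-negative and bounded by the run time
  expect_true(all(rec$waiting$wait >= 0))
  expect_true(all(rec$waiting$wait <= rec$steps * cfg$dt + 1e-9))
  expect_gt(sum(rec$waiting$wait), 0)
})

test_that("a single released bead crosses within twice the drift estimate", {
  # overdamped drift oracle: time to travel a distance z is z / (F/xi)
  f <- 60
  sys <- bare_system(c(0, 0, 0), temp = 1.5)
  sys$ff <- ff_params(f = f)
  sys$pull_on <- TRUE
  # the target is far enough that the velocity-relaxation transient (one
  # m/xi time) is small against the drift time
  z_target <- 200
  drift_time <- z_target / (f_to_force(f) / 1)
  out <- run_langevin(sys, ceiling(2.5 * drift_time / 5e-3),
                      thermostat_spec(T_p = 1.5, xi = 1, dt = 5e-3),
                      sample_stride = 5L, seed = 8)
  crossed <- out$samples$time[which(out$samples$com_z >= z_target)[1]]
  expect_false(is.na(crossed))
  expect_lt(crossed, 2 * drift_time)
  expect_gt(crossed, drift_time / 2)
})

test_that("the instantaneous failure predicate follows its definition", {
  cfg <- small_cfg(fail_lateral = 4)
  sys <- init_translocation(cfg, seed = 9)
  # pulled bead on the trans side: never a failure
  sys$pos[sys$pulled, ] <- c(0, 0, 0.5)
  expect_false(detect_failure(sys, cfg))
  # far from the axis on the cis side: sliding
  sys$pos[sys$pulled, ] <- c(10, 0, -0.5)
  expect_true(detect_failure(sys, cfg))
  # infinite threshold disables detection
  cfg_inf <- small_cfg(fail_lateral = Inf)
  expect_false(detect_failure(sys, cfg_inf))
})

test_that("exhausted budgets yield timeout records, not errors", {
  cfg <- protocol_config(n = 2, f = 0.3, pore = "large", mode = "immobile",
                         n_traj = 2, therm_steps = 100, max_steps = 600,
                         cells = c(12L, 7L), seed = 31)
  ens <- run_ensemble(cfg)
  expect_true(all(ens$status %in% c("timeout", "failed_slide")))
  expect_warning(mt <- mean_translocation_time(ens), "undefined")
  expect_true(is.na(mt$tau))
})

test_that("ensembles are reproducible and tally their outcomes", {
  cfg <- small_cfg()
  a <- run_ensemble(cfg)
  b <- run_ensemble(cfg)
  expect_identical(a$tau, b$tau)
  expect_identical(a$seed, cfg$seed + seq_len(cfg$n_traj))
  tal <- attr(a, "tallies")
  expect_identical(as.integer(sum(tal)), nrow(a))
  expect_identical(unname(tal["translocated"]),
                   sum(a$status == "translocated"))
})

test_that("stronger pulling shortens the mean translocation time", {
  slow <- small_cfg(f = 10)
  fast <- small_cfg(f = 40)
  fast$seed <- 77
  t_slow <- mean_translocation_time(run_ensemble(slow))
  t_fast <- mean_translocation_time(run_ensemble(fast))
  expect_gt(t_slow$tau, t_fast$tau)
})

test_that("the effective pore radius tracks rim displacements exactly", {
  mem <- carve_pore(suppressWarnings(build_membrane(cells = c(12L, 7L),
                                                    n_ref = 2)), 1.75)
  pol <- build_polymer(1, seed = 11)
  sys <- assemble_system(pol, mem, mode = "kinetic", k = 300)
  r_rim <- sqrt(mem$sites[mem$rim_idx, 1]^2 + mem$sites[mem$rim_idx, 2]^2)
  static_val <- min(r_rim) - 1 / 3
  expect_equal(effective_pore_radius(sys), static_val)

  # radial outward displacement d increases R_eff by exactly d
  out <- sys
  rim <- sys$rim_idx
  rr <- sqrt(out$pos[rim, 1]^2 + out$pos[rim, 2]^2)
  out$pos[rim, 1:2] <- out$pos[rim, 1:2] * (1 + 0.1 / rr)
  expect_equal(effective_pore_radius(out), static_val + 0.1, tolerance = 1e-9)

  empty <- sys
  empty$rim_idx <- integer(0)
  expect_error(effective_pore_radius(empty), "empty")
})

test_that("run configuration validation rejects inconsistent settings", {
  expect_error(protocol_config(f = -1), "f > 0")
  expect_error(protocol_config(n_traj = 0), "n_traj")
  expect_error(protocol_config(therm_steps = 100, max_steps = 50),
               "max_steps")
})

test_that("base beads wait in the tight pore longer than backbone beads", {
  # intermittent stalling in the small pore correlates with the grafted B
  # beads, which must tilt through the aperture; sign-level check at the
  # lowest force with reliable desk-scale successes
  cfg <- protocol_config(n = 16, f = 30, pore = "small", mode = "immobile",
                         n_traj = 5, therm_steps = 2e4, max_steps = 1.2e6,
                         seed = 71)
  ens <- suppressWarnings(run_ensemble(cfg, keep_waiting = TRUE))
  ok <- ens$status == "translocated"
  expect_gt(sum(ok), 2)
  w <- dplyr::bind_rows(ens$waiting[ok])
  expect_gt(mean(w$wait[w$label == "B"]), mean(w$wait[w$label != "B"]))
})
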