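# WCA pairs, FENE bonds, harmonic tethers and the assembled force/energy
# evaluation, checked against closed forms, numerical gradients and a
# plain-R all-pairs reference.

test_that("the WCA pair kernel matches its closed form and cutoff contract", {
  # at the cutoff: energy and force vanish (continuity of the truncation)
  at_cut <- pair_energy_force(2^(1 / 6), sigma = 1)
  expect_equal(at_cut$energy, 0, tolerance = 1e-12)
  expect_equal(at_cut$force, 0, tolerance = 1e-12)
  just_in <- pair_energy_force(2^(1 / 6) - 1e-8, sigma = 1)
  expect_lt(just_in$energy, 1e-7)

  # at r = sigma: U = 4 eps (1 - 1) + eps = eps, F = 24 eps / sigma
  at_sig <- pair_energy_force(1, sigma = 1)
  expect_equal(at_sig$energy, 1)
  expect_equal(at_sig$force, 24)
  scaled <- pair_energy_force(1.25, sigma = 1.25)
  expect_equal(scaled$energy, 1)
  expect_equal(scaled$force, 24 / 1.25)

  # beyond the cutoff: identically zero
  out <- pair_energy_force(c(1.2, 2, 10), sigma = 1)
  expect_identical(out$energy, c(0, 0, 0))
  expect_identical(out$force, c(0, 0, 0))

  # purely repulsive inside the cutoff (zero to rounding at the endpoint)
  grid <- seq(0.8, 2^(1 / 6), length.out = 200)
  expect_true(all(pair_energy_force(grid, 1)$force >= -1e-12))

  expect_error(pair_energy_force(0), "positive")
  expect_error(pair_energy_force(-1), "positive")
})

test_that("the FENE bond kernel matches its closed form and guards the divergence", {
  expect_equal(bond_energy_force(1e-8, sigma = 1)$energy, 0, tolerance = 1e-12)
  half <- bond_energy_force(0.75, sigma = 1, kf = 30)
  expect_equal(half$energy, -0.5 * 30 * 1.5^2 * log(1 - 0.25))
  expect_lt(half$force, 0) # attractive
  expect_error(bond_energy_force(1.5, sigma = 1), "broken")
  expect_error(bond_energy_force(2, sigma = 1), "broken")
  expect_error(bond_energy_force(0, sigma = 1), "positive")
})

test_that("the combined FENE interaction has a single stable minimum below R0", {
  for (sigma in c(1, 1.25)) {
    u <- function(r) pair_energy_force(r, sigma)$energy +
      bond_energy_force(r, sigma)$energy
    opt <- optimize(u, c(0.5 * sigma, 1.4999 * sigma))
    expect_gt(opt$minimum, 0)
    expect_lt(opt$minimum, 1.5 * sigma)
    # net radial force crosses zero exactly once on a fine grid
    grid <- seq(0.7 * sigma, 1.45 * sigma, length.out = 2000)
    fnet <- pair_energy_force(grid, sigma)$force +
      bond_energy_force(grid, sigma)$force
    expect_identical(sum(diff(sign(fnet)) != 0), 1L)
    # the rest length used by the growth equals this minimum
    expect_equal(poremd:::fene_rest_length(sigma), opt$minimum,
                 tolerance = 1e-4)
  }
})

test_that("the harmonic tether follows U = k/2 d^2 with restoring force", {
  at_anchor <- tether_energy_force(c(1, 2, 3), c(1, 2, 3), k = 300)
  expect_equal(at_anchor$energy, 0)
  expect_equal(at_anchor$force, c(0, 0, 0))

  d <- 0.2
  off <- tether_energy_force(c(d, 0, 0), c(0, 0, 0), k = 300)
  expect_equal(off$energy, 150 * d^2)
  expect_equal(off$force, c(-300 * d, 0, 0))

  # force balance: under a constant load F the equilibrium displacement is
  # F / k, where the tether force exactly cancels the load
  F_ext <- 4.5
  bal <- tether_energy_force(c(F_ext / 300, 0, 0), c(0, 0, 0), k = 300)
  expect_equal(bal$force[1], -F_ext)

  expect_error(tether_energy_force(c(0, 0, 0), c(0, 0, 0), k = -1), ">= 0")
  expect_error(tether_energy_force(c(0, 0, 0), c(0, 0, 0), k = Inf), "finite")
})

test_that("isolated beads beyond the cutoff feel no force", {
  sys <- bare_system(rbind(c(0, 0, 0), c(3, 0, 0)))
  out <- total_forces(sys, neighbor_list = FALSE)
  expect_equal(out$forces, matrix(0, 2, 3))
  expect_equal(out$energy, 0)
})

test_that("pair and bond forces obey Newton's third law; external terms break it", {
  sys <- free_chain_system(4, seed = 5)
  out <- total_forces(sys)
  expect_lt(max(abs(colSums(out$forces))), 1e-9)

  # with the pull active the total force gains exactly F_pull in z
  pulled <- sys
  pulled$ff <- ff_params(f = 2)
  pulled$pull_on <- TRUE
  out2 <- total_forces(pulled)
  expect_equal(colSums(out2$forces), c(0, 0, 3), tolerance = 1e-9)
})

test_that("forces are minus the energy gradient on randomized configurations", {
  h <- 1e-6
  for (seed in c(11, 12)) {
    sys <- random_small_system(seed)
    f0 <- total_forces(sys, neighbor_list = FALSE)
    scale <- max(1, max(abs(f0$forces)))
    for (trial in 1:6) {
      i <- sample(which(!sys$frozen), 1)
      ax <- sample(3, 1)
      up <- sys; up$pos[i, ax] <- up$pos[i, ax] + h
      dn <- sys; dn$pos[i, ax] <- dn$pos[i, ax] - h
      num <- -(total_forces(up, neighbor_list = FALSE)$energy -
                 total_forces(dn, neighbor_list = FALSE)$energy) / (2 * h)
      expect_lt(abs(num - f0$forces[i, ax]) / scale, 1e-6)
    }
  }
})

test_that("the engine agrees with the plain-R all-pairs reference", {
  for (seed in 21:26) {
    sys <- random_small_system(seed)
    ref <- r_reference_forces(sys)
    for (nl in c(TRUE, FALSE)) {
      out <- total_forces(sys, neighbor_list = nl)
      scale <- max(1, max(abs(ref$forces)))
      expect_lt(max(abs(out$forces - ref$forces)) / scale, 1e-10)
      expect_equal(out$energy, ref$energy, tolerance = 1e-10)
    }
  }
})

test_that("energy is invariant under periodic box translations", {
  sys <- random_small_system(31)
  e0 <- total_forces(sys, neighbor_list = FALSE)$energy
  shifted <- sys
  shifted$pos[, 1] <- shifted$pos[, 1] + sys$box[1]
  expect_equal(total_forces(shifted, neighbor_list = FALSE)$energy, e0,
               tolerance = 1e-10)
  shifted2 <- sys
  shifted2$pos[, 2] <- shifted2$pos[, 2] - 2 * sys$box[2]
  expect_equal(total_forces(shifted2, neighbor_list = FALSE)$energy, e0,
               tolerance = 1e-10)
})

test_that("membrane-membrane interactions are counted only in kinetic mode", {
  mem <- carve_pore(suppressWarnings(build_membrane(cells = c(3L, 2L), n_ref = 1)),
                    0.6)
  pol <- build_polymer(1, seed = 7)
  imm <- assemble_system(pol, mem, mode = "immobile")
  kin <- assemble_system(pol, mem, mode = "kinetic", k = 300)
  # squeeze two membrane beads together: only the kinetic system notices
  imm$pos[imm$n_poly + 1, 1:2] <- imm$pos[imm$n_poly + 2, 1:2] + c(0.1, 0)
  imm$pos[imm$n_poly + 1, 3] <- imm$pos[imm$n_poly + 2, 3]
  kin$pos[kin$n_poly + 1, ] <- imm$pos[imm$n_poly + 1, ]
  e_imm <- total_forces(imm, neighbor_list = FALSE)$energy
  e_kin <- total_forces(kin, neighbor_list = FALSE)$energy
  expect_gt(e_kin, e_imm + 1) # WCA contact at r = 0.1 with sigma 1/3
})

test_that("ff_params exposes the documented constants", {
  p <- ff_params(f = 2)
  expect_equal(p$F_pull, 3)
  expect_equal(p$sigma["P", "B"], 1.25)
  expect_equal(p$sigma["C", "C"], 1 / 3)
  expect_equal(p$sigma["S", "C"], 1)
  expect_equal(p$cutoff["B", "B"], 2^(1 / 6) * 1.5)
  expect_error(ff_params(k = -5), ">= 0")
})
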