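# Shared oracles and fixture builders. Everything here is deliberately
# independent of the compiled engine: plain-R force sums, closed-form
# sampling transforms and blocked error estimates used to check the
# implementation from a second route.

# Standard error of a correlated time series via block averaging.
block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  bl <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1) * bl + 1):(b * bl)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}

# Inverse-Gaussian sampler (Michael-Schucany-Haas transformation); used as
# the independent generator when checking the first-passage fit.
rinvgauss_oracle <- function(n, mu, lambda) {
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# Plain-R all-pairs force and energy reference, assembled from the exported
# scalar kernels. O(N^2); minimum image in x-y only.
r_reference_forces <- function(system) {
  pos <- system$pos
  n <- nrow(pos)
  kind <- system$beads$kind
  grp <- system$beads$group
  sig <- sigma_table()
  Lx <- system$box[1]; Ly <- system$box[2]
  forces <- matrix(0, n, 3)
  energy <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!system$mm_pairs && grp[i] == "membrane" && grp[j] == "membrane") next
      d <- pos[i, ] - pos[j, ]
      d[1] <- d[1] - Lx * round(d[1] / Lx)
      d[2] <- d[2] - Ly * round(d[2] / Ly)
      r <- sqrt(sum(d^2))
      pe <- pair_energy_force(r, sig[kind[i], kind[j]])
      energy <- energy + pe$energy
      forces[i, ] <- forces[i, ] + pe$force * d / r
      forces[j, ] <- forces[j, ] - pe$force * d / r
    }
  }
  if (nrow(system$bonds) > 0) {
    for (b in seq_len(nrow(system$bonds))) {
      i <- system$bonds$i[b]; j <- system$bonds$j[b]
      d <- pos[i, ] - pos[j, ]
      d[1] <- d[1] - Lx * round(d[1] / Lx)
      d[2] <- d[2] - Ly * round(d[2] / Ly)
      r <- sqrt(sum(d^2))
      be <- bond_energy_force(r, system$bonds$sigma[b], system$ff$kf)
      energy <- energy + be$energy
      forces[i, ] <- forces[i, ] + be$force * d / r
      forces[j, ] <- forces[j, ] - be$force * d / r
    }
  }
  for (i in seq_len(n)) {
    if (system$tether_k[i] > 0) {
      te <- tether_energy_force(pos[i, ], system$anchor[i, ], system$tether_k[i])
      energy <- energy + te$energy
      forces[i, ] <- forces[i, ] + te$force
    }
  }
  if (system$pull_on) forces[system$pulled, 3] <-
    forces[system$pulled, 3] + system$ff$F_pull
  list(forces = forces, energy = energy)
}

# Minimal hand-built systems the engine accepts: isolated beads, optionally
# tethered, in an effectively open box.
bare_system <- function(pos, vel = NULL, sigma_kind = 1L, mass = 1,
                        tether_k = 0, anchor = NULL, frozen = FALSE,
                        temp = 1.5, box = c(1e9, 1e9)) {
  pos <- rbind(pos)
  n <- nrow(pos)
  labels <- KIND_LEVELS_TEST[sigma_kind]
  sys <- structure(list(
    beads = tibble::tibble(
      id = seq_len(n), label = rep_len(labels, n),
      kind = rep_len(as.integer(sigma_kind), n), group = "polymer",
      sigma = c(1, 1, 1.5, 1 / 3)[rep_len(sigma_kind, n)],
      mass = rep_len(mass, n)),
    pos = pos,
    vel = if (is.null(vel)) matrix(0, n, 3) else rbind(vel),
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           type = character(0), sigma = numeric(0),
                           R0 = numeric(0), K = numeric(0)),
    tether_k = rep_len(tether_k, n),
    anchor = if (is.null(anchor)) matrix(0, n, 3) else rbind(anchor),
    frozen = rep_len(frozen, n),
    temp = rep_len(temp, n),
    pulled = 1L, pull_on = FALSE,
    box = c(Lx = box[1], Ly = box[2]),
    mm_pairs = FALSE, mode = "immobile",
    k = Inf, T_p = temp[1], T_m = 0,
    ff = ff_params(),
    n_poly = n, rim_idx = integer(0), pore_radius = NA_real_, d = NA_real_,
    step = 0L, time = 0), class = "poremd_system")
  sys
}

KIND_LEVELS_TEST <- c("P", "S", "B", "C")

# Randomized small mixed system (short chain plus a membrane patch) for
# force-consistency property tests.
random_small_system <- function(seed, kinetic = sample(c(TRUE, FALSE), 1)) {
  set.seed(seed)
  n <- sample(1:3, 1)
  mem <- carve_pore(suppressWarnings(
    build_membrane(cells = c(3L, 2L), n_ref = 1)), 0.6)
  pol <- build_polymer(n, avoid = mem$sites, box = mem$box)
  sys <- assemble_system(pol, mem,
                         mode = if (kinetic) "kinetic" else "immobile",
                         k = if (kinetic) 300 else Inf,
                         T_m = 0, f = stats::runif(1, 0, 5))
  # jitter positions a little to decorrelate from the growth geometry
  mobile <- !sys$frozen
  sys$pos[mobile, ] <- sys$pos[mobile, ] +
    matrix(stats::rnorm(sum(mobile) * 3, 0, 0.02), sum(mobile), 3)
  sys$pull_on <- sample(c(TRUE, FALSE), 1)
  sys
}
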