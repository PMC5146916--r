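# Polymer and membrane construction: bead/bond bookkeeping, self-avoiding
# cis-side growth, honeycomb lattice structure and pore carving.

test_that("the structured chain has 3n+1 beads and the enumerated bond set", {
  p <- build_polymer(16, seed = 1)
  expect_identical(unname(p$counts["N"]), 49L)
  expect_identical(unname(p$counts["n_P"]), 17L)
  expect_identical(p$beads$label[1], "P")
  expect_identical(p$pulled_bead, 1L)

  # independent enumeration: walk the repeat structure P-(S,B,P)*n and count
  # S-P links (every S flanked by two P) and S-B grafts
  labels <- c("P", rep(c("S", "B", "P"), 16))
  s_at <- which(labels == "S")
  oracle_sp <- sum(vapply(s_at, function(i) {
    sum(labels[c(max(i - 1, 1), min(i + 2, length(labels)))] == "P")
  }, numeric(1)))
  oracle_sb <- length(s_at)
  expect_identical(nrow(p$bonds), as.integer(oracle_sp + oracle_sb))
  expect_identical(sum(p$bonds$type == "SP"), as.integer(oracle_sp))
  expect_identical(sum(p$bonds$type == "SB"), as.integer(oracle_sb))

  # every bond joins beads adjacent in the repeat structure
  expect_true(all(p$bonds$j - p$bonds$i <= 2))
  # B beads carry exactly one bond, to their S
  for (b in which(p$beads$label == "B")) {
    hits <- sum(p$bonds$i == b | p$bonds$j == b)
    expect_identical(hits, 1L)
  }
})

test_that("the smallest chain n = 1 is P-S(-B)-P with 4 beads", {
  p <- build_polymer(1, seed = 2)
  expect_identical(unname(p$counts["N"]), 4L)
  expect_identical(p$beads$label, c("P", "S", "B", "P"))
  expect_identical(nrow(p$bonds), 3L)
})

test_that("initial conformations are cis-side, overlap-free and unbroken", {
  sig <- poremd:::sigma_table()
  for (seed in 1:5) {
    p <- build_polymer(8, seed = seed)
    # all beads except the pinned head strictly below the membrane plane
    expect_identical(p$pos[1, ], c(0, 0, 0))
    expect_true(all(p$pos[-1, 3] < 0))
    # no pair closer than 0.8 of the WCA contact distance
    dmat <- as.matrix(dist(p$pos))
    lim <- 0.8 * 2^(1 / 6) * sig[p$beads$kind, p$beads$kind]
    diag(dmat) <- Inf
    expect_true(all(dmat >= lim - 1e-12))
    # bond lengths strictly below the FENE maximum
    blen <- sqrt(rowSums((p$pos[p$bonds$i, ] - p$pos[p$bonds$j, ])^2))
    expect_true(all(blen < p$bonds$R0))
  }
})

test_that("growth is reproducible for a fixed seed and fails loudly when impossible", {
  a <- build_polymer(6, seed = 42)
  b <- build_polymer(6, seed = 42)
  expect_identical(a$pos, b$pos)
  expect_error(build_polymer(0), "n >= 1")
  # an avoid wall covering the whole accessible half-space forces failure
  grid <- as.matrix(expand.grid(x = seq(-6, 6, 0.5), y = seq(-6, 6, 0.5),
                                z = seq(-3, -0.1, 0.4)))
  expect_error(build_polymer(4, seed = 3, avoid = grid, max_restarts = 2),
               "growth failed")
})

test_that("the default membrane has 5488 sites in a near-square box", {
  m <- build_membrane()
  expect_identical(m$n_sites, 5488L)
  expect_lt(abs(m$box[1] - m$box[2]) / m$box[1], 0.02)
  expect_true(all(m$sites[, 3] == 0))
})

test_that("every honeycomb site has exactly three neighbours at the bond distance", {
  m <- suppressWarnings(build_membrane(cells = c(6L, 4L), n_ref = 1))
  s <- m$sites
  Lx <- m$box[1]; Ly <- m$box[2]
  counts <- vapply(seq_len(nrow(s)), function(i) {
    dx <- s[, 1] - s[i, 1]; dy <- s[, 2] - s[i, 2]
    dx <- dx - Lx * round(dx / Lx)
    dy <- dy - Ly * round(dy / Ly)
    r <- sqrt(dx^2 + dy^2)
    sum(abs(r - m$d) < 1e-9)
  }, numeric(1))
  expect_true(all(counts == 3))
})

test_that("the lattice maps onto itself under box translations", {
  m <- suppressWarnings(build_membrane(cells = c(5L, 3L), n_ref = 1))
  canon <- function(xy) {
    # map into [0, L) and sort: a canonical representation of the site set
    x <- round(xy[, 1] %% m$box[1], 9)
    y <- round(xy[, 2] %% m$box[2], 9)
    x[x == round(m$box[1], 9)] <- 0
    y[y == round(m$box[2], 9)] <- 0
    unname(cbind(x, y)[order(x, y), ])
  }
  orig <- canon(m$sites[, 1:2])
  shifted_x <- canon(cbind(m$sites[, 1] + m$box[1], m$sites[, 2]))
  shifted_y <- canon(cbind(m$sites[, 1], m$sites[, 2] + m$box[2]))
  expect_equal(orig, shifted_x, tolerance = 1e-9)
  expect_equal(orig, shifted_y, tolerance = 1e-9)
})

test_that("non-commensurate extents are rejected with the nearest valid sizes", {
  expect_error(build_membrane(extent = c(10, 10)), "not commensurate")
  err <- tryCatch(build_membrane(extent = c(10, 10)), error = conditionMessage)
  expect_match(err, "nearest valid")
  d <- 0.375
  m <- suppressWarnings(build_membrane(extent = c(8 * sqrt(3) * d, 4 * 3 * d),
                                       n_ref = 1))
  expect_identical(m$cells, c(8L, 4L))
})

test_that("a single hexagonal ring has six sites at the bond distance", {
  ring <- hexagon_ring(0.375)
  expect_identical(nrow(ring), 6L)
  expect_equal(sqrt(ring[, 1]^2 + ring[, 2]^2), rep(0.375, 6))
  # consecutive vertices are bond-distance apart
  nn <- sqrt(rowSums((ring - ring[c(2:6, 1), ])^2))
  expect_equal(nn, rep(0.375, 6))
})

test_that("pore carving removes sites strictly inside R and reports the count", {
  m <- suppressWarnings(build_membrane(cells = c(12L, 7L), n_ref = 2))
  small <- carve_pore(m, 1.25)
  expect_identical(small$n_removed, 24L)
  expect_true(all(sqrt(small$sites[, 1]^2 + small$sites[, 2]^2) >= 1.25))
  large <- carve_pore(m, 1.75)
  expect_identical(large$n_removed, 54L)

  # strict inequality: carving exactly at the first remaining shell removes
  # nothing more
  r_min <- min(sqrt(small$sites[, 1]^2 + small$sites[, 2]^2))
  again <- carve_pore(small, r_min)
  expect_identical(again$n_removed, 0L)

  expect_identical(carve_pore(m, 0)$n_removed, 0L)
  expect_error(carve_pore(m, 10), "half the box")
})

test_that("carving is idempotent and monotone in the radius", {
  m <- suppressWarnings(build_membrane(cells = c(12L, 7L), n_ref = 2))
  once <- carve_pore(m, 1.25)
  twice <- carve_pore(once, 1.25)
  expect_identical(twice$n_removed, 0L)
  expect_identical(twice$n_removed_total, 24L)
  removed <- vapply(seq(0, 2, 0.25), function(R) carve_pore(m, R)$n_removed,
                    integer(1))
  expect_true(all(diff(removed) >= 0))
})

test_that("the pore rim is the first shell of surviving sites", {
  m <- carve_pore(suppressWarnings(build_membrane(cells = c(12L, 7L), n_ref = 2)),
                  1.75)
  r <- sqrt(m$sites[, 1]^2 + m$sites[, 2]^2)
  expect_true(all(r[m$rim_idx] < 1.75 + m$d))
  expect_true(all(r[-m$rim_idx] >= 1.75 + m$d))
  expect_gt(length(m$rim_idx), 0)
})

test_that("an undersized box for the configured chain triggers the reach warning", {
  expect_warning(build_membrane(cells = c(8L, 5L), n_ref = 16),
                 "periodic image")
  expect_silent(build_membrane(cells = c(8L, 5L), n_ref = 2))
})
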