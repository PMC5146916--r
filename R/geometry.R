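# Geometry builders: the structured polymer chain and the honeycomb membrane
# with a carved nano-pore. Lengths are in reduced units where the backbone
# bead radius a = sigma_P = 1.

KIND_LEVELS <- c("P", "S", "B", "C")

#' Bead kinds of the coarse-grained model
#'
#' Four bead kinds: phosphate-like (P) and sugar-like (S) backbone units,
#' base-like (B) side units, and membrane carbon-like (C) sites. Radii in
#' units of `a`: P and S have sigma 1, B has 1.5, C has 1/3 (its
#' membrane-membrane interaction radius; against polymer beads a C site
#' interacts with sigma = 1 so the polymer cannot sneak between adjacent
#' membrane sites).
#'
#' @param m_C Membrane bead mass (polymer beads always have mass 1).
#' @return A tibble with columns `label`, `kind` (integer code), `sigma`,
#'   `mass`.
#' @examples
#' bead_kinds()
#' @export
bead_kinds <- function(m_C = 1) {
  stopifnot(is.numeric(m_C), m_C > 0)
  tibble::tibble(
    label = KIND_LEVELS,
    kind = 1:4,
    sigma = c(1, 1, 1.5, 1 / 3),
    mass = c(1, 1, 1, m_C)
  )
}

# Pairwise interaction radii sigma_ij by kind pair. Polymer-polymer pairs use
# the arithmetic mixing rule sigma_ij = (sigma_i + sigma_j)/2; all
# membrane-polymer pairs use sigma = 1 (overriding the mixing rule) and
# membrane-membrane pairs use sigma = 1/3.
sigma_table <- function() {
  s <- c(1, 1, 1.5) # P, S, B radii
  m <- matrix(0, 4, 4, dimnames = list(KIND_LEVELS, KIND_LEVELS))
  for (i in 1:3) for (j in 1:3) m[i, j] <- (s[i] + s[j]) / 2
  m[4, 1:3] <- 1
  m[1:3, 4] <- 1
  m[4, 4] <- 1 / 3
  m
}

# Rest length of the FENE bond (WCA repulsion + finitely extensible
# attraction) for interaction radius sigma. Scale-free in sigma.
fene_rest_length <- function(sigma = 1, kf = 30) {
  u <- function(r) {
    sr6 <- (1 / r)^6
    wca <- if (r < 2^(1 / 6)) 4 * (sr6^2 - sr6) + 1 else 0
    wca - 0.5 * (kf) * 1.5^2 * log(1 - (r / 1.5)^2)
  }
  sigma * stats::optimize(u, c(0.7, 1.3))$minimum
}

#' Build the structured polymer
#'
#' Constructs the bead-spring single-stranded-DNA model: a backbone of
#' alternating P and S beads starting and ending with P (one extra P bead at
#' the head of the chain, which is the bead the pulling force acts on), with
#' one B bead grafted to every S. For `n` repeat units the chain has
#' `N = 3n + 1` beads, `2n` backbone S-P bonds and `n` side S-B bonds.
#'
#' The initial conformation is grown self-avoidingly into the cis half-space
#' `z < 0`, with the first (pulled) P bead pinned at the origin and all bonds
#' at the FENE rest length. Any overlap-free cis-side start is equivalent
#' after thermalization.
#'
#' @param n Number of repeat units (>= 1).
#' @param seed Optional integer seed for the growth; if `NULL` the current
#'   RNG state is used.
#' @param kf FENE stiffness prefactor (energy / sigma_ij^2); the bond
#'   stiffness of a bond with interaction radius sigma_ij is `kf / sigma_ij^2`
#'   and its maximum extension `1.5 sigma_ij`.
#' @param avoid Optional matrix of site positions (e.g. membrane sites) the
#'   growth must keep a polymer-membrane contact distance from.
#' @param box Optional periodic box lengths `c(Lx, Ly)`; when given, the
#'   self-avoidance and `avoid` checks use the minimum-image convention so
#'   the grown chain does not overlap its own periodic image.
#' @param max_restarts Chain-level restarts before growth fails with an error.
#' @return An object of class `poremd_polymer`: bead table, bond table,
#'   pulled-bead index and an `N x 3` matrix of initial positions.
#' @examples
#' p <- build_polymer(4, seed = 1)
#' p$counts
#' @export
build_polymer <- function(n, seed = NULL, kf = 30, avoid = NULL, box = NULL,
                          max_restarts = 50L) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  N <- 3L * n + 1L

  labels <- c("P", rep(c("S", "B", "P"), n))
  kind <- match(labels, KIND_LEVELS)
  st <- sigma_table()

  # bonds: backbone P-S / S-P plus side S-B
  backbone <- which(labels != "B")
  bb_pairs <- cbind(backbone[-length(backbone)], backbone[-1])
  s_idx <- which(labels == "S")
  sb_pairs <- cbind(s_idx, s_idx + 1L)
  bonds <- rbind(bb_pairs, sb_pairs)
  bond_type <- c(rep("SP", nrow(bb_pairs)), rep("SB", nrow(sb_pairs)))
  bond_sigma <- ifelse(bond_type == "SP", 1, 1.25)
  bonds <- tibble::tibble(
    i = bonds[, 1], j = bonds[, 2], type = bond_type, sigma = bond_sigma,
    R0 = 1.5 * bond_sigma, K = kf / bond_sigma^2
  )

  pos <- grow_chain(labels, kind, bonds, st, kf, avoid, box, max_restarts)

  structure(list(
    beads = tibble::tibble(
      id = seq_len(N), label = labels, kind = kind, group = "polymer",
      sigma = c(1, 1, 1.5, 1 / 3)[kind], mass = 1
    ),
    bonds = bonds,
    pulled_bead = 1L,
    pos = pos,
    counts = c(n = n, n_P = n + 1L, n_S = n, n_B = n, N = N),
    kf = kf
  ), class = "poremd_polymer")
}

# Self-avoiding growth into z < 0. Each new bead is placed at the FENE rest
# distance from its bonded partner in a random direction, rejected if it
# rises above the membrane plane, approaches a non-bonded bead closer than
# 0.9 of the WCA contact distance, or overlaps a site in `avoid`.
grow_chain <- function(labels, kind, bonds, st, kf, avoid, box, max_restarts) {
  N <- length(labels)
  mi2 <- function(dx, dy, dz) {
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    dx^2 + dy^2 + dz^2
  }
  r_sp <- fene_rest_length(1, kf)
  r_sb <- fene_rest_length(1.25, kf)
  contact <- 0.9 * 2^(1 / 6)
  # parent bead (bonded partner already placed) for each bead > 1
  parent <- integer(N)
  for (b in seq_len(nrow(bonds))) parent[max(bonds$i[b], bonds$j[b])] <-
    min(bonds$i[b], bonds$j[b])
  rlen <- ifelse(labels == "B", r_sb, r_sp)

  for (restart in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, N, 3)
    pos[1, ] <- 0
    ok <- TRUE
    for (i in 2:N) {
      placed <- FALSE
      for (try in 1:500) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- pos[parent[i], ] + rlen[i] * dir
        if (cand[3] >= -0.05) next
        prev <- seq_len(i - 1)
        nb <- prev[prev != parent[i]]
        if (length(nb)) {
          d2 <- mi2(pos[nb, 1] - cand[1], pos[nb, 2] - cand[2],
                    pos[nb, 3] - cand[3])
          lim <- (contact * st[kind[nb], kind[i]])^2
          if (any(d2 < lim)) next
        }
        if (!is.null(avoid) && cand[3] > -1.02) {
          da2 <- mi2(avoid[, 1] - cand[1], avoid[, 2] - cand[2],
                     avoid[, 3] - cand[3])
          if (any(da2 < (contact * 1)^2)) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  rlang::abort(
    "polymer growth failed: could not resolve overlaps after bounded retries")
}

#' @export
print.poremd_polymer <- function(x, ...) {
  cat("<poremd_polymer> n =", x$counts["n"], " N =", x$counts["N"],
      "beads,", nrow(x$bonds), "bonds; pulled bead", x$pulled_bead, "\n")
  invisible(x)
}

# Honeycomb site generator: nx x ny rectangular four-site cells of width
# sqrt(3) d and height 3 d, shifted so that the origin sits at a hexagon
# center, wrapped into the centered box.
honeycomb_sites <- function(nx, ny, d) {
  cw <- sqrt(3) * d
  ch <- 3 * d
  base <- rbind(c(0, 0), c(0, d), c(cw / 2, 1.5 * d), c(cw / 2, 2.5 * d))
  ii <- rep(seq_len(nx) - 1L, each = ny)
  jj <- rep(seq_len(ny) - 1L, times = nx)
  xs <- as.vector(outer(base[, 1], ii * cw, `+`))
  ys <- as.vector(outer(base[, 2], jj * ch, `+`))
  Lx <- nx * cw
  Ly <- ny * ch
  # hexagon center closest to the lattice origin
  xs <- xs - cw / 2
  ys <- ys - d / 2
  xs <- xs - Lx * round(xs / Lx)
  ys <- ys - Ly * round(ys / Ly)
  list(sites = cbind(x = xs, y = ys, z = 0), box = c(Lx = Lx, Ly = Ly))
}

#' Build the honeycomb membrane
#'
#' Generates a graphene-like honeycomb arrangement of C sites in the `z = 0`
#' plane, periodic in x and y, with the future pore center on a hexagon
#' center at the origin. The extent is specified in rectangular lattice cells
#' of four sites each (cell size `sqrt(3) d` by `3 d`), or as a target box
#' length that must be commensurate with those cells.
#'
#' The site spacing is a calibrated quantity: the default nearest-neighbour
#' distance `d = 0.375` (in units of the polymer bead radius `a`), together
#' with the hexagon-center origin, reproduces the reference pore-carving
#' counts of 24 sites inside radius 1.25 and 54 inside 1.75 (see
#' [carve_pore()]). The default extent of 49 x 28 cells gives 5488 sites in a
#' near-square box of about 31.8 x 31.5.
#'
#' @param cells Integer vector of length 2: cell counts along x and y.
#' @param extent Alternative to `cells`: target box edge length(s); must be
#'   commensurate with the cell size or an error lists the nearest valid
#'   sizes.
#' @param d Nearest-neighbour (bond) distance of the honeycomb lattice.
#' @param n_ref Polymer repeat count used for the box-size adequacy check: a
#'   warning is issued if the box edge is smaller than the rest-length contour
#'   of that chain, since the chain could then interact with its own periodic
#'   image.
#' @return An object of class `poremd_membrane` with the site matrix, box
#'   lengths, lattice metadata and (after carving) the pore fields.
#' @examples
#' m <- build_membrane(cells = c(8, 5), n_ref = 2)
#' m$n_sites
#' @export
build_membrane <- function(cells = c(49L, 28L), extent = NULL, d = 0.375,
                           n_ref = 16) {
  stopifnot(d > 0)
  cw <- sqrt(3) * d
  ch <- 3 * d
  if (!is.null(extent)) {
    extent <- rep_len(extent, 2)
    kx <- extent[1] / cw
    ky <- extent[2] / ch
    if (abs(kx - round(kx)) > 1e-8 || abs(ky - round(ky)) > 1e-8) {
      rlang::abort(sprintf(
        paste0("requested extent (%.4f, %.4f) is not commensurate with the ",
               "lattice cell (%.4f, %.4f); nearest valid sizes: ",
               "x in {%.4f, %.4f}, y in {%.4f, %.4f}"),
        extent[1], extent[2], cw, ch,
        floor(kx) * cw, ceiling(kx) * cw, floor(ky) * ch, ceiling(ky) * ch))
    }
    cells <- c(round(kx), round(ky))
  }
  cells <- as.integer(cells)
  stopifnot(length(cells) == 2, all(cells >= 1))
  hc <- honeycomb_sites(cells[1], cells[2], d)
  contour <- 2 * n_ref * fene_rest_length(1)
  if (min(hc$box) < contour) {
    rlang::warn(sprintf(
      paste0("membrane box (%.2f x %.2f) is smaller than the rest-length ",
             "contour (%.2f) of an n = %d chain; a stretched chain could ",
             "reach its own periodic image"),
      hc$box[1], hc$box[2], contour, as.integer(n_ref)))
  }
  structure(list(
    sites = hc$sites,
    box = hc$box,
    d = d,
    cells = cells,
    n_sites = nrow(hc$sites),
    pore_radius = NA_real_,
    n_removed = 0L,
    n_removed_total = 0L,
    rim_idx = integer(0),
    convention = list(origin = "hexagon_center", bond_length = d)
  ), class = "poremd_membrane")
}

#' @export
print.poremd_membrane <- function(x, ...) {
  cat("<poremd_membrane>", x$n_sites, "sites, box",
      sprintf("%.2f x %.2f", x$box[1], x$box[2]), "; bond length", x$d, "\n")
  if (!is.na(x$pore_radius)) {
    cat("  pore radius", x$pore_radius, ":", x$n_removed_total,
        "sites removed,", length(x$rim_idx), "rim sites\n")
  }
  invisible(x)
}

#' Carve the nano-pore
#'
#' Removes every membrane site whose planar distance from the origin (the
#' pore center, a hexagon center of the lattice) is strictly less than `R`.
#' The reference radii are `R_s = 1.25` (24 sites removed under the default
#' lattice) and `R_l = 1.75` (54 sites). Sites with distance in
#' `[R, R + d)` are recorded as the pore rim, used by
#' [effective_pore_radius()].
#'
#' @param membrane A `poremd_membrane`.
#' @param R Pore radius (>= 0); must not exceed half the box edge.
#' @return The carved membrane; `$n_removed` is the number of sites removed
#'   by this call (carving twice with the same radius removes nothing more).
#' @examples
#' m <- carve_pore(build_membrane(cells = c(8, 5), n_ref = 2), 1.25)
#' m$n_removed # 24
#' @export
carve_pore <- function(membrane, R) {
  stopifnot(inherits(membrane, "poremd_membrane"), is.numeric(R),
            length(R) == 1, R >= 0)
  if (R > min(membrane$box) / 2) {
    rlang::abort("pore radius exceeds half the box edge: the pore would touch its own periodic image")
  }
  r <- sqrt(membrane$sites[, 1]^2 + membrane$sites[, 2]^2)
  drop <- r < R
  membrane$n_removed <- sum(drop)
  membrane$n_removed_total <- membrane$n_removed_total + sum(drop)
  membrane$sites <- membrane$sites[!drop, , drop = FALSE]
  membrane$n_sites <- nrow(membrane$sites)
  membrane$pore_radius <- R
  r <- r[!drop]
  membrane$rim_idx <- which(r < R + membrane$d)
  if (R > 0 && length(membrane$rim_idx) == 0) {
    rlang::warn("carved pore has an empty rim set")
  }
  membrane
}

#' A single hexagonal ring of sites
#'
#' The smallest closed honeycomb motif: six sites at distance `d` around the
#' origin. Mainly useful for desk-checking lattice conventions.
#'
#' @param d Bond length.
#' @return A 6 x 3 matrix of positions in the `z = 0` plane.
#' @export
hexagon_ring <- function(d = 0.375) {
  ang <- pi / 6 + (0:5) * pi / 3
  cbind(x = d * cos(ang), y = d * sin(ang), z = 0)
}
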