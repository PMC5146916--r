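# Force field: purely repulsive truncated-shifted Lennard-Jones (WCA) pairs,
# FENE bonds (the WCA + finitely-extensible attraction on bonded pairs),
# harmonic tethers for the kinetic membrane, and the constant pulling force.
# Bonded pairs are NOT excluded from the pair term: their WCA repulsion plus
# the attractive bond term IS the FENE interaction.

#' Force-field parameter set
#'
#' Collects all interaction constants of the model in reduced units: the
#' energy scale `eps`, the per-kind-pair interaction radii (backbone and side
#' beads mix arithmetically; membrane-polymer pairs use sigma = 1 and
#' membrane-membrane pairs sigma = 1/3), the WCA cutoffs `2^(1/6) sigma_ij`,
#' the FENE stiffness prefactor `kf` (per-bond stiffness `kf / sigma_ij^2`,
#' maximum extension `1.5 sigma_ij`), the membrane tether stiffness `k`
#' (`Inf` = immobile membrane), and the dimensionless pulling force `f`
#' (applied force `F = f k_B T_p / a = 1.5 f` along +z).
#'
#' @param eps Energy scale (default 1).
#' @param kf FENE stiffness prefactor in `eps / sigma_ij^2`.
#' @param k Tether stiffness; `Inf` marks membrane beads immobile.
#' @param f Dimensionless pulling force.
#' @param T_p Polymer temperature used in the `f` to force conversion.
#' @return An object of class `poremd_ff`.
#' @examples
#' p <- ff_params(f = 2)
#' p$F_pull # 3
#' @export
ff_params <- function(eps = 1, kf = 30, k = Inf, f = 0, T_p = 1.5) {
  stopifnot(eps > 0, kf > 0, f >= 0)
  if (is.na(k) || k < 0) rlang::abort("tether stiffness k must be >= 0 (Inf = immobile)")
  sig <- sigma_table()
  structure(list(
    eps = eps, sigma = sig, cutoff = 2^(1 / 6) * sig,
    kf = kf, k = k, f = f, T_p = T_p, F_pull = f_to_force(f, T_p)
  ), class = "poremd_ff")
}

#' @export
print.poremd_ff <- function(x, ...) {
  cat("<poremd_ff> eps =", x$eps, " kf =", x$kf, " k =", x$k,
      " f =", x$f, "(F =", x$F_pull, ")\n")
  invisible(x)
}

#' WCA pair energy and force
#'
#' The 12-6 Lennard-Jones potential shifted up by `eps` and truncated at its
#' minimum `2^(1/6) sigma`, so that energy and force go continuously to zero
#' at the cutoff. Purely repulsive: the returned scalar force (directed along
#' the outward separation vector) is non-negative everywhere.
#'
#' @param r Distance(s) between the two beads; must be positive.
#' @param sigma Interaction radius `sigma_ij`.
#' @param eps Energy scale.
#' @return A tibble with columns `r`, `energy`, `force`.
#' @examples
#' pair_energy_force(1, sigma = 1) # energy eps, force 24 eps
#' @export
pair_energy_force <- function(r, sigma = 1, eps = 1) {
  stopifnot(is.numeric(r), sigma > 0, eps > 0)
  if (any(r <= 0)) rlang::abort("pair distance must be positive")
  rc <- 2^(1 / 6) * sigma
  sr6 <- (sigma / r)^6
  e <- ifelse(r <= rc, 4 * eps * (sr6^2 - sr6) + eps, 0)
  f <- ifelse(r <= rc, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  tibble::tibble(r = r, energy = e, force = f)
}

#' FENE bond energy and force
#'
#' The attractive finitely extensible term of the FENE interaction,
#' \eqn{-\frac{1}{2} K R_0^2 \ln(1 - (r/R_0)^2)} with stiffness
#' `K = kf / sigma^2` and maximum extension `R0 = 1.5 sigma`. It diverges as
#' `r` approaches `R0`; a distance at or beyond `R0` is a broken bond and
#' raises an error. The full bond interaction is this term plus the WCA
#' repulsion of [pair_energy_force()].
#'
#' @param r Bond length(s), in `(0, 1.5 sigma)`.
#' @param sigma Interaction radius of the bonded pair.
#' @param kf Stiffness prefactor.
#' @return A tibble with columns `r`, `energy`, `force` (negative = directed
#'   inward, i.e. attractive).
#' @examples
#' bond_energy_force(0.75, sigma = 1) # energy -0.5*30*1.5^2*log(3/4)
#' @export
bond_energy_force <- function(r, sigma = 1, kf = 30) {
  stopifnot(is.numeric(r), sigma > 0, kf > 0)
  if (any(r <= 0)) rlang::abort("bond length must be positive")
  R0 <- 1.5 * sigma
  if (any(r >= R0)) {
    rlang::abort(sprintf(
      "broken FENE bond: length %.4f >= maximum extension %.4f (integration step too large or force too strong)",
      max(r), R0))
  }
  K <- kf / sigma^2
  w <- 1 - (r / R0)^2
  tibble::tibble(r = r,
                 energy = -0.5 * K * R0^2 * log(w),
                 force = -K * r / w)
}

#' Harmonic tether energy and force
#'
#' Kinetic-membrane beads are tethered to their lattice anchors by
#' `U = k/2 |r - r_o|^2`. The immobile membrane is the `k = Inf` limit,
#' handled by marking beads frozen rather than by arithmetic.
#'
#' @param pos Position (length-3 vector or n x 3 matrix).
#' @param anchor Anchor position(s), same shape.
#' @param k Tether stiffness (>= 0, finite).
#' @return A list with `energy` (scalar or vector) and `force` (same shape as
#'   `pos`).
#' @examples
#' tether_energy_force(c(0.1, 0, 0), c(0, 0, 0), k = 300)
#' @export
tether_energy_force <- function(pos, anchor, k) {
  if (is.na(k) || !is.finite(k) || k < 0) {
    rlang::abort("tether stiffness must be finite and >= 0 (use frozen beads for k = Inf)")
  }
  pos <- rbind(pos)
  anchor <- rbind(anchor)
  d <- pos - anchor
  e <- 0.5 * k * rowSums(d^2)
  f <- -k * d
  if (nrow(pos) == 1) list(energy = e[[1]], force = f[1, ]) else
    list(energy = e, force = f)
}

#' Total forces and potential energy of a system
#'
#' Assembles WCA pairs (minimum image in x-y), FENE bonds, harmonic tethers
#' and the pulling force on the pulled bead (when the pull is switched on)
#' for a [assemble_system()] object. Membrane-membrane pair interactions are
#' included only for the kinetic membrane. The neighbor-list path uses cell
#' binning with a Verlet skin and must agree with the brute-force all-pairs
#' path to round-off.
#'
#' @param system A `poremd_system`.
#' @param neighbor_list Use the cell/Verlet neighbor list (`TRUE`) or the
#'   O(N^2) all-pairs reference path (`FALSE`).
#' @param skin Verlet skin distance.
#' @return A list with `forces` (N x 3 matrix) and `energy` (total potential
#'   energy).
#' @export
total_forces <- function(system, neighbor_list = TRUE, skin = 0.3) {
  stopifnot(inherits(system, "poremd_system"))
  s <- system
  res <- cpp_forces(
    s$pos, s$vel, s$beads$kind - 1L,
    as.integer(s$beads$group == "membrane"), s$frozen, s$beads$mass, s$temp,
    s$ff$sigma, s$ff$eps,
    bonds_matrix(s), s$bonds$R0, s$bonds$K,
    s$tether_k, s$anchor, s$box[1], s$box[2], s$mm_pairs,
    if (s$pull_on) s$pulled - 1L else -1L, s$ff$F_pull,
    if (neighbor_list) "cell" else "brute", skin)
  res
}

bonds_matrix <- function(system) {
  if (nrow(system$bonds) == 0) {
    matrix(integer(0), 0, 2)
  } else {
    cbind(system$bonds$i - 1L, system$bonds$j - 1L)
  }
}
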