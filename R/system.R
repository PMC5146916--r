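# System assembly: combine a polymer and an (optionally carved) membrane into
# one simulation-ready object holding positions, velocities, bonds, tethers,
# thermostat targets and frozen flags.

#' Assemble a polymer + membrane simulation system
#'
#' Combines a [build_polymer()] chain and a [carve_pore()] membrane into a
#' single system. Two membrane modes are supported: `"immobile"` (the
#' `k = Inf` reference: membrane beads are frozen force sources and
#' membrane-membrane interactions are skipped) and `"kinetic"` (beads
#' tethered to their lattice anchors with stiffness `k`, thermostatted at
#' `T_m`, and interacting among themselves).
#'
#' @param polymer A `poremd_polymer`.
#' @param membrane A `poremd_membrane`, or `NULL` for a free chain.
#' @param mode `"immobile"` or `"kinetic"`.
#' @param k Tether stiffness for the kinetic membrane (75 to 1e4 is the
#'   physically interesting range; `Inf` is equivalent to `mode =
#'   "immobile"`).
#' @param T_m Membrane temperature, `0 <= T_m <= T_p`.
#' @param T_p Polymer temperature (default 3/2).
#' @param m_C Membrane bead mass.
#' @param f Dimensionless pulling force (the pull itself is switched on by
#'   [run_translocation()], not at assembly).
#' @param kf FENE stiffness prefactor.
#' @return An object of class `poremd_system`.
#' @export
assemble_system <- function(polymer, membrane = NULL,
                            mode = c("immobile", "kinetic"),
                            k = Inf, T_m = 0, T_p = 1.5, m_C = 1, f = 0,
                            kf = polymer$kf) {
  mode <- match.arg(mode)
  stopifnot(inherits(polymer, "poremd_polymer"), T_m >= 0, T_p > 0, m_C > 0)
  if (T_m > T_p) rlang::warn("membrane temperature exceeds the polymer temperature")
  if (mode == "kinetic" && is.infinite(k)) mode <- "immobile"
  if (mode == "kinetic" && (is.na(k) || k < 0)) {
    rlang::abort("kinetic membrane needs a finite tether stiffness k >= 0")
  }

  np <- nrow(polymer$beads)
  beads <- polymer$beads
  pos <- polymer$pos
  tether_k <- rep(0, np)
  anchor <- matrix(0, np, 3)
  frozen <- rep(FALSE, np)
  temp <- rep(T_p, np)

  rim_idx <- integer(0)
  pore_radius <- NA_real_
  box <- c(Lx = 1e9, Ly = 1e9)
  d <- NA_real_

  if (!is.null(membrane)) {
    stopifnot(inherits(membrane, "poremd_membrane"))
    nm <- membrane$n_sites
    beads <- dplyr::bind_rows(beads, tibble::tibble(
      id = np + seq_len(nm), label = "C", kind = 4L, group = "membrane",
      sigma = 1 / 3, mass = m_C))
    pos <- rbind(pos, membrane$sites)
    anchor <- rbind(anchor, membrane$sites)
    if (mode == "immobile") {
      tether_k <- c(tether_k, rep(0, nm))
      frozen <- c(frozen, rep(TRUE, nm))
    } else {
      tether_k <- c(tether_k, rep(k, nm))
      frozen <- c(frozen, rep(FALSE, nm))
    }
    temp <- c(temp, rep(T_m, nm))
    rim_idx <- np + membrane$rim_idx
    pore_radius <- membrane$pore_radius
    box <- membrane$box
    d <- membrane$d
  }

  structure(list(
    beads = beads,
    pos = unname(pos),
    vel = matrix(0, nrow(beads), 3),
    bonds = polymer$bonds,
    tether_k = tether_k,
    anchor = unname(anchor),
    frozen = frozen,
    temp = temp,
    pulled = polymer$pulled_bead,
    pull_on = FALSE,
    box = box,
    mm_pairs = mode == "kinetic",
    mode = mode,
    k = k, T_p = T_p, T_m = T_m,
    ff = ff_params(kf = kf, k = k, f = f, T_p = T_p),
    n_poly = np,
    rim_idx = rim_idx,
    pore_radius = pore_radius,
    d = d,
    step = 0L,
    time = 0
  ), class = "poremd_system")
}

#' @export
print.poremd_system <- function(x, ...) {
  nm <- nrow(x$beads) - x$n_poly
  cat("<poremd_system>", x$n_poly, "polymer beads",
      if (nm > 0) paste0("+ ", nm, " membrane sites (", x$mode, ")") else
        "(free chain)",
      "\n  f =", x$ff$f, " T_p =", x$T_p,
      if (nm > 0) paste0(" T_m = ", x$T_m, " k = ", x$k) else "",
      " step", x$step, "\n")
  invisible(x)
}

#' Free structured chain ready for simulation
#'
#' Convenience constructor for the membrane-free validation runs (diffusion
#' and gyration-radius scaling): builds the polymer, assembles it without a
#' membrane, unpins the first bead and draws Maxwell velocities at `T_p`.
#'
#' @inheritParams build_polymer
#' @param T_p Polymer temperature.
#' @return A `poremd_system` with no membrane and no frozen beads.
#' @export
free_chain_system <- function(n, seed = NULL, T_p = 1.5, kf = 30) {
  if (!is.null(seed)) set.seed(seed)
  pol <- build_polymer(n, kf = kf)
  sys <- assemble_system(pol, NULL, mode = "immobile", T_p = T_p, kf = kf)
  sys$vel <- maxwell_velocities(nrow(sys$beads), T_p, sys$beads$mass)
  sys
}

# Maxwell-Boltzmann velocity draw at temperature T (componentwise normal with
# variance T/m).
maxwell_velocities <- function(n, T, mass) {
  matrix(stats::rnorm(3 * n), n, 3) * sqrt(T / mass)
}
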