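# Fast invariant suite: geometry counts, unit rows, force-field consistency.
# Runs in seconds; used by the command-line `validate` entry point.

#' Run the fast model-invariant checks
#'
#' Desk-scale sanity suite: pore-carving counts (24 sites at radius 1.25 and
#' 54 at 1.75 under the calibrated lattice), the force and time unit
#' conversions, WCA cutoff continuity, the force-is-minus-gradient identity
#' on a random small chain, Newton's third law, and agreement between the
#' neighbor-list and brute-force force paths.
#'
#' @param seed Seed for the randomized checks.
#' @param quiet Suppress the per-check messages.
#' @return A tibble with columns `check` and `passed` (all `TRUE` on a
#'   healthy build), invisibly when `quiet = FALSE`.
#' @export
validate_model <- function(seed = 1, quiet = FALSE) {
  set.seed(seed)
  checks <- list()
  membrane <- build_membrane(cells = c(12L, 7L), n_ref = 2)
  checks[["pore count R = 1.25 is 24"]] <-
    carve_pore(membrane, 1.25)$n_removed == 24L
  checks[["pore count R = 1.75 is 54"]] <-
    carve_pore(membrane, 1.75)$n_removed == 54L
  checks[["force unit is 9.1 pN"]] <-
    abs(lj_to_si(1, "force") - 9.1e-12) < 0.05e-12
  checks[["time unit is 2.3 ps"]] <-
    abs(lj_to_si(1, "time") - 2.3e-12) < 0.05e-12
  pe <- pair_energy_force(2^(1 / 6), 1)
  checks[["WCA vanishes at the cutoff"]] <-
    abs(pe$energy) < 1e-12 && abs(pe$force) < 1e-12

  sys <- free_chain_system(4, seed = seed)
  ff <- total_forces(sys, neighbor_list = FALSE)
  checks[["Newton's third law"]] <-
    max(abs(colSums(ff$forces))) < 1e-9
  nl <- total_forces(sys, neighbor_list = TRUE)
  checks[["neighbor list matches brute force"]] <-
    max(abs(nl$forces - ff$forces)) < 1e-10

  h <- 1e-6
  i <- sample(nrow(sys$pos), 1)
  num <- vapply(1:3, function(ax) {
    up <- sys; up$pos[i, ax] <- up$pos[i, ax] + h
    dn <- sys; dn$pos[i, ax] <- dn$pos[i, ax] - h
    -(total_forces(up, neighbor_list = FALSE)$energy -
        total_forces(dn, neighbor_list = FALSE)$energy) / (2 * h)
  }, numeric(1))
  checks[["force equals minus energy gradient"]] <-
    max(abs(num - ff$forces[i, ])) < 1e-4 * max(1, max(abs(ff$forces[i, ])))

  out <- tibble::tibble(check = names(checks),
                        passed = unlist(checks, use.names = FALSE))
  if (!quiet) {
    for (r in seq_len(nrow(out))) {
      message(sprintf("[%s] %s", if (out$passed[r]) "ok" else "FAIL",
                      out$check[r]))
    }
  }
  out
}
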