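#' Reduced (Lennard-Jones) unit system and SI conversions
#'
#' The simulator works in reduced units with \eqn{\epsilon = \sigma_P = m =
#' k_B = 1}. The physical system mimicked is single-stranded DNA against a
#' graphene-like sheet, fixed by three defining scales: length `a` = 0.3 nm
#' (the backbone bead radius), mass `m` = 1.6e-25 kg, and energy
#' `eps` = 2.74e-21 J. All other scales derive from these:
#' time \eqn{\sqrt{m a^2/\epsilon}} (2.3 ps), force \eqn{\epsilon/a}
#' (9.1 pN), temperature \eqn{\epsilon/k_B} (198.5 K, so the polymer
#' temperature 3/2 corresponds to about 298 K), and friction \eqn{m/\tau}.
#'
#' @return A tibble with one row per quantity kind: the multiplicative scale
#'   from LJ to SI and the SI unit.
#' @examples
#' unit_system()
#' lj_to_si(1, "force") # ~9.1e-12 N
#' @export
unit_system <- function() {
  a <- 0.3e-9
  m <- 1.6e-25
  eps <- 2.74e-21
  kB <- 1.380649e-23
  tau <- sqrt(m * a^2 / eps)
  tibble::tibble(
    quantity = c("length", "mass", "energy", "temperature", "force", "time",
                 "friction", "velocity"),
    scale = c(a, m, eps, eps / kB, eps / a, tau, m / tau, a / tau),
    si_unit = c("m", "kg", "J", "K", "N", "s", "kg/s", "m/s")
  )
}

unit_scale <- function(quantity) {
  us <- unit_system()
  i <- match(quantity, us$quantity)
  if (anyNA(i)) {
    rlang::abort(paste0("unknown quantity kind: ",
                        paste(quantity[is.na(i)], collapse = ", "),
                        "; valid kinds: ", paste(us$quantity, collapse = ", ")))
  }
  us$scale[i]
}

#' Convert between reduced (LJ) and SI units
#'
#' @param value Numeric vector in LJ units (`lj_to_si`) or SI units
#'   (`si_to_lj`).
#' @param quantity One of `"length"`, `"mass"`, `"energy"`, `"temperature"`,
#'   `"force"`, `"time"`, `"friction"`, `"velocity"` (recycled against
#'   `value`).
#' @return Numeric vector in the other unit system (SI base units: m, kg, J,
#'   K, N, s, kg/s).
#' @examples
#' lj_to_si(1, "time") # ~2.3e-12 s
#' si_to_lj(9.1e-12, "force") # ~1
#' @export
lj_to_si <- function(value, quantity) {
  stopifnot(is.numeric(value))
  value * unit_scale(quantity)
}

#' @rdname lj_to_si
#' @export
si_to_lj <- function(value, quantity) {
  stopifnot(is.numeric(value))
  value / unit_scale(quantity)
}

#' Dimensionless pulling force to LJ force units
#'
#' The control parameter of the translocation protocol is the rescaled force
#' \eqn{f = F a / (k_B T_p)}. With \eqn{a = k_B = 1} and the polymer
#' temperature \eqn{T_p = 3/2}, the force applied to the pulled bead in LJ
#' force units is \eqn{F = 1.5 f}.
#'
#' @param f Dimensionless force.
#' @param T_p Polymer temperature (LJ units).
#' @return Force in LJ units.
#' @examples
#' f_to_force(2) # 3
#' @export
f_to_force <- function(f, T_p = 1.5) {
  stopifnot(is.numeric(f), all(f >= 0))
  f * T_p
}
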