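# Translocation-time statistics: ensemble means and errors, inverse-Gaussian
# first-passage fits, power-law force scaling, normalized ratios against a
# reference membrane, and free-chain validation observables.

#' Mean translocation time of an ensemble
#'
#' Arithmetic mean and standard error of the translocation time over the
#' successful (translocated) trajectories only; failed and timed-out
#' trajectories never enter the statistics.
#'
#' @param ensemble A `poremd_ensemble`, or any data frame with columns
#'   `status` and `tau`.
#' @return A one-row tibble: `n_total`, `n_success`, `tau`, `tau_se` (`NA`
#'   with a warning when there are no successes; `tau_se` is `NA` for a
#'   single success).
#' @export
mean_translocation_time <- function(ensemble) {
  stopifnot(is.data.frame(ensemble), all(c("status", "tau") %in% names(ensemble)))
  t_ok <- ensemble$tau[ensemble$status == "translocated"]
  if (length(t_ok) == 0) {
    rlang::warn("no successful translocations: mean translocation time is undefined")
    return(tibble::tibble(n_total = nrow(ensemble), n_success = 0L,
                          tau = NA_real_, tau_se = NA_real_))
  }
  tibble::tibble(
    n_total = nrow(ensemble),
    n_success = length(t_ok),
    tau = mean(t_ok),
    tau_se = if (length(t_ok) > 1) stats::sd(t_ok) / sqrt(length(t_ok)) else NA_real_)
}

# Inverse-Gaussian (drift-diffusion first-passage) density and distribution.
# mu = L/v is the mean first-passage time and lambda = L^2/(2D) the shape;
# the absolute distance L is not identifiable from times alone, so (mu,
# lambda) are the two fitted shape parameters.
dinvgauss <- function(x, mu, lambda, log = FALSE) {
  ld <- ifelse(x > 0,
               0.5 * log(lambda / (2 * pi * x^3)) -
                 lambda * (x - mu)^2 / (2 * mu^2 * x),
               -Inf)
  if (log) ld else exp(ld)
}

pinvgauss <- function(q, mu, lambda) {
  ifelse(q <= 0, 0,
         stats::pnorm(sqrt(lambda / q) * (q / mu - 1)) +
           exp(2 * lambda / mu +
                 stats::pnorm(-sqrt(lambda / q) * (q / mu + 1), log.p = TRUE)))
}

#' Fit the first-passage distribution of translocation times
#'
#' Maximum-likelihood fit of the one-dimensional drift-diffusion
#' first-passage density (the inverse-Gaussian family) to a sample of
#' translocation times. For a process with effective distance `L`, drift `v`
#' and diffusivity `D`, the identifiable parameters are the mean
#' `mu = L / v` and the shape `lambda = L^2 / (2 D)`; the MLE is closed form
#' (`mu` is the sample mean, a moment identity of the family).
#'
#' @param times Positive translocation times (at least `min_n`).
#' @param min_n Minimum sample size accepted for a distribution fit.
#' @return A `poremd_fp_fit` with the estimates, their asymptotic standard
#'   errors, the log-likelihood and a Kolmogorov-Smirnov goodness-of-fit
#'   statistic. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_first_passage <- function(times, min_n = 50L) {
  times <- times[!is.na(times)]
  if (length(times) < min_n) {
    rlang::abort(sprintf("first-passage fit needs at least %d times, got %d",
                         min_n, length(times)))
  }
  if (any(times <= 0)) rlang::abort("translocation times must be positive")
  if (stats::sd(times) == 0) {
    rlang::abort("degenerate sample: all translocation times identical")
  }
  n <- length(times)
  mu <- mean(times)
  inv_disp <- mean(1 / times) - 1 / mu # = 1/lambda MLE
  if (inv_disp <= 0) rlang::abort("first-passage fit did not converge: non-positive dispersion")
  lambda <- 1 / inv_disp
  ll <- sum(dinvgauss(times, mu, lambda, log = TRUE))
  ks <- suppressWarnings(
    stats::ks.test(times, function(q) pinvgauss(q, mu, lambda)))
  structure(list(
    mu = mu, lambda = lambda,
    mu_se = sqrt(mu^3 / (n * lambda)),
    lambda_se = sqrt(2 * lambda^2 / n),
    loglik = ll, n = n,
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    times = times
  ), class = "poremd_fp_fit")
}

#' @export
print.poremd_fp_fit <- function(x, ...) {
  cat("<poremd_fp_fit> inverse-Gaussian first-passage fit, n =", x$n,
      "\n  mu =", signif(x$mu, 5), "+/-", signif(x$mu_se, 3),
      "  lambda =", signif(x$lambda, 5), "+/-", signif(x$lambda_se, 3),
      "\n  logLik =", signif(x$loglik, 6),
      "  KS D =", signif(x$ks_stat, 3), "(p =", signif(x$ks_p, 3), ")\n")
  invisible(x)
}

#' @export
tidy.poremd_fp_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "lambda"),
                 estimate = c(x$mu, x$lambda),
                 std.error = c(x$mu_se, x$lambda_se))
}

#' @export
glance.poremd_fp_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, logLik = x$loglik,
                 ks.statistic = x$ks_stat, ks.p.value = x$ks_p)
}

#' Power-law fit of translocation time versus force
#'
#' Weighted least squares of `log(tau)` on `log(f)` inside a fit window,
#' reporting the decay exponent `gamma` of `tau(f) ~ f^-gamma` and its
#' standard error. Weights are the inverse squared relative errors when
#' `tau_se` is available. The high-force window default is `f >= 10`; the
#' crossover regime of the narrow pore lives at `f <= 4`.
#'
#' @param data Data frame with columns `f`, `tau` and optionally `tau_se`
#'   (e.g. the output of [force_sweep()]).
#' @param window Numeric length-2 inclusive range of `f` to fit; `NULL` fits
#'   all points.
#' @return A `poremd_scaling_fit` with `exponent = gamma` (positive for a
#'   decay). At least 3 points must fall in the window.
#' @examples
#' fit_power_law(tibble::tibble(f = c(10, 20, 40), tau = 100 / c(10, 20, 40)))
#' @export
fit_power_law <- function(data, window = NULL) {
  stopifnot(is.data.frame(data), all(c("f", "tau") %in% names(data)))
  d <- data
  if (!is.null(window)) d <- d[d$f >= window[1] & d$f <= window[2], ]
  if (nrow(d) < 3) rlang::abort("power-law fit needs at least 3 points in the window")
  if (any(d$f <= 0) || any(d$tau <= 0)) rlang::abort("f and tau must be positive")
  w <- if ("tau_se" %in% names(d) && all(is.finite(d$tau_se)) && all(d$tau_se > 0)) {
    (d$tau / d$tau_se)^2
  } else {
    rep(1, nrow(d))
  }
  fit <- stats::lm(log(tau) ~ log(f), data = d, weights = w)
  se_fit <- suppressWarnings(sqrt(diag(vcov(fit))))  # exact data: zero residuals
  new_scaling_fit(
    exponent = -unname(coef(fit)[2]),
    se = se_fit[2],
    window = range(d$f), n_points = nrow(d),
    data = tibble::tibble(x = d$f, y = d$tau,
                          se = if ("tau_se" %in% names(d)) d$tau_se else NA_real_),
    type = "force", xlab = "f", ylab = "tau")
}

new_scaling_fit <- function(exponent, se, window, n_points, data, type,
                            xlab, ylab) {
  structure(list(exponent = unname(exponent), se = unname(se),
                 window = window, n_points = n_points, data = data,
                 type = type, xlab = xlab, ylab = ylab),
            class = "poremd_scaling_fit")
}

#' @export
print.poremd_scaling_fit <- function(x, ...) {
  cat("<poremd_scaling_fit>", x$type, "scaling:",
      switch(x$type, force = "tau ~ f^-gamma, gamma",
             flory = "Rg ~ n^nu, nu",
             diffusion = "D ~ N^alpha, alpha", "exponent"),
      "=", signif(x$exponent, 4), "+/-", signif(x$se, 3),
      sprintf("(%d points, window %.3g..%.3g)\n",
              x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.poremd_scaling_fit <- function(x, ...) {
  tibble::tibble(term = "exponent", estimate = x$exponent, std.error = x$se)
}

#' @export
glance.poremd_scaling_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_points, window.min = x$window[1],
                 window.max = x$window[2], type = x$type)
}

#' Normalized translocation time
#'
#' The ratio `tau* = tau(ensemble) / tau(reference)` of mean translocation
#' times between two ensembles at the same force, with the error propagated
#' in quadrature. The reference is the immobile membrane for the
#' deformability study (`tau*(k, f) = tau(k, f) / tau(Inf, f)`) and the
#' `T_m = 0` kinetic membrane for the temperature study.
#'
#' @param ensemble,reference `poremd_ensemble` objects (or data frames with
#'   `status`/`tau` plus a config attribute carrying `f`).
#' @return A one-row tibble: `f`, `tau_star`, `tau_star_se`.
#' @export
normalized_tau <- function(ensemble, reference) {
  f1 <- attr(ensemble, "config")$f
  f2 <- attr(reference, "config")$f
  if (!is.null(f1) && !is.null(f2) && !isTRUE(all.equal(f1, f2))) {
    rlang::abort(sprintf("ensembles are at different forces (f = %s vs %s)", f1, f2))
  }
  a <- mean_translocation_time(ensemble)
  b <- mean_translocation_time(reference)
  ratio <- a$tau / b$tau
  se <- ratio * sqrt((a$tau_se / a$tau)^2 + (b$tau_se / b$tau)^2)
  tibble::tibble(f = if (is.null(f1)) NA_real_ else f1,
                 tau_star = ratio, tau_star_se = se)
}

#' Gyration radius
#'
#' Mass-weighted radius of gyration of a configuration:
#' \eqn{R_g^2 = \sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i}.
#'
#' @param pos N x 3 position matrix.
#' @param mass Optional bead masses (default equal).
#' @return Scalar `Rg`.
#' @examples
#' gyration_radius(rbind(c(0, 0, 0), c(1, 0, 0))) # 0.5
#' @export
gyration_radius <- function(pos, mass = NULL) {
  pos <- rbind(pos)
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  com <- colSums(pos * mass) / sum(mass)
  sqrt(sum(mass * rowSums(sweep(pos, 2, com)^2)) / sum(mass))
}

#' Flory-exponent fit of gyration-radius scaling
#'
#' Log-log fit of the equilibrium gyration radius against the repeat count
#' `n` (the number of nucleotide-like units). The structured chain shows an
#' apparent exponent above the ideal self-avoiding value 0.588 because of
#' its grafted side beads and finite length.
#'
#' The fit is unweighted by default: the deviations of short chains from
#' the asymptotic power law are systematic corrections to scaling, not
#' sampling noise, so inverse-variance weights (which concentrate the fit
#' on the most precisely measured, shortest chain) estimate the small-`n`
#' local slope rather than the scaling exponent.
#'
#' @param data Data frame with columns `n` and `rg`, optionally `rg_se`, for
#'   at least 3 chain lengths.
#' @param weighted Weight by inverse squared relative errors (`rg_se`).
#' @return A `poremd_scaling_fit` with `exponent = nu`.
#' @export
flory_fit <- function(data, weighted = FALSE) {
  stopifnot(is.data.frame(data), all(c("n", "rg") %in% names(data)))
  if (nrow(data) < 3) rlang::abort("Flory fit needs at least 3 chain lengths")
  if (any(data$n <= 0) || any(data$rg <= 0)) rlang::abort("n and rg must be positive")
  w <- if (weighted && "rg_se" %in% names(data) && all(is.finite(data$rg_se)) &&
           all(data$rg_se > 0)) (data$rg / data$rg_se)^2 else rep(1, nrow(data))
  fit <- stats::lm(log(rg) ~ log(n), data = data, weights = w)
  new_scaling_fit(unname(coef(fit)[2]),
                  suppressWarnings(sqrt(diag(vcov(fit))))[2],
                  range(data$n), nrow(data),
                  tibble::tibble(x = data$n, y = data$rg,
                                 se = if ("rg_se" %in% names(data)) data$rg_se else NA_real_),
                  "flory", "n", "Rg")
}

#' Diffusion constant from a center-of-mass trajectory
#'
#' Estimates `D` from the long-time slope of the center-of-mass mean-squared
#' displacement, `MSD(t) = 6 D t` in three dimensions. The MSD is computed
#' either from the initial time origin only (`origins = "first"`, exact for
#' a deterministic check) or averaged over all available time origins
#' (`origins = "all"`, the statistically efficient default).
#'
#' @param com Data frame or matrix with the center-of-mass trajectory; a
#'   data frame must have columns `time`, `com_x`, `com_y`, `com_z` (the
#'   `samples` tibble of [run_langevin()] works directly).
#' @param time Sample times (ignored when `com` is a data frame).
#' @param window Length-2 lag-time range used for the slope fit; must lie
#'   inside the trajectory.
#' @param origins `"all"` or `"first"`.
#' @param dimension Spatial dimension (3).
#' @return A one-row tibble: `D`, `slope`, `slope_se`, `t_min`, `t_max`.
#' @export
diffusion_constant <- function(com, time = NULL, window,
                               origins = c("all", "first"), dimension = 3) {
  origins <- match.arg(origins)
  if (is.data.frame(com)) {
    time <- com$time
    com <- cbind(com$com_x, com$com_y, com$com_z)
  }
  com <- as.matrix(com)
  stopifnot(length(time) == nrow(com), length(window) == 2)
  dt <- time[2] - time[1]
  span <- time[length(time)] - time[1]
  if (window[2] > span) {
    rlang::abort(sprintf("fit window extends to lag %.3g but the trajectory spans only %.3g",
                         window[2], span))
  }
  lags <- unique(round(seq(window[1] / dt, window[2] / dt, length.out = 25)))
  lags <- lags[lags >= 1]
  n <- nrow(com)
  msd <- vapply(lags, function(L) {
    if (origins == "first") {
      sum((com[1 + L, ] - com[1, ])^2)
    } else {
      idx <- seq_len(n - L)
      mean(rowSums((com[idx + L, , drop = FALSE] - com[idx, , drop = FALSE])^2))
    }
  }, numeric(1))
  fit <- stats::lm(msd ~ 0 + I(lags * dt))
  slope <- unname(coef(fit)[1])
  tibble::tibble(D = slope / (2 * dimension), slope = slope,
                 slope_se = suppressWarnings(sqrt(diag(vcov(fit))))[1],
                 t_min = window[1], t_max = window[2])
}

#' Diffusion-constant scaling with chain length
#'
#' Log-log fit of the center-of-mass diffusion constant against the number
#' of beads `N`. Without hydrodynamics the total chain friction is the sum
#' of the bead frictions, so `D = k_B T / (N xi)` and the expected exponent
#' is -1.
#'
#' @param data Data frame with columns `N` and `D`, optionally `D_se`, for
#'   at least 3 chain lengths.
#' @return A `poremd_scaling_fit` with `exponent` (the signed slope, about
#'   -1).
#' @export
diffusion_scaling <- function(data) {
  stopifnot(is.data.frame(data), all(c("N", "D") %in% names(data)))
  if (nrow(data) < 3) rlang::abort("diffusion scaling needs at least 3 chain lengths")
  if (any(data$N <= 0) || any(data$D <= 0)) rlang::abort("N and D must be positive")
  w <- if ("D_se" %in% names(data) && all(is.finite(data$D_se)) &&
           all(data$D_se > 0)) (data$D / data$D_se)^2 else rep(1, nrow(data))
  fit <- stats::lm(log(D) ~ log(N), data = data, weights = w)
  new_scaling_fit(unname(coef(fit)[2]),
                  suppressWarnings(sqrt(diag(vcov(fit))))[2],
                  range(data$N), nrow(data),
                  tibble::tibble(x = data$N, y = data$D,
                                 se = if ("D_se" %in% names(data)) data$D_se else NA_real_),
                  "diffusion", "N", "D")
}
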