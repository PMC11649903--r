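#' Rate constants of the competing discharge pathways
#'
#' A loaded E2~Ub conjugate (`E2L`) decays by three competing reactions:
#' pseudo-first-order hydrolysis (`k1`), second-order discharge onto an
#' added nucleophile at concentration `nu` (`k2 * nu`), and first-order
#' intramolecular autoubiquitination producing `E2Ub` (`k3`). Units are
#' fixed package-wide: minutes and millimolar, so `k1` and `k3` are in
#' 1/min and `k2` in 1/(mM min).
#'
#' @param k1 Hydrolysis rate constant, 1/min.
#' @param k2 Nucleophile discharge rate constant, 1/(mM min).
#' @param k3 Intramolecular autoubiquitination rate constant, 1/min.
#' @param E2L0 Initially loaded fraction (densitometric scale), in (0, 1].
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k1 = 0.015, k2 = 3.8e-4, k3 = 0.002)
#' @export
kinetic_params <- function(k1, k2 = 0, k3 = 0, E2L0 = 1) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3), is.numeric(E2L0),
            length(k1) == 1L, length(k2) == 1L, length(k3) == 1L,
            length(E2L0) == 1L)
  if (!is.finite(k1) || !is.finite(k2) || !is.finite(k3) || !is.finite(E2L0))
    stop("rate constants and E2L0 must be finite")
  if (k1 < 0 || k2 < 0 || k3 < 0)
    stop("rate constants must be non-negative")
  if (E2L0 <= 0 || E2L0 > 1)
    stop("E2L0 must lie in (0, 1]")
  structure(list(k1 = k1, k2 = k2, k3 = k3, E2L0 = E2L0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Discharge kinetic parameters (min, mM units)\n")
  cat(sprintf("  k1 (hydrolysis)          : %g /min\n", x$k1))
  cat(sprintf("  k2 (nucleophile attack)  : %g /(mM min)\n", x$k2))
  cat(sprintf("  k3 (autoubiquitination)  : %g /min\n", x$k3))
  cat(sprintf("  E2L0 (loaded fraction)   : %g\n", x$E2L0))
  invisible(x)
}

.check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L)
    stop("times must be a non-empty numeric vector")
  bad <- which(!is.finite(times) | times < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite time at index %d (t = %g)",
                 bad[1L], times[bad[1L]]))
  invisible(times)
}

#' Closed-form species trajectories of the chase reaction
#'
#' Evaluates the analytic solution of the competing-pathway rate laws.
#' With the observed decay constant `kobs = k1 + k2*nu + k3`,
#' the loaded fraction is `E2L(t) = E2L0 * exp(-kobs * t)`, the
#' autoubiquitinated fraction builds up to a plateau,
#' `E2Ub(t) = (k3 * E2L0 / kobs) * (1 - exp(-kobs * t))`, and the
#' discharged apo fraction follows by mass balance,
#' `E2(t) = E2L0 - E2L(t) - E2Ub(t)`.
#'
#' @param params A [kinetic_params] object.
#' @param nu Nucleophile concentration, mM (non-negative scalar).
#' @param times Evaluation times, min (non-negative).
#' @return A data frame with columns `t`, `E2L`, `E2`, `E2Ub`, `nu`.
#' @seealso [observed_mono_signal()], [ode_species()]
#' @examples
#' p <- kinetic_params(k1 = 0.015, k2 = 3.8e-4, k3 = 0.002)
#' closed_form_species(p, nu = 250, times = c(0, 15, 30, 60))
#' @export
closed_form_species <- function(params, nu, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0)
    stop("nu must be a non-negative finite scalar (mM)")
  .check_times(times)
  kobs <- params$k1 + params$k2 * nu + params$k3
  e <- exp(-kobs * times)
  E2L <- params$E2L0 * e
  E2Ub <- if (kobs > 0) (params$k3 * params$E2L0 / kobs) * (1 - e)
          else rep(0, length(times))
  E2 <- params$E2L0 - E2L - E2Ub
  data.frame(t = times, E2L = E2L, E2 = E2, E2Ub = E2Ub, nu = nu)
}

#' Observed mono-ubiquitinated band signal
#'
#' On non-reducing gels the autoubiquitinated E2 co-migrates with the
#' thioester-loaded E2, so the quantifiable mono-Ub band is the sum
#' `E2L(t) + E2Ub(t)`. This is the model function used in all discharge
#' fits. With `k3 = 0` it is strictly decreasing (whenever
#' `k1 + k2*nu > 0`); with `k3 > 0` it decays to the asymptote
#' `k3 * E2L0 / (k1 + k2*nu + k3)`.
#'
#' @inheritParams closed_form_species
#' @param label Free-text label stored on the returned course.
#' @return A [time_course] with observable `"mono_band"`.
#' @export
observed_mono_signal <- function(params, nu, times, label = "") {
  sp <- closed_form_species(params, nu, times)
  time_course(times = sp$t, signal = sp$E2L + sp$E2Ub, nu = nu,
              observable = "mono_band", label = label)
}

#' Numerical integration oracle for the discharge rate laws
#'
#' Integrates the differential rate laws
#' `dE2L/dt = -(k1 + k2*nu + k3) E2L`, `dE2/dt = (k1 + k2*nu) E2L`,
#' `dE2Ub/dt = k3 E2L` with a stiff-capable solver at tight tolerance.
#' This is deliberately independent of [closed_form_species()] and serves
#' as a brute-force validator of the analytic solution.
#'
#' @inheritParams closed_form_species
#' @param rtol,atol Solver tolerances passed to [deSolve::ode()].
#' @return A data frame with the same columns as [closed_form_species()].
#' @export
ode_species <- function(params, nu, times, rtol = 1e-12, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0)
    stop("nu must be a non-negative finite scalar (mM)")
  .check_times(times)
  t_ode <- times
  prepend <- times[1L] > 0
  if (prepend) t_ode <- c(0, times)
  rhs <- function(t, y, p) {
    list(c(E2L = -(p$k1 + p$k2 * nu + p$k3) * y[["E2L"]],
           E2  =  (p$k1 + p$k2 * nu) * y[["E2L"]],
           E2Ub = p$k3 * y[["E2L"]]))
  }
  out <- try(deSolve::ode(y = c(E2L = params$E2L0, E2 = 0, E2Ub = 0),
                          times = t_ode, func = rhs, parms = params,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out)))
    stop(sprintf(
      "ODE integration failed for k1=%g k2=%g k3=%g E2L0=%g nu=%g",
      params$k1, params$k2, params$k3, params$E2L0, nu))
  out <- as.data.frame(out)
  if (prepend) out <- out[-1L, , drop = FALSE]
  data.frame(t = times, E2L = out$E2L, E2 = out$E2, E2Ub = out$E2Ub, nu = nu)
}

#' Convert between first-order rate constants and half-lives
#'
#' `half_life_from_rate(k)` returns `ln(2)/k` (min for k in 1/min);
#' `rate_from_half_life` is its algebraic inverse.
#'
#' @param k First-order rate constant (> 0), 1/min.
#' @param t_half Half-life (> 0), min.
#' @return Numeric scalar or vector.
#' @examples
#' half_life_from_rate(0.015) # ~46 min
#' @export
half_life_from_rate <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("k must be a positive finite rate constant")
  log(2) / k
}

#' @rdname half_life_from_rate
#' @export
rate_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    stop("t_half must be a positive finite half-life")
  log(2) / t_half
}
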