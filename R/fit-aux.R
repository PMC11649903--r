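#' A rate constant with its standard error
#'
#' @param value Rate (any of k1, k2, k_obs); units as context dictates.
#' @param sd Standard error/deviation of the rate, same units; >= 0.
#' @param flagged Logical: set when the producing fit was degenerate.
#' @param note Free-text diagnostic.
#' @return An object of class `rate_with_error`.
#' @export
rate_with_error <- function(value, sd = 0, flagged = FALSE, note = "") {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(sd), length(sd) == 1L)
  if (is.finite(sd) && sd < 0) stop("sd must be non-negative")
  structure(list(value = value, sd = sd, flagged = isTRUE(flagged),
                 note = note),
            class = "rate_with_error")
}

#' @export
print.rate_with_error <- function(x, ...) {
  cat(sprintf("rate %.4g +/- %.3g%s%s\n", x$value, x$sd,
              if (x$flagged) "  [flagged]" else "",
              if (nzchar(x$note)) paste0("  (", x$note, ")") else ""))
  invisible(x)
}

.course_xy <- function(course, times, signal) {
  if (!is.null(course)) {
    stopifnot(inherits(course, "time_course"))
    list(t = course$time_min, y = course$signal)
  } else list(t = times, y = signal)
}

#' Mono-exponential fit of a kinetic trace
#'
#' Fits `A * exp(-k_obs * t) + C` by Levenberg-Marquardt least squares,
#' as used for fluorescence anisotropy traces where only the overall
#' observed decay rate is needed. Non-decaying input yields a `k_obs`
#' near zero with a large standard error and the result is flagged.
#'
#' @param course A [time_course] (or supply `times`/`signal` directly).
#' @param times,signal Alternative raw vectors.
#' @return A [rate_with_error] for `k_obs` (1/min) with the full
#'   parameter vector in `attr(, "parameters")` and their standard
#'   errors in `attr(, "stderr")`.
#' @export
fit_mono_exponential <- function(course = NULL, times = NULL,
                                 signal = NULL) {
  xy <- .course_xy(course, times, signal)
  t <- xy$t; y <- xy$y
  if (length(t) < 4L) stop("mono-exponential fit needs >= 4 points")

  C0 <- min(y)
  A0 <- y[1L] - C0
  decaying <- A0 > 0 && stats::cor(t, y) < 0
  k0 <- if (decaying) {
    z <- pmax((y - C0) / A0, 1e-8)
    max(-unname(coef(stats::lm(log(z) ~ t))[2L]), 1e-8)
  } else 1e-6
  if (A0 == 0) A0 <- max(abs(y[1L]), 1e-3)

  fn <- function(p) p[1L] * exp(-exp(p[2L]) * t) + p[3L] - y
  lf <- minpack.lm::nls.lm(par = c(A0, log(k0), C0), fn = fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(lf)
  k <- exp(p[2L])
  n <- length(t); dof <- max(n - 3L, 1L)
  s2 <- sum(fn(p)^2) / dof
  J <- .num_jacobian(fn, p)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(Inf, 3L, 3L))
  sd_k <- k * sqrt(max(vc[2L, 2L], 0))         # delta method off log scale
  sds <- c(A = sqrt(max(vc[1L, 1L], 0)), k_obs = sd_k,
           C = sqrt(max(vc[3L, 3L], 0)))
  flagged <- !decaying || !is.finite(sd_k) || sd_k >= abs(k)
  out <- rate_with_error(k, sd_k, flagged = flagged,
                         note = if (flagged) "non-decaying or ill-determined"
                                else "")
  attr(out, "parameters") <- c(A = p[1L], k_obs = k, C = p[3L])
  attr(out, "stderr") <- sds
  out
}

#' Double-exponential fit of a kinetic trace
#'
#' Fits `A1 * exp(-k_a * t) + A2 * exp(-k_b * t) + C` with the
#' convention `k_a >= k_b` (components reordered after fitting). Used
#' for biphasic build-up/decay such as the emergence of NaOH-sensitive
#' and -resistant modification. If the two rates collapse
#' (`k_a / k_b < 1.2`) the result is flagged as effectively
#' mono-exponential.
#'
#' @inheritParams fit_mono_exponential
#' @return A named list with `parameters` (`A1, k_a, A2, k_b, C`),
#'   `stderr`, `residual_rms` and `flagged`.
#' @export
fit_double_exponential <- function(course = NULL, times = NULL,
                                   signal = NULL) {
  xy <- .course_xy(course, times, signal)
  t <- xy$t; y <- xy$y
  if (length(t) < 6L) stop("double-exponential fit needs >= 6 points")

  mono <- fit_mono_exponential(times = t, signal = y)
  pm <- attr(mono, "parameters")
  k0 <- max(mono$value, 1e-6)
  A0 <- pm[["A"]]
  if (abs(A0) < 1e-12) A0 <- max(abs(y[1L] - min(y)), 1e-3)

  fn <- function(p) p[1L] * exp(-exp(p[2L]) * t) +
    p[3L] * exp(-exp(p[4L]) * t) + p[5L] - y
  start <- c(A0 / 2, log(k0 * 4), A0 / 2, log(k0 / 4), pm[["C"]])
  lf <- minpack.lm::nls.lm(par = start, fn = fn,
                           control = minpack.lm::nls.lm.control(maxiter = 400))
  p <- coef(lf)
  ka <- exp(p[2L]); kb <- exp(p[4L])
  A1 <- p[1L]; A2 <- p[3L]
  if (kb > ka) { tmp <- ka; ka <- kb; kb <- tmp
                 tmp <- A1; A1 <- A2; A2 <- tmp
                 p <- c(A1, log(ka), A2, log(kb), p[5L]) }
  n <- length(t); dof <- max(n - 5L, 1L)
  s2 <- sum(fn(p)^2) / dof
  J <- .num_jacobian(fn, p)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(Inf, 5L, 5L))
  sds <- c(A1 = sqrt(max(vc[1L, 1L], 0)),
           k_a = ka * sqrt(max(vc[2L, 2L], 0)),
           A2 = sqrt(max(vc[3L, 3L], 0)),
           k_b = kb * sqrt(max(vc[4L, 4L], 0)),
           C = sqrt(max(vc[5L, 5L], 0)))
  degenerate <- ka / max(kb, 1e-300) < 1.2
  list(parameters = c(A1 = A1, k_a = ka, A2 = A2, k_b = kb, C = p[5L]),
       stderr = sds,
       residual_rms = sqrt(mean(fn(p)^2)),
       flagged = degenerate,
       note = if (degenerate) "rates collapsed: effectively mono-exponential"
              else "")
}

#' Linear fit of observed rates against concentration
#'
#' Ordinary least squares of `k_obs` on concentration (e.g. a RING-domain
#' titration); the intercept is the E3-free rate and the slope the
#' concentration dependence.
#'
#' @param conc Concentrations (mM or uM, caller's convention).
#' @param k_obs Observed rate at each concentration.
#' @return List with `slope`, `intercept` (both [rate_with_error]),
#'   `residual_rms` and the underlying `lm` fit.
#' @export
fit_linear_rate_vs_conc <- function(conc, k_obs) {
  stopifnot(is.numeric(conc), is.numeric(k_obs),
            length(conc) == length(k_obs))
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct concentrations for a linear fit")
  fit <- stats::lm(k_obs ~ conc)
  sm <- summary(fit)$coefficients
  se_int <- if (nrow(sm) >= 1L) sm[1L, 2L] else NA_real_
  se_slo <- sm[2L, 2L]
  list(slope = rate_with_error(unname(coef(fit)[2L]),
                               ifelse(is.finite(se_slo), se_slo, 0)),
       intercept = rate_with_error(unname(coef(fit)[1L]),
                                   ifelse(is.finite(se_int), se_int, 0)),
       residual_rms = sqrt(mean(residuals(fit)^2)),
       fit = fit)
}

#' pH dose-response fit of observed discharge rates
#'
#' Fits a 4-parameter logistic in pH,
#' `k(pH) = floor + (ceiling - floor) / (1 + 10^(slope * (midpoint - pH)))`,
#' to `k_obs` values from a pH titration; the midpoint estimates the
#' apparent pKa of the rate-limiting deprotonation.
#'
#' @param ph pH values (>= 5 points spanning the transition).
#' @param k_obs Observed rate at each pH.
#' @return List with `floor`, `ceiling`, `midpoint`, `slope` estimates,
#'   `stderr`, `midpoint` as [rate_with_error]-style pair, `flagged`
#'   for unidentifiable transitions, and `residual_rms`.
#' @export
fit_ph_dose_response <- function(ph, k_obs) {
  stopifnot(is.numeric(ph), is.numeric(k_obs), length(ph) == length(k_obs))
  if (length(ph) < 5L) stop("pH dose-response fit needs >= 5 points")
  rng <- diff(range(k_obs))
  if (rng <= 0 || rng < 1e-9 * max(abs(k_obs), 1)) {
    return(list(parameters = c(floor = min(k_obs), ceiling = max(k_obs),
                               midpoint = NA_real_, slope = NA_real_),
                stderr = c(floor = NA, ceiling = NA, midpoint = NA,
                           slope = NA),
                flagged = TRUE,
                note = "flat data: midpoint and slope unidentifiable",
                residual_rms = stats::sd(k_obs)))
  }
  lo0 <- min(k_obs); hi0 <- max(k_obs)
  half <- lo0 + (hi0 - lo0) / 2
  mid0 <- stats::approx(k_obs, ph, xout = half, ties = mean)$y
  if (!is.finite(mid0)) mid0 <- stats::median(ph)
  fn <- function(p) p[1L] + (p[2L] - p[1L]) /
    (1 + 10^(p[4L] * (p[3L] - ph))) - k_obs
  lf <- minpack.lm::nls.lm(par = c(lo0, hi0, mid0, 1),
                           fn = fn,
                           control = minpack.lm::nls.lm.control(maxiter = 400))
  p <- coef(lf)
  dof <- max(length(ph) - 4L, 1L)
  s2 <- sum(fn(p)^2) / dof
  J <- .num_jacobian(fn, p)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(Inf, 4L, 4L))
  sds <- sqrt(pmax(diag(vc), 0))
  names(sds) <- c("floor", "ceiling", "midpoint", "slope")
  flagged <- !is.finite(sds[["midpoint"]]) ||
    sds[["midpoint"]] > diff(range(ph))
  list(parameters = c(floor = p[1L], ceiling = p[2L], midpoint = p[3L],
                      slope = p[4L]),
       stderr = sds, flagged = flagged,
       note = if (flagged) "midpoint poorly determined" else "",
       residual_rms = sqrt(mean(fn(p)^2)))
}

#' Fold difference between wild-type and mutant rates with propagated error
#'
#' Computes `ratio = k_WT / k_Mut` and propagates the standard deviations
#' of the averaged rate constants as
#' `d(ratio) = ratio * sqrt((dk_WT/k_WT)^2 + (dk_Mut/k_Mut)^2)`.
#'
#' @param wt,mut [rate_with_error] objects (or 2-element numeric
#'   `c(value, sd)` vectors); both values must be positive.
#' @return A [rate_with_error] holding the fold difference.
#' @examples
#' fold_change_with_error(rate_with_error(1, 0.1), rate_with_error(1, 0.1))
#' @export
fold_change_with_error <- function(wt, mut) {
  as_rwe <- function(x) {
    if (inherits(x, "rate_with_error")) return(x)
    if (is.numeric(x) && length(x) == 2L) return(rate_with_error(x[1L], x[2L]))
    stop("expected a rate_with_error or c(value, sd)")
  }
  wt <- as_rwe(wt); mut <- as_rwe(mut)
  if (mut$value <= 0)
    stop("mutant rate must be positive (fold change undefined)")
  if (wt$value <= 0)
    stop("wild-type rate must be positive for relative-error propagation")
  ratio <- wt$value / mut$value
  err <- ratio * sqrt((wt$sd / wt$value)^2 + (mut$sd / mut$value)^2)
  rate_with_error(ratio, err)
}

#' Kinetic solvent isotope ratios from paired H2O/D2O experiments
#'
#' For rate constants measured in parallel in H2O and D2O, computes the
#' per-pair ratio `k_H2O / k_D2O` (the KSIE) and its mean and SD across
#' pairs. A KSIE well above 1 is diagnostic of rate-limiting proton
#' transfer, as expected for general base catalysis.
#'
#' @param k_h2o,k_d2o Equal-length vectors of positive rate constants
#'   from paired experiments.
#' @return List with `ratios`, `mean`, `sd`, `n`.
#' @export
solvent_isotope_ratio <- function(k_h2o, k_d2o) {
  stopifnot(is.numeric(k_h2o), is.numeric(k_d2o))
  if (length(k_h2o) != length(k_d2o))
    stop("unmatched pair lengths: each H2O rate needs its D2O partner")
  if (length(k_h2o) == 0L) stop("no pairs supplied")
  if (any(k_h2o <= 0) || any(k_d2o <= 0))
    stop("all rate constants must be positive")
  ratios <- k_h2o / k_d2o
  list(ratios = ratios, mean = mean(ratios),
       sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
       n = length(ratios))
}
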