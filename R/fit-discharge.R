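#' @importFrom stats coef vcov predict fitted residuals simulate setNames
NULL

.par_names <- c("k1", "k2", "k3", "E2L0")
.rate_names <- c("k1", "k2", "k3")
.LOG_FLOOR <- log(1e-12)
.LOG_CEIL <- log(1e3)

# Model signal for one course: observed mono band E2L(t) + E2Ub(t).
.mono_model <- function(k1, k2, k3, E2L0, nu, times) {
  kobs <- k1 + k2 * nu + k3
  if (kobs <= 0) return(rep(E2L0, length(times)))
  e <- exp(-kobs * times)
  E2L0 * e + (k3 * E2L0 / kobs) * (1 - e)
}

# Deterministic initialization:
#   E2L0 from the first sample of the first course;
#   k1 from a mono-exponential pre-fit of the lowest-nu course;
#   k2 from (k_obs(nu) - k1)/nu of the highest-nu course;
#   k3 from the late-time plateau p ~= k3/kobs.
.init_discharge <- function(design, fix) {
  courses <- design$courses
  nus <- vapply(courses, nu_of, numeric(1L))
  co0 <- courses[[which.min(nus)]]
  E2L0 <- max(co0$signal[1L], 1e-3)
  amp0 <- co0$signal[1L] - min(co0$signal)
  # non-decaying course: start unidentifiable rates at the floor so they
  # stay there (zero gradient once the flat solution is reached)
  flat <- amp0 <= 1e-9
  k_lo <- .rough_kobs(co0)
  k1 <- if (flat) 1e-12 else max(k_lo, 1e-6)
  k2 <- 1e-12
  if (max(nus) > 0) {
    co_hi <- courses[[which.max(nus)]]
    amp_hi <- co_hi$signal[1L] - min(co_hi$signal)
    k_hi <- .rough_kobs(co_hi)
    k2 <- if (amp_hi <= 1e-9) 1e-12
          else if (k_hi > k_lo) (k_hi - k_lo) / max(nus)
          else max(k_lo, 1e-6) / max(nus)    # same order as the nu=0 rate
  }
  plateau <- max(0, min(co0$signal) / E2L0)
  k3 <- if (flat || plateau >= 1 - 1e-9) 1e-12
        else max(k1 * plateau / max(1 - plateau, 1e-3), 1e-8)
  init <- c(k1 = k1, k2 = k2, k3 = k3, E2L0 = E2L0)
  init[names(fix)] <- unlist(fix)
  init
}

# Crude decay-rate estimate from the first half-amplitude crossing;
# robust to plateau noise, only used for initialization.
.rough_kobs <- function(course) {
  y <- course$signal
  t <- course$time_min
  base <- min(y)
  amp <- y[1L] - base
  if (amp <= 0) return(1e-6)
  half <- base + amp / 2
  below <- which(y <= half)
  below <- below[below > 1L]
  if (!length(below)) {                      # never crosses: slow decay
    z <- pmax((y - base) / amp, 1e-8)
    fit <- stats::lm(log(z) ~ t)
    return(max(-unname(coef(fit)[2L]), 1e-6))
  }
  i <- below[1L]
  frac <- (y[i - 1L] - half) / max(y[i - 1L] - y[i], 1e-12)
  t_half <- t[i - 1L] + frac * (t[i] - t[i - 1L])
  max(log(2) / max(t_half, 1e-6), 1e-6)
}

#' Global fit of the competing-pathway discharge model
#'
#' Fits the observed mono-ubiquitinated signal `E2L(t) + E2Ub(t)` jointly
#' to all courses of a chase design by Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]). The kinetic parameters (`E2L0`, `k1`, `k2`,
#' `k3`) are shared across courses while each course's nucleophile
#' concentration is held fixed at its recorded value, so a nucleophile-free
#' course pins down `k1` (and `k3`) and nucleophile-containing courses
#' determine `k2`. Rates are optimized on the log scale, which enforces
#' positivity across their orders-of-magnitude range.
#'
#' @param design A [chase_design]; every course must carry the
#'   `mono_band` or `modified_fraction` observable semantics of a
#'   fraction-scale signal.
#' @param fix Named numeric vector of parameters to hold fixed, e.g.
#'   `c(k2 = 0, k3 = 0)` for a hydrolysis-only fit.
#' @param init Optional [kinetic_params] or named numeric vector of
#'   starting values; by default a deterministic heuristic is used
#'   (E2L0 from the first sample, `k1` from a mono-exponential pre-fit of
#'   the nucleophile-free course, `k2` from the excess decay rate of the
#'   highest-nu course, `k3` from the late-time plateau).
#' @param apparent Logical; set `TRUE` when the courses were recorded in
#'   the presence of a RING-domain E3. The discharge then occurs from a
#'   mixture of RING-bound and free conjugate, so the fitted constants
#'   are apparent, meaningful only at that RING concentration; the flag
#'   is carried through to printing.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `discharge_fit` with components
#'   `estimates` (named vector on the natural scale), `stderr`, `vcov`
#'   (free parameters, natural scale), `residual_rms`, `n_points`, `df`,
#'   `converged`, `apparent`, `design`, `fix`, `init`, `message`. Methods:
#'   [coef()], [vcov()], [predict()], [fitted()], [residuals()],
#'   [summary()], [plot()], [simulate()].
#' @examples
#' p <- kinetic_params(k1 = 0.015, k2 = 3.8e-4, k3 = 0.002)
#' tt <- seq(0, 120, by = 10)
#' d <- chase_design(observed_mono_signal(p, 0, tt),
#'                   observed_mono_signal(p, 250, tt))
#' fit <- fit_discharge(d)
#' coef(fit)
#' @export
fit_discharge <- function(design, fix = NULL, init = NULL,
                          apparent = FALSE,
                          control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (!inherits(design, "chase_design"))
    stop("design must be a chase_design")
  if (length(design$courses) == 0L) stop("empty chase design")
  if (!is.null(fix)) {
    if (is.null(names(fix)) || !all(names(fix) %in% .par_names))
      stop("fix must be a named vector over {k1, k2, k3, E2L0}")
    if (any(fix < 0)) stop("fixed parameter values must be non-negative")
  }
  fix <- as.list(fix)
  free <- setdiff(.par_names, names(fix))
  if (length(free) == 0L) stop("no free parameters to fit")

  start <- .init_discharge(design, fix)
  if (!is.null(init)) {
    if (inherits(init, "kinetic_params")) init <- unlist(init)
    start[intersect(names(init), .par_names)] <-
      init[intersect(names(init), .par_names)]
    start[names(fix)] <- unlist(fix)
  }

  # theta: log scale for free rates, natural for E2L0
  to_theta <- function(p) {
    th <- numeric(0)
    for (nm in free)
      th[nm] <- if (nm %in% .rate_names) log(max(p[[nm]], 1e-10)) else p[[nm]]
    th
  }
  from_theta <- function(th) {
    p <- unlist(fix)
    for (nm in free)
      p[nm] <- if (nm %in% .rate_names) exp(th[[nm]]) else th[[nm]]
    p[.par_names]
  }
  lower <- vapply(free, function(nm)
    if (nm %in% .rate_names) .LOG_FLOOR else 1e-6, numeric(1L))
  upper <- vapply(free, function(nm)
    if (nm %in% .rate_names) .LOG_CEIL else 2, numeric(1L))

  obs <- unlist(lapply(design$courses, function(co) co$signal))
  resid_fun <- function(th) {
    p <- from_theta(setNames(th, free))
    unlist(lapply(design$courses, function(co) {
      .mono_model(p[["k1"]], p[["k2"]], p[["k3"]], p[["E2L0"]],
                  nu_of(co), co$time_min) - co$signal
    }))
  }

  th0 <- to_theta(as.list(start))
  lm_fit <- minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                               fn = resid_fun, control = control)
  th_hat <- setNames(coef(lm_fit), free)
  p_hat <- from_theta(th_hat)
  r <- resid_fun(th_hat)
  n <- length(obs)
  dof <- max(n - length(free), 1L)
  s2 <- sum(r^2) / dof
  converged <- lm_fit$info %in% 1:4

  # covariance: numeric Jacobian on the theta scale, delta method to
  # the natural scale (dk/dtheta = k for log-scale rates)
  J <- .num_jacobian(resid_fun, th_hat)
  vc_th <- tryCatch(s2 * solve(crossprod(J)),
                    error = function(e) matrix(NA_real_, length(free),
                                               length(free)))
  g <- vapply(free, function(nm)
    if (nm %in% .rate_names) p_hat[[nm]] else 1, numeric(1L))
  vc <- diag(g, length(g)) %*% vc_th %*% diag(g, length(g))
  dimnames(vc) <- list(free, free)
  stderr <- setNames(rep(NA_real_, 4L), .par_names)
  stderr[free] <- sqrt(pmax(diag(vc), 0))

  structure(list(estimates = p_hat, stderr = stderr, vcov = vc,
                 residual_rms = sqrt(mean(r^2)), n_points = n, df = dof,
                 converged = converged, apparent = isTRUE(apparent),
                 design = design, fix = fix, free = free,
                 init = start, message = lm_fit$message,
                 deviance = sum(r^2)),
            class = "discharge_fit")
}

.num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' @export
coef.discharge_fit <- function(object, ...) object$estimates

#' @export
vcov.discharge_fit <- function(object, ...) object$vcov

#' @export
print.discharge_fit <- function(x, digits = 4, ...) {
  cat("Global competing-pathway discharge fit",
      if (x$apparent) "(APPARENT rate constants: RING-containing data)"
      else "", "\n")
  cat(sprintf("  %d course(s), %d points, residual RMS %.4g%s\n",
              length(x$design$courses), x$n_points, x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$estimates
  for (nm in .par_names) {
    tag <- if (nm %in% names(x$fix)) " (fixed)" else
      sprintf(" +/- %.3g", x$stderr[[nm]])
    cat(sprintf("  %-5s = %.*g%s\n", nm, digits, est[[nm]], tag))
  }
  invisible(x)
}

#' @export
summary.discharge_fit <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(estimate = unname(est[.par_names]),
                    std_error = unname(object$stderr[.par_names]),
                    fixed = .par_names %in% names(object$fix),
                    row.names = .par_names)
  structure(list(coefficients = tab, residual_rms = object$residual_rms,
                 n_points = object$n_points, df = object$df,
                 converged = object$converged, apparent = object$apparent,
                 message = object$message,
                 half_life_k1 = if (est[["k1"]] > 0)
                   half_life_from_rate(est[["k1"]]) else Inf),
            class = "summary.discharge_fit")
}

#' @export
print.summary.discharge_fit <- function(x, ...) {
  cat("Competing-pathway discharge fit summary\n")
  if (x$apparent)
    cat("  (apparent rate constants: discharge from RING-bound/free mixture)\n")
  print(x$coefficients)
  cat(sprintf("residual RMS %.4g on %d points (df %d); k1 half-life %.3g min\n",
              x$residual_rms, x$n_points, x$df, x$half_life_k1))
  if (!x$converged)
    cat("WARNING: optimizer did not converge:", x$message, "\n")
  invisible(x)
}

#' Predict the observed mono-band signal from a fitted model
#'
#' @param object A `discharge_fit`.
#' @param newdata Data frame with columns `time_min` and `nu_mM`; when
#'   omitted, the design's own time grids are used.
#' @param ... Unused.
#' @return Numeric vector of predicted signals.
#' @export
predict.discharge_fit <- function(object, newdata = NULL, ...) {
  p <- object$estimates
  if (is.null(newdata)) return(fitted(object))
  stopifnot(all(c("time_min", "nu_mM") %in% names(newdata)))
  vapply(seq_len(nrow(newdata)), function(i)
    .mono_model(p[["k1"]], p[["k2"]], p[["k3"]], p[["E2L0"]],
                newdata$nu_mM[i], newdata$time_min[i]), numeric(1L))
}

#' @export
fitted.discharge_fit <- function(object, ...) {
  p <- object$estimates
  unlist(lapply(object$design$courses, function(co)
    .mono_model(p[["k1"]], p[["k2"]], p[["k3"]], p[["E2L0"]],
                nu_of(co), co$time_min)))
}

#' @export
residuals.discharge_fit <- function(object, ...) {
  unlist(lapply(object$design$courses, function(co) co$signal)) -
    fitted(object)
}

#' Plot a discharge fit: data points and fitted curves per course
#' @param x A `discharge_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.discharge_fit <- function(x, ...) {
  courses <- x$design$courses
  p <- x$estimates
  cols <- grDevices::hcl.colors(max(length(courses), 2L), "Dark 3")
  xr <- range(unlist(lapply(courses, function(co) co$time_min)))
  yr <- range(unlist(lapply(courses, function(co) co$signal)), 0)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (min)",
                 ylab = "mono-Ub band fraction", ...)
  tg <- seq(xr[1L], xr[2L], length.out = 200L)
  for (i in seq_along(courses)) {
    co <- courses[[i]]
    graphics::points(co$time_min, co$signal, col = cols[i], pch = 16)
    graphics::lines(tg, .mono_model(p[["k1"]], p[["k2"]], p[["k3"]],
                                    p[["E2L0"]], nu_of(co), tg),
                    col = cols[i])
  }
  graphics::legend("topright", bty = "n", col = cols[seq_along(courses)],
                   pch = 16, legend = sprintf("nu = %g mM",
                     vapply(courses, nu_of, numeric(1L))))
  invisible(x)
}

#' Simulate chase designs from a fitted discharge model
#'
#' Draws new noisy designs on the fitted parameter values at the original
#' time grids, with Gaussian noise of SD equal to the fit's residual RMS
#' (or a supplied `sigma`).
#'
#' @param object A `discharge_fit`.
#' @param nsim Number of simulated designs.
#' @param seed Integer seed.
#' @param sigma Noise SD on the fraction scale; defaults to the residual
#'   RMS of the fit.
#' @param ... Unused.
#' @return A list of `nsim` [chase_design] objects.
#' @export
simulate.discharge_fit <- function(object, nsim = 1, seed = NULL,
                                   sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- object$residual_rms
  p <- object$estimates
  kp <- kinetic_params(p[["k1"]], p[["k2"]], p[["k3"]],
                       min(p[["E2L0"]], 1))
  lapply(seq_len(nsim), function(s) {
    chase_design(lapply(object$design$courses, function(co) {
      mu <- .mono_model(p[["k1"]], p[["k2"]], p[["k3"]], p[["E2L0"]],
                        nu_of(co), co$time_min)
      time_course(co$time_min, mu + stats::rnorm(length(mu), 0, sigma),
                  nu = nu_of(co), observable = attr(co, "observable"),
                  label = sprintf("sim %d of '%s'", s, attr(co, "label")))
    }))
  })
}
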